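# synthetic generator from the model class itself: alternating states,
# inverse-Gaussian dwell times, Gaussian emissions
gen_edhmm_signal <- function(duration = 300, fs = 50, mu = c(0, 1),
                             sd = c(0.2, 0.2), dur_mu = c(0.8, 0.6),
                             dur_lambda = c(2, 2), seed = 1) {
  set.seed(seed)
  t_total <- 0
  states <- integer(0)
  lens <- numeric(0)
  s <- 0
  while (t_total < duration) {
    d <- max(1 / fs, rinvgauss(1, dur_mu[s + 1], dur_lambda[s + 1]))
    states <- c(states, s)
    lens <- c(lens, d)
    t_total <- t_total + d
    s <- 1 - s
  }
  lab <- rep(states, times = round(lens * fs))
  n <- min(length(lab), round(duration * fs))
  lab <- lab[seq_len(n)]
  x <- mu[lab + 1] + rnorm(n, 0, sd[lab + 1])
  list(x = x, lab = lab, fs = fs)
}

test_that("Viterbi equals exhaustive enumeration on a 12-sample toy", {
  set.seed(41)
  for (trial in 1:5) {
    T_ <- 12; D <- 4
    loglik <- matrix(rnorm(T_ * 2, sd = 2), T_, 2)
    p <- matrix(runif(D * 2, 0.05, 1), D, 2)
    p <- sweep(p, 2, colSums(p), "/")
    logdur <- log(p)
    surv <- apply(p, 2, function(q) rev(cumsum(rev(q))))
    logsurv <- log(surv)
    logpi <- log(c(0.5, 0.5))
    vit <- udsnet:::viterbi_ed_cpp(loglik, logdur, logsurv, logpi)
    vit_score <- udsnet:::path_score_cpp(vit, loglik, logdur, logsurv, logpi)
    oracle <- enumerate_decode(loglik, logdur, logsurv, logpi)
    expect_equal(vit_score, oracle$score, tolerance = 1e-10)
  }
})

test_that("a constant signal at the Down mean decodes as a single Down state", {
  n <- 500
  loglik <- cbind(dnorm(rep(0, n), 0, 1, log = TRUE),
                  dnorm(rep(0, n), 3, 1, log = TRUE))
  # duration support must cover the dwell for a censored single segment
  p <- matrix(1 / 600, 600, 2)
  logdur <- log(p)
  logsurv <- log(apply(p, 2, function(q) rev(cumsum(rev(q)))))
  path <- udsnet:::viterbi_ed_cpp(loglik, logdur, logsurv, log(c(0.5, 0.5)))
  expect_true(all(path == 0))
})

test_that("fitting recovers means, SDs and duration scale from model data", {
  g <- gen_edhmm_signal(duration = 400, seed = 5)
  rec <- recording(g$x, g$fs, "vm")
  m <- fit_edhmm(rec, prefiltered = TRUE, max_duration = 10)
  expect_lt(abs(m$global_means["down"] - 0), 0.1)
  expect_lt(abs(m$global_means["up"] - 1), 0.1)
  # duration means within 10%
  expect_lt(abs(m$duration[[1]]$mu - 0.8) / 0.8, 0.10)
  expect_lt(abs(m$duration[[2]]$mu - 0.6) / 0.6, 0.10)
  # EM objective history is monotone non-decreasing
  expect_true(all(diff(m$loglik_history) >= -1e-8 * abs(m$loglik_history[1])))
  # and the decode matches the generating labels almost everywhere
  sq <- viterbi_decode(m, rec)
  tt <- seq(0.01, length(g$x) / g$fs - 0.01, by = 0.02)
  acc <- mean((label_at(sq, tt) == "U") == (g$lab[pmin(floor(tt * g$fs) + 1,
                                                       length(g$lab))] == 1))
  expect_gt(acc, 0.95)
})

test_that("decoding is deterministic and strictly alternating", {
  g <- gen_edhmm_signal(duration = 200, seed = 6)
  rec <- recording(g$x, g$fs, "vm")
  m <- fit_edhmm(rec, prefiltered = TRUE, max_duration = 10)
  s1 <- viterbi_decode(m, rec)
  s2 <- viterbi_decode(m, rec)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$state[-1] != s1$state[-nrow(s1)]))
  expect_true(all(s1$end > s1$start))
})

test_that("label-swap symmetry: negated emissions give the complementary path", {
  set.seed(42)
  T_ <- 300
  x <- rnorm(T_) + rep(rep(c(0, 1), each = 25), 6)
  ll <- cbind(dnorm(x, 0, 0.5, log = TRUE), dnorm(x, 1, 0.5, log = TRUE))
  p <- matrix(stats::dgeom(0:59, 0.05) + 1e-12, 60, 2)
  p <- sweep(p, 2, colSums(p), "/")
  logdur <- log(p)
  logsurv <- log(apply(p, 2, function(q) rev(cumsum(rev(q)))))
  logpi <- log(c(0.5, 0.5))
  path <- udsnet:::viterbi_ed_cpp(ll, logdur, logsurv, logpi)
  path_sw <- udsnet:::viterbi_ed_cpp(ll[, 2:1], logdur, logsurv, logpi)
  expect_equal(path_sw, 1L - path)
})

test_that("decode accuracy increases with state separation", {
  accs <- vapply(c(0.25, 0.6, 1.2), function(sep) {
    g <- gen_edhmm_signal(duration = 250, mu = c(0, sep),
                          sd = c(0.35, 0.35), seed = 7)
    rec <- recording(g$x, g$fs, "vm")
    m <- tryCatch(fit_edhmm(rec, prefiltered = TRUE, max_duration = 10),
                  error = function(e) NULL)
    if (is.null(m)) return(0.5)
    sq <- viterbi_decode(m, rec)
    tt <- seq(0.01, length(g$x) / g$fs - 0.01, by = 0.02)
    mean((label_at(sq, tt) == "U") ==
           (g$lab[pmin(floor(tt * g$fs) + 1, length(g$lab))] == 1))
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
  expect_gt(accs[3], 0.95)
})

test_that("a unimodal signal is rejected as UDS-free", {
  set.seed(43)
  rec <- recording(rnorm(200 * 50), 50, "vm")
  expect_error(fit_edhmm(rec, prefiltered = TRUE), "no UDS")
})
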