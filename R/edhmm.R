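#' @name edhmm
#' @title Explicit-duration HMM segmentation of Up/Down states
#'
#' @description
#' Two-state hidden semi-Markov model with Gaussian emissions and
#' inverse-Gaussian state-duration distributions, decoded by an
#' explicit-duration Viterbi recursion. With two states and explicit
#' durations the transition matrix is forced (each state hands over to
#' the other with probability 1), so the free parameters are the
#' time-varying state means (estimated on a sliding window, so slow
#' drift of the recording does not corrupt the state assignment), the
#' per-state observation SDs, and the duration parameters.
NULL

# inverse-Gaussian density, closed-form MLE, and a discretized pmf
dinvgauss_log <- function(x, mu, lambda) {
  0.5 * log(lambda / (2 * pi * x^3)) - lambda * (x - mu)^2 / (2 * mu^2 * x)
}

invgauss_mle <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2) return(NULL)
  mu <- mean(x)
  lambda <- length(x) / sum(1 / x - 1 / mu)
  if (!is.finite(lambda) || lambda <= 0) return(NULL)
  list(mu = mu, lambda = lambda)
}

# duration pmf/survival over 1..d_max samples at rate fs (log scale)
duration_tables <- function(mu_s, lambda_s, d_max, fs) {
  d <- seq_len(d_max) / fs
  lp <- dinvgauss_log(d, mu_s, lambda_s)
  lp <- lp - log(sum(exp(lp - max(lp))) ) - max(lp)  # normalize
  p <- exp(lp)
  surv <- rev(cumsum(rev(p)))
  list(logp = lp, logsurv = log(pmax(surv, .Machine$double.xmin)))
}

#' Draw durations from an inverse-Gaussian distribution
#'
#' Michael-Schucany-Haas transformation sampler; used by the test suite
#' to generate data from the model class.
#'
#' @param n number of draws
#' @param mu mean (s)
#' @param lambda shape (s)
#' @export
rinvgauss <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)^2
  x <- mu + mu^2 * nu / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
  ifelse(stats::runif(n) <= mu / (mu + x), x, mu^2 / x)
}

edhmm_config <- function(fs_model = 50, max_duration = 30,
                         mean_window = 50, max_iter = 50, tol = 1e-4,
                         prefiltered = FALSE, band = c(0.05, 2)) {
  list(fs_model = fs_model, max_duration = max_duration,
       mean_window = mean_window, max_iter = max_iter, tol = tol,
       prefiltered = prefiltered, band = band)
}

# downsample a recording to the model rate (assumes band-limited input)
to_model_rate <- function(rec, fs_model) {
  ratio <- rec$fs / fs_model
  if (abs(ratio - round(ratio)) < 1e-9) {
    x <- rec$signal[seq(1, length(rec$signal), by = round(ratio))]
  } else {
    t_in <- (seq_along(rec$signal) - 1) / rec$fs
    t_out <- seq(0, max(t_in), by = 1 / fs_model)
    x <- stats::approx(t_in, rec$signal, xout = t_out)$y
  }
  x
}

# sliding-window state means given a hard path (or weights), clamped at
# the edges; samples of the other state are excluded from the window
sliding_means <- function(x, path, window_n) {
  n <- length(x)
  half <- window_n %/% 2
  mu <- matrix(NA_real_, n, 2)
  for (s in 0:1) {
    w <- as.numeric(path == s)
    cs_x <- cumsum(c(0, x * w))
    cs_w <- cumsum(c(0, w))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    nsum <- cs_w[hi + 1] - cs_w[lo]
    xsum <- cs_x[hi + 1] - cs_x[lo]
    glob <- if (sum(w) > 0) sum(x * w) / sum(w) else mean(x)
    mu[, s + 1] <- ifelse(nsum > 0, xsum / pmax(nsum, 1), glob)
  }
  # enforce Down mean < Up mean everywhere (degenerate windows only)
  bad <- mu[, 2] <= mu[, 1]
  if (any(bad)) {
    mid <- (mu[bad, 1] + mu[bad, 2]) / 2
    eps <- 1e-6 + stats::sd(x) * 1e-3
    mu[bad, 1] <- mid - eps
    mu[bad, 2] <- mid + eps
  }
  mu
}

emission_loglik <- function(x, mu, sd2) {
  cbind(stats::dnorm(x, mu[, 1], sd2[1], log = TRUE),
        stats::dnorm(x, mu[, 2], sd2[2], log = TRUE))
}

#' Fit the explicit-duration HMM to a band-limited recording
#'
#' The signal is band-passed to the UDS band (unless `prefiltered`),
#' downsampled to the decoding rate (default 50 Hz; the 0.05-2 Hz band
#' makes higher rates redundant), restricted to synchronized epochs, and
#' fitted by segmental EM: (i) initialization by a two-component
#' Gaussian mixture; (ii) alternation of explicit-duration Viterbi
#' decoding with re-estimation of sliding-window state means, state SDs
#' and inverse-Gaussian duration parameters (closed-form MLE). The
#' tracked objective is the joint (path + data) log score; an iteration
#' that would decrease it is reverted and the fit stops, so the recorded
#' history is monotone non-decreasing.
#'
#' @param rec a [recording()]
#' @param epochs optional [epoch_set()] of desynchronized intervals to
#'   exclude (the complement is analyzed); `NULL` uses the whole signal
#' @param cfg list from `edhmm_config()`; entries may be overridden via
#'   `...`
#' @param ... overrides for `edhmm_config()` entries
#' @return an object of class `edhmm_model`
#' @export
fit_edhmm <- function(rec, epochs = NULL, cfg = NULL, ...) {
  stopifnot(inherits(rec, "recording"))
  cfg <- utils::modifyList(if (is.null(cfg)) edhmm_config() else cfg,
                           list(...))
  if (!cfg$prefiltered) rec <- uds_band_filter(rec, cfg$band)
  x_full <- to_model_rate(rec, cfg$fs_model)
  keep <- sync_mask(length(x_full), cfg$fs_model, epochs)
  x <- x_full[keep]
  if (length(x) < 120 * cfg$fs_model)
    stop("need at least 120 s of synchronized data")
  # -- initialization: 2-component Gaussian mixture
  sub <- if (length(x) > 20000) x[seq(1, length(x), length.out = 20000)] else x
  gm <- mclust::Mclust(sub, G = 1:2, modelNames = "V", verbose = FALSE)
  if (gm$G < 2)
    stop("no UDS detected: a single Gaussian fits the signal best")
  mus <- gm$parameters$mean
  sds <- sqrt(gm$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, 2)
  ord <- order(mus)
  mus <- mus[ord]; sds <- sds[ord]
  pooled <- sqrt(mean(sds^2))
  if (diff(mus) < 0.5 * pooled)
    stop("no UDS detected: mixture separation below 0.5 pooled SD")
  d_max_n <- round(cfg$max_duration * cfg$fs_model)
  n <- length(x)
  mu_t <- cbind(rep(mus[1], n), rep(mus[2], n))
  sd2 <- sds
  dur <- list(list(mu = 0.8, lambda = 1.2), list(mu = 0.8, lambda = 1.2))
  logpi <- log(c(0.5, 0.5))
  window_n <- round(cfg$mean_window * cfg$fs_model)

  score_path <- function(path, mu_t, sd2, dur) {
    ll <- emission_loglik(x, mu_t, sd2)
    tabs <- lapply(dur, function(d)
      duration_tables(d$mu, d$lambda, d_max_n, cfg$fs_model))
    logdur <- cbind(tabs[[1]]$logp, tabs[[2]]$logp)
    logsurv <- cbind(tabs[[1]]$logsurv, tabs[[2]]$logsurv)
    path_score_cpp(path, ll, logdur, logsurv, logpi)
  }
  decode <- function(mu_t, sd2, dur) {
    ll <- emission_loglik(x, mu_t, sd2)
    tabs <- lapply(dur, function(d)
      duration_tables(d$mu, d$lambda, d_max_n, cfg$fs_model))
    logdur <- cbind(tabs[[1]]$logp, tabs[[2]]$logp)
    logsurv <- cbind(tabs[[1]]$logsurv, tabs[[2]]$logsurv)
    viterbi_ed_cpp(ll, logdur, logsurv, logpi)
  }

  history <- numeric(0)
  path <- decode(mu_t, sd2, dur)
  score <- score_path(path, mu_t, sd2, dur)
  history <- c(history, score)
  for (it in seq_len(cfg$max_iter)) {
    # M-step given the path
    mu_new <- sliding_means(x, path, window_n)
    sd_new <- vapply(0:1, function(s) {
      r <- x[path == s] - mu_new[path == s, s + 1]
      if (length(r) > 1) stats::sd(r) else sd2[s + 1]
    }, numeric(1))
    sd_new <- pmax(sd_new, 1e-6)
    segs <- rle(path)
    dur_new <- dur
    for (s in 0:1) {
      lens <- segs$lengths[segs$values == s]
      if (length(lens) > 2) lens <- lens[-c(1, length(lens))]  # edges
      fit <- invgauss_mle(lens / cfg$fs_model)
      if (!is.null(fit)) dur_new[[s + 1]] <- fit
    }
    path_new <- decode(mu_new, sd_new, dur_new)
    score_new <- score_path(path_new, mu_new, sd_new, dur_new)
    if (score_new < score - abs(score) * 1e-12) break  # revert and stop
    improved <- score_new > score + abs(score) * cfg$tol
    mu_t <- mu_new; sd2 <- sd_new; dur <- dur_new; path <- path_new
    score <- score_new
    history <- c(history, score)
    if (!improved) break
  }
  structure(list(mu_t = mu_t, sd = sd2, duration = dur, logpi = logpi,
                 fs_model = cfg$fs_model, d_max_n = d_max_n,
                 keep = keep, n_full = length(x_full),
                 loglik_history = history, cfg = cfg,
                 global_means = c(down = mean(mu_t[, 1]),
                                  up = mean(mu_t[, 2]))),
            class = "edhmm_model")
}

#' @export
print.edhmm_model <- function(x, ...) {
  cat(sprintf("edhmm_model at %g Hz: Down mean %.3g, Up mean %.3g, SDs %.3g/%.3g\n",
              x$fs_model, x$global_means[1], x$global_means[2],
              x$sd[1], x$sd[2]))
  cat(sprintf("  durations IG(mu=%.2fs, lambda=%.2f) / IG(mu=%.2fs, lambda=%.2f); %d EM steps\n",
              x$duration[[1]]$mu, x$duration[[1]]$lambda,
              x$duration[[2]]$mu, x$duration[[2]]$lambda,
              length(x$loglik_history)))
  invisible(x)
}

sync_mask <- function(n, fs, epochs) {
  keep <- rep(TRUE, n)
  if (!is.null(epochs) && nrow(epochs) > 0) {
    for (i in seq_len(nrow(epochs))) {
      i0 <- max(1, floor(epochs$start[i] * fs) + 1)
      i1 <- min(n, ceiling(epochs$end[i] * fs))
      if (i1 >= i0) keep[i0:i1] <- FALSE
    }
  }
  keep
}

#' Decode a recording into an Up/Down state sequence
#'
#' Maximum a posteriori duration-explicit path (Viterbi) under a fitted
#' [fit_edhmm()] model; deterministic. The recording is band-passed and
#' downsampled exactly as during fitting; each synchronized stretch is
#' decoded separately, and boundary times are reported at the decoding
#' resolution.
#'
#' @param model an `edhmm_model`
#' @param rec the [recording()] to decode (typically the one the model
#'   was fitted on)
#' @param epochs optional [epoch_set()] of desynchronized intervals to
#'   exclude
#' @return a [state_sequence()] when the synchronized data form one
#'   contiguous stretch; otherwise a `state_sequence_list` (plain list
#'   of per-stretch [state_sequence()]s, in time order)
#' @export
viterbi_decode <- function(model, rec, epochs = NULL) {
  stopifnot(inherits(model, "edhmm_model"), inherits(rec, "recording"))
  cfg <- model$cfg
  if (!cfg$prefiltered) rec <- uds_band_filter(rec, cfg$band)
  x_full <- to_model_rate(rec, cfg$fs_model)
  keep <- sync_mask(length(x_full), cfg$fs_model, epochs)
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  seqs <- list()
  tabs <- lapply(model$duration, function(d)
    duration_tables(d$mu, d$lambda, model$d_max_n, model$fs_model))
  logdur <- cbind(tabs[[1]]$logp, tabs[[2]]$logp)
  logsurv <- cbind(tabs[[1]]$logsurv, tabs[[2]]$logsurv)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    x <- x_full[idx]
    # per-sample means: reuse fitted sliding means when the geometry
    # matches, else the global state means
    mu <- if (nrow(model$mu_t) == length(x_full)) model$mu_t[idx, , drop = FALSE]
          else cbind(rep(model$global_means[1], length(x)),
                     rep(model$global_means[2], length(x)))
    ll <- emission_loglik(x, mu, model$sd)
    path <- viterbi_ed_cpp(ll, logdur, logsurv, model$logpi)
    r <- rle(path)
    e_i <- cumsum(r$lengths)
    s_i <- c(1, e_i[-length(e_i)] + 1)
    t0 <- (idx[1] - 1) / model$fs_model
    seqs[[length(seqs) + 1]] <-
      state_sequence(data.frame(start = t0 + (s_i - 1) / model$fs_model,
                                end = t0 + e_i / model$fs_model,
                                state = ifelse(r$values == 1, "U", "D")),
                     source = rec$role)
  }
  if (!length(seqs)) stop("no synchronized data to decode")
  if (length(seqs) == 1) return(seqs[[1]])
  structure(seqs, class = "state_sequence_list")
}

#' @export
print.state_sequence_list <- function(x, ...) {
  cat("state_sequence_list with", length(x), "synchronized stretches:\n")
  for (s in x) print(s)
  invisible(x)
}

#' Brute-force explicit-duration decoding oracle
#'
#' Enumerates every alternating segmentation of a (short) observation
#' vector and returns the highest-scoring path under the same
#' probabilistic model as [viterbi_decode()] (full duration pmf for all
#' segments but the last, survival for the last). Exponential in the
#' sequence length: a test oracle, not a tool.
#'
#' @param loglik T x 2 matrix of per-sample emission log-likelihoods
#' @param logdur,logsurv D x 2 duration log-pmf and log-survival tables
#' @param logpi length-2 initial state log-probabilities
#' @return list with `path` (0/1 vector) and `score`
#' @export
enumerate_decode <- function(loglik, logdur, logsurv, logpi) {
  T_ <- nrow(loglik)
  D <- nrow(logdur)
  best <- list(path = NULL, score = -Inf)
  recurse <- function(t, s, acc, path) {
    # choose the duration d of the segment starting at t+1 in state s
    for (d in seq_len(min(D, T_ - t))) {
      em <- sum(loglik[(t + 1):(t + d), s + 1])
      if (t + d == T_) {
        sc <- acc + em + logsurv[d, s + 1]
        if (sc > best$score)
          best <<- list(path = c(path, rep(s, d)), score = sc)
      } else {
        recurse(t + d, 1 - s, acc + em + logdur[d, s + 1],
                c(path, rep(s, d)))
      }
    }
  }
  for (s in 0:1) recurse(0, s, logpi[s + 1], integer(0))
  best
}
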