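test_that("response function matches its closed form at the band edges", {
  g <- 6; th <- 0.0517
  expect_equal(response(th, g, th), 0)
  expect_equal(response(th + 1 / g, g, th), 1)
  expect_equal(response(th + 1 / (2 * g), g, th), 0.5)
  expect_error(response(NaN, g, th), "finite")
  expect_error(response(0.1, -1, th), "gain")
})

test_that("response is continuous, non-decreasing and bounded on random inputs", {
  set.seed(11)
  for (i in 1:20) {
    g <- runif(1, 0.5, 40)
    th <- runif(1, -0.5, 0.5)
    x <- sort(runif(500, -2, 2))
    y <- response(x, g, th)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(diff(y) >= 0))
    # continuity: increments bounded by the local slope
    expect_true(all(diff(y) <= g * diff(x) + 1e-12))
  }
})

test_that("the Down state has exactly zero drift without noise or input", {
  p <- uds_params()
  expect_equal(drift(c(0, 0, 0), p), c(dE = 0, dI = 0, dA = 0))
})

test_that("drift vanishes at the adapted Up fixed point", {
  p <- uds_params()
  fp <- fixed_points(p, "self_consistent")
  st <- c(fp$up[["E"]], fp$up[["I"]], fp$a_up)
  expect_true(all(abs(drift(st, p)) < 1e-12))
})

test_that("adaptation accumulates from saturated excitation as W_AE/tau_A", {
  p <- uds_params()
  d <- drift(c(1, 0.3, 0), p)
  expect_equal(unname(d["dA"]), 1.1 / 300)
})

test_that("nullclines evaluate to their closed forms and shift linearly in A*", {
  p <- uds_params()
  nc <- nullclines(0, p, a_star = 0)
  expect_equal(nc$E_inh, 0.2778 / 1.66, tolerance = 1e-12)
  expect_equal(nc$E_exc, 6 * 0.0517 / 5, tolerance = 1e-12)
  # excitatory nullcline shifts by g_e*w_ea*dA/(g_e*w_ee-1) at every I
  iv <- seq(0, 1, by = 0.1)
  d <- nullclines(iv, p, a_star = 0.1)$E_exc - nullclines(iv, p, 0)$E_exc
  expect_equal(d, rep(6 * 0.166 * 0.1 / 5, length(iv)), tolerance = 1e-12)
  expect_error(nullclines(0, uds_params(w_ee = 0.1)), "degenerate")
})

test_that("closed-form fixed points agree with numerical nullcline roots", {
  p <- uds_params()
  fp <- fixed_points(p, "self_consistent")
  expect_equal(unname(fp$down), c(0, 0))
  # independent oracle: bisection on the nullcline difference with
  # adaptation slaved to activity (A = w_ae * E)
  f <- function(I) {
    e_inh <- ((1 + p$g_i * p$w_ii) * I + p$g_i * p$theta_i) /
      (p$g_i * p$w_ie)
    a <- p$w_ae * e_inh
    e_exc <- (p$g_e * p$w_ei * I + p$g_e * (p$w_ea * a + p$theta_e)) /
      (p$g_e * p$w_ee - 1)
    e_exc - e_inh
  }
  root <- uniroot(f, c(0.05, 2), tol = 1e-14)$root
  expect_equal(unname(fp$up[["I"]]), root, tolerance = 1e-10)
  # reference coordinates computed from the closed forms directly
  bI <- p$w_ii + 1 / p$g_i
  aE <- p$w_ee - 1 / p$g_e - p$w_ea * p$w_ae
  den <- p$w_ei * p$w_ie - aE * bI
  expect_equal(unname(fp$up[["E"]]),
               (p$w_ei * p$theta_i - bI * p$theta_e) / den,
               tolerance = 1e-14)
  expect_equal(unname(fp$up[["E"]]), 0.2007, tolerance = 1e-3)
  expect_equal(unname(fp$up[["I"]]), 0.4751, tolerance = 1e-3)
  expect_true(fp$linear_regime)
})

test_that("the separatrix point sits at the printed coordinates", {
  fp0 <- fixed_points(uds_params(), "frozen", a_star = 0)
  expect_equal(unname(fp0$saddle[["I"]]), 6 * 0.0517 / 5, tolerance = 1e-12)
  expect_equal(unname(fp0$saddle[["E"]]), 0)
})

test_that("raising frozen adaptation strictly lowers the Up-point activity", {
  p <- uds_params()
  a_grid <- seq(0, 0.3, by = 0.05)
  e_up <- vapply(a_grid, function(a)
    fixed_points(p, "frozen", a_star = a)$up[["E"]], numeric(1))
  expect_true(all(diff(e_up) < 0))
})

test_that("absent intersection is reported, not thrown", {
  # a huge excitatory threshold pushes the intersection to negative E
  fp <- fixed_points(uds_params(theta_e = 1), "self_consistent")
  expect_null(fp$up)
  expect_null(fp$saddle)
})

test_that("printed stability conditions evaluate verbatim; eigenvalues decide", {
  rd <- regime_diagnostics(uds_params())
  # existence condition: RHS (9.96/3.9044)*0.0517 ~ 0.1319 < theta_I
  expect_true(rd$condition_existence_1)
  # second existence condition has a negative RHS at these parameters
  expect_false(rd$condition_existence_2)
  # determinant condition: 0.1357 < 0.2756
  expect_true(rd$condition_det)
  # trace condition as printed: 5*7 = 35 < 10*3.49 = 34.9 is FALSE
  expect_false(rd$condition_trace)
  # the authoritative test: Jacobian eigenvalues have negative real part
  expect_true(all(Re(rd$eigenvalues) < 0))
  expect_true(rd$numerically_stable_up)
})

test_that("parameters serialize losslessly to JSON and YAML", {
  p <- uds_params(w_ee = 1.07, w_ext = 0.22)
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p))
    unlink(f)
  }
  expect_error(update_params(p, bogus = 1), "unknown")
  expect_error(uds_params(tau_e = -1), "positive")
  expect_error(uds_params(sigma_noise = -0.1), "non-negative")
})
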