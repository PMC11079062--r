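#' Threshold-linear response function with saturation
#'
#' The population response \eqn{\Omega(x)} is 0 at or below the threshold
#' \eqn{\theta}, rises linearly with slope `gain` over the band
#' \eqn{(\theta, \theta + 1/g)}, and saturates at 1 beyond. It is
#' continuous and non-decreasing; the value at exactly \eqn{x = \theta}
#' is 0 (the sub-threshold branch).
#'
#' @param x input current (vectorized)
#' @param gain response gain g (> 0)
#' @param threshold response threshold \eqn{\theta}
#' @return activity in \[0, 1\], same length as `x`
#' @export
response <- function(x, gain, threshold) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("response(): input current must be finite numeric")
  if (gain <= 0) stop("response(): gain must be positive")
  pmin(1, pmax(0, gain * (x - threshold)))
}

#' Instantaneous drift of one network
#'
#' Evaluates the deterministic right-hand side of the rate equations at a
#' given state, external current and noise sample:
#' \deqn{\tau_E dE/dt = -E + \Omega_E(W_{EE}E - W_{EI}I - W_{EA}A + \xi_E + i_E)}
#' \deqn{\tau_I dI/dt = -I + \Omega_I(W_{IE}E - W_{II}I + \xi_I)}
#' \deqn{\tau_A dA/dt = -A + W_{AE}E}
#' Noise enters inside the response-function argument. Time unit is ms,
#' so the returned derivatives are per ms.
#'
#' @param state numeric vector `c(E, I, A)`
#' @param params a [uds_params()] object
#' @param i_e external current into the excitatory population
#' @param xi_e,xi_i noise samples for the two populations
#' @return numeric vector `c(dE, dI, dA)` (per ms)
#' @export
drift <- function(state, params, i_e = 0, xi_e = 0, xi_i = 0) {
  stopifnot(inherits(params, "uds_params"), length(state) == 3)
  E <- state[[1]]; I <- state[[2]]; A <- state[[3]]
  p <- params
  dE <- (-E + response(p$w_ee * E - p$w_ei * I - p$w_ea * A + xi_e + i_e,
                       p$g_e, p$theta_e)) / p$tau_e
  dI <- (-I + response(p$w_ie * E - p$w_ii * I + xi_i, p$g_i, p$theta_i)) / p$tau_i
  dA <- (-A + p$w_ae * E) / p$tau_a
  c(dE = dE, dI = dI, dA = dA)
}

#' Nullclines of the fast (E, I) subsystem at frozen adaptation
#'
#' With adaptation frozen at `a_star`, the zero-drift curves of the two
#' populations in the linear band of the response function solve to
#' \deqn{E = \frac{g_E W_{EI} I + g_E (W_{EA} A^* + \theta_E)}{g_E W_{EE} - 1}}
#' (excitatory) and
#' \deqn{E = \frac{(1 + g_I W_{II}) I + g_I \theta_I}{g_I W_{IE}}}
#' (inhibitory). The excitatory nullcline shifts upward linearly with
#' `a_star`, which is how slow adaptation sculpts the bistability.
#'
#' @param i_values inhibitory activity values at which to evaluate
#' @param params a [uds_params()] object; requires `g_e * w_ee > 1`
#' @param a_star frozen adaptation level
#' @return data.frame with columns `I`, `E_exc` (excitatory nullcline) and
#'   `E_inh` (inhibitory nullcline)
#' @export
nullclines <- function(i_values, params, a_star = 0) {
  stopifnot(inherits(params, "uds_params"))
  p <- params
  den <- p$g_e * p$w_ee - 1
  if (den <= 0)
    stop("degenerate excitatory nullcline: g_e * w_ee must exceed 1")
  E_exc <- (p$g_e * p$w_ei * i_values + p$g_e * (p$w_ea * a_star + p$theta_e)) / den
  E_inh <- ((1 + p$g_i * p$w_ii) * i_values + p$g_i * p$theta_i) / (p$g_i * p$w_ie)
  data.frame(I = i_values, E_exc = E_exc, E_inh = E_inh)
}

#' Fixed points of one network
#'
#' The Down state (E, I) = (0, 0) is always a steady state. The Up state
#' is the positive intersection of the two nullclines: in
#' `"self_consistent"` mode adaptation is slaved to activity
#' (\eqn{A = W_{AE} E}), giving the closed forms
#' \deqn{E_{up} = \frac{W_{EI}\theta_I - (W_{II} + 1/g_I)\theta_E}
#'  {W_{EI}W_{IE} - (W_{EE} - 1/g_E - W_{EA}W_{AE})(W_{II} + 1/g_I)}}
#' and the corresponding expression for \eqn{I_{up}}; in `"frozen"` mode
#' the intersection is computed at the supplied `a_star`. A third point
#' sits on the separatrix at \eqn{E = 0},
#' \eqn{I = g_E(W_{EA}A^* + \theta_E)/(g_E W_{EE} - 1)}.
#'
#' Closed forms assume the linear band of the response function; the
#' result carries a `linear_regime` flag verifying post hoc that both
#' response arguments at the Up point lie strictly inside their bands.
#' If the nullclines have no positive intersection the Up point and
#' saddle are reported as absent (`NULL`), not as an error.
#'
#' @param params a [uds_params()] object
#' @param adaptation_mode `"self_consistent"` (A = W_AE E, the default) or
#'   `"frozen"`
#' @param a_star adaptation level used in `"frozen"` mode (and for the
#'   saddle in that mode)
#' @return a list of class `fixed_point_report` with elements `down`,
#'   `up`, `saddle` (each `c(E, I)` or `NULL`), `a_up` (adaptation at the
#'   Up point), and `linear_regime`.
#' @export
fixed_points <- function(params, adaptation_mode = c("self_consistent", "frozen"),
                         a_star = 0) {
  stopifnot(inherits(params, "uds_params"))
  adaptation_mode <- match.arg(adaptation_mode)
  p <- params
  if (p$g_e * p$w_ee <= 1)
    stop("degenerate excitatory nullcline: g_e * w_ee must exceed 1")
  bI <- p$w_ii + 1 / p$g_i
  if (adaptation_mode == "self_consistent") {
    aE <- p$w_ee - 1 / p$g_e - p$w_ea * p$w_ae
    den <- p$w_ei * p$w_ie - aE * bI
    up <- if (abs(den) > .Machine$double.eps) {
      c(E = (p$w_ei * p$theta_i - bI * p$theta_e) / den,
        I = (aE * p$theta_i - p$w_ie * p$theta_e) / den)
    } else NULL
    a_sep <- 0  # at E = 0 the slaved adaptation vanishes
  } else {
    # frozen a_star: equate the two nullclines, linear in I
    aE <- p$w_ee - 1 / p$g_e
    th_eff <- p$theta_e + p$w_ea * a_star
    den <- p$w_ei * p$w_ie - aE * bI
    up <- if (abs(den) > .Machine$double.eps) {
      c(E = (p$w_ei * p$theta_i - bI * th_eff) / den,
        I = (aE * p$theta_i - p$w_ie * th_eff) / den)
    } else NULL
    a_sep <- a_star
  }
  if (!is.null(up) && (up[["E"]] <= 0 || up[["I"]] <= 0)) up <- NULL
  saddle <- c(E = 0,
              I = p$g_e * (p$w_ea * a_sep + p$theta_e) / (p$g_e * p$w_ee - 1))
  if (is.null(up)) saddle <- NULL
  a_up <- if (is.null(up)) NULL else {
    if (adaptation_mode == "self_consistent") p$w_ae * up[["E"]] else a_star
  }
  linear <- NA
  if (!is.null(up)) {
    A <- if (adaptation_mode == "self_consistent") a_up else a_star
    xe <- p$w_ee * up[["E"]] - p$w_ei * up[["I"]] - p$w_ea * A
    xi <- p$w_ie * up[["E"]] - p$w_ii * up[["I"]]
    linear <- (xe > p$theta_e && xe < p$theta_e + 1 / p$g_e &&
               xi > p$theta_i && xi < p$theta_i + 1 / p$g_i)
  }
  structure(list(down = c(E = 0, I = 0), up = up, saddle = saddle,
                 a_up = a_up, adaptation_mode = adaptation_mode,
                 a_star = a_star, linear_regime = linear),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat("Fixed points (", x$adaptation_mode, " adaptation)\n", sep = "")
  cat(sprintf("  Down:   E = %.6f, I = %.6f\n", x$down[1], x$down[2]))
  if (is.null(x$up)) cat("  Up:     absent (no positive nullcline intersection)\n")
  else cat(sprintf("  Up:     E = %.6f, I = %.6f  (A = %.6f)\n",
                   x$up[1], x$up[2], x$a_up))
  if (!is.null(x$saddle))
    cat(sprintf("  Saddle: E = %.6f, I = %.6f (on separatrix)\n",
                x$saddle[1], x$saddle[2]))
  if (!is.na(x$linear_regime) && !x$linear_regime)
    cat("  warning: Up point outside the linear response band\n")
  invisible(x)
}

#' Stability and existence diagnostics of the Up state
#'
#' Evaluates, verbatim, the four printed inequalities that the reference
#' parameter set is stated to satisfy (existence of a positive nullcline
#' intersection and negative-trace/positive-determinant of the linearized
#' fast subsystem), and independently computes the eigenvalues of the
#' exact 2x2 Jacobian of the (E, I) equations (A frozen at the Up-point
#' value) at the Up fixed point. The eigenvalue test is authoritative:
#' two of the printed inequalities are marginal or inconsistent at the
#' reference parameters (one right-hand side is negative, one inequality
#' fails by 0.3%), while the Jacobian at the Up point is plainly stable.
#'
#' @param params a [uds_params()] object
#' @return a list of class `regime_diagnostics` with the four condition
#'   booleans (`condition_existence_1`, `condition_existence_2`,
#'   `condition_det`, `condition_trace`), `jacobian`, `eigenvalues`,
#'   `numerically_stable_up`, and the underlying `fixed_points` report.
#' @export
regime_diagnostics <- function(params) {
  stopifnot(inherits(params, "uds_params"))
  p <- params
  fp <- fixed_points(p, "self_consistent")

  # printed existence conditions, evaluated verbatim
  c7 <- p$theta_i >
    (p$g_e * p$w_ie / (p$g_e * p$w_ee - p$g_e * p$w_ea * p$w_ae - 1)) * p$theta_e
  c8_rhs <- (1 + p$g_i * p$w_ii) /
    (p$w_ee * (1 + p$g_i * p$w_ii) - p$g_i * p$w_ei * p$w_ie)
  c8 <- p$g_e < c8_rhs
  # printed determinant / trace conditions
  c11 <- (p$w_ii + 1 / p$g_i) * (p$w_ee + 1 / p$g_e) < p$w_ei * p$w_ie
  c12 <- p$tau_i * (p$g_e * p$w_ee + 1) < p$tau_e * (p$g_i * p$w_ii + 1)

  J <- eig <- NULL; stable <- NA
  if (!is.null(fp$up)) {
    # linear-band Jacobian of (dE/dt, dI/dt) at the Up point, A frozen
    J <- matrix(c((p$g_e * p$w_ee - 1) / p$tau_e, -p$g_e * p$w_ei / p$tau_e,
                  p$g_i * p$w_ie / p$tau_i, -(p$g_i * p$w_ii + 1) / p$tau_i),
                2, 2, byrow = TRUE,
                dimnames = list(c("E", "I"), c("E", "I")))
    eig <- eigen(J, only.values = TRUE)$values
    stable <- all(Re(eig) < 0)
  }
  structure(list(condition_existence_1 = c7, condition_existence_2 = c8,
                 condition_det = c11, condition_trace = c12,
                 jacobian = J, eigenvalues = eig,
                 numerically_stable_up = stable,
                 fixed_points = fp),
            class = "regime_diagnostics")
}

#' @export
print.regime_diagnostics <- function(x, ...) {
  cat("Up-state regime diagnostics\n")
  cat(sprintf("  printed conditions: existence %s / %s, det %s, trace %s\n",
              x$condition_existence_1, x$condition_existence_2,
              x$condition_det, x$condition_trace))
  if (!is.null(x$eigenvalues))
    cat(sprintf("  Jacobian eigenvalues: %s; stable: %s\n",
                paste(format(x$eigenvalues, digits = 4), collapse = ", "),
                x$numerically_stable_up))
  invisible(x)
}
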