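#' Simulate one mean-field network
#'
#' Integrates the stochastic rate equations with a fixed-step classical
#' RK4 scheme (default step 0.2 ms). The noise current is an
#' Ornstein-Uhlenbeck process with stationary SD `params$sigma_noise`
#' and correlation time `tau_noise` (default 200 ms), updated once per
#' step (exact discretization, so the process statistics do not depend
#' on `dt`) and held constant across the RK4 substeps. By default the
#' noise feeds the excitatory population only: the inhibitory response
#' band is only `1/g_i` wide, so direct inhibitory noise of the same
#' amplitude destroys the Up state at sub-sigma excursions (see the
#' methods vignette); `sigma_i_frac` scales an independent stream into
#' the inhibitory population, and `params$shared_noise` routes the
#' excitatory stream into both.
#'
#' The response function is integrated in threshold-linear form: at the
#' reference operating point the excitatory activity never approaches
#' the saturation ceiling, and upward excursions are terminated by the
#' fast inhibitory loop (transient inhibitory activity above 1) rather
#' than by a hard ceiling, which would otherwise create a spurious
#' absorbing high-rate state. Set `response_cap = 1` to restore the hard
#' ceiling of the textbook response.
#'
#' The simulation starts in the Down state `(0, 0, 0)` (configurable)
#' and a burn-in period is discarded so state-occupancy statistics are
#' not biased by the initial transient.
#'
#' @param params a [uds_params()] object; use [sim_params()] for the
#'   reference operating point
#' @param duration simulated time to keep, in seconds
#' @param dt integration step in ms
#' @param seed integer seed; the trajectory is fully reproducible given
#'   `(params, duration, dt, seed, drive)`
#' @param drive external current into the excitatory population: `NULL`
#'   (none), a scalar (constant current), or a numeric vector sampled at
#'   the integration step covering burn-in plus duration (as produced for
#'   the efferent member of a coupled pair)
#' @param burn_in seconds discarded before recording starts
#' @param record_dt sampling interval (ms) of the stored trajectories;
#'   must be a multiple of `dt`
#' @param init initial state `c(E, I, A)`
#' @param tau_noise noise correlation time (ms)
#' @param sigma_i_frac multiplier on the independent inhibitory noise
#'   stream (0 = none, the default)
#' @param response_cap saturation ceiling of the response function during
#'   integration; `Inf` (default) integrates the threshold-linear form
#' @param method `"rk4"` (default) or `"euler"` (first-order comparison
#'   integrator, same noise convention)
#' @param keep_full_e if `TRUE` the per-step excitatory trajectory
#'   (including burn-in) is attached as attribute `"E_full"`, for use as
#'   a downstream drive
#' @return a `sim_trace`: data.frame with columns `t` (s), `E`, `I`, `A`,
#'   with the parameters, dt, and seed attached as attributes.
#' @export
simulate_network <- function(params, duration, dt = 0.2, seed = 1,
                             drive = NULL, burn_in = 5, record_dt = 2,
                             init = c(0, 0, 0), tau_noise = 200,
                             sigma_i_frac = 0, response_cap = Inf,
                             method = c("rk4", "euler"),
                             keep_full_e = FALSE) {
  stopifnot(inherits(params, "uds_params"), duration > 0, dt > 0,
            tau_noise > 0, sigma_i_frac >= 0)
  method <- match.arg(method)
  record_every <- round(record_dt / dt)
  if (abs(record_every * dt - record_dt) > 1e-9)
    stop("record_dt must be a multiple of dt")
  n_burn <- round(burn_in * 1000 / dt)
  n_burn <- (n_burn %/% record_every) * record_every  # align to record grid
  n_keep <- round(duration * 1000 / dt)
  n_steps <- n_burn + n_keep
  drv <- numeric(0)
  if (!is.null(drive)) {
    drv <- if (length(drive) == 1) rep(drive, n_steps) else as.numeric(drive)
    if (length(drv) < n_steps)
      stop("drive trace does not cover burn-in plus duration")
  }
  pv <- unlist(params[c("tau_e", "tau_i", "tau_a", "g_e", "g_i",
                        "theta_e", "theta_i", "w_ee", "w_ei", "w_ie",
                        "w_ii", "w_ea", "w_ae")])
  set.seed(as.integer(seed %% 2147483647))
  out <- sim_network_cpp(pv, n_steps, dt, record_every, drv, init,
                         params$sigma_noise, tau_noise, sigma_i_frac,
                         params$shared_noise,
                         if (is.finite(response_cap)) response_cap else -1,
                         keep_full_e, method == "euler")
  keep_from <- n_burn %/% record_every + 1L
  idx <- keep_from:length(out$E)
  # exactly duration/record_dt samples: drop the trailing fencepost so
  # rendered recordings have round, FFT-friendly lengths
  n_want <- n_keep %/% record_every
  if (length(idx) > n_want) idx <- idx[seq_len(n_want)]
  tr <- data.frame(t = (seq_along(idx) - 1) * record_dt / 1000,
                   E = out$E[idx], I = out$I[idx], A = out$A[idx])
  attr(tr, "params") <- params
  attr(tr, "dt") <- dt
  attr(tr, "record_dt") <- record_dt
  attr(tr, "seed") <- seed
  attr(tr, "burn_in") <- burn_in
  attr(tr, "method") <- method
  attr(tr, "tau_noise") <- tau_noise
  if (keep_full_e) attr(tr, "E_full") <- out$E_full
  if (!is.null(drive)) {
    steps <- pmin(n_burn + (seq_along(idx) - 1L) * record_every + 1L, n_steps)
    attr(tr, "drive_rec") <- drv[steps]
  }
  class(tr) <- c("sim_trace", "data.frame")
  tr
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("sim_trace: %.1f s at %g ms sampling (dt = %g ms, seed %s)\n",
              max(x$t), attr(x, "record_dt"), attr(x, "dt"),
              format(attr(x, "seed"))))
  cat(sprintf("  E in [%.3f, %.3f], mean %.3f\n", min(x$E), max(x$E), mean(x$E)))
  invisible(x)
}

#' Simulate the unidirectionally coupled afferent/efferent pair
#'
#' The afferent network evolves independently; the efferent network
#' receives the external excitatory current
#' `i_E(t) = w_ext * E_afferent(t)` each integration step, with no
#' back-coupling. By convention all internal parameters of the two
#' networks are identical except the efferent recurrent excitation
#' (`W_INT`, the efferent `w_ee`); both are taken from the supplied
#' parameter objects, so asymmetric variants remain expressible.
#'
#' @param afferent_params,efferent_params [uds_params()] objects; the
#'   coupling weight is `efferent_params$w_ext` unless overridden
#' @param w_ext afferent-to-efferent weight; default
#'   `efferent_params$w_ext`
#' @param duration,dt,seed,burn_in,record_dt,tau_noise,sigma_i_frac,response_cap,method
#'   as in [simulate_network()]; the afferent and efferent networks
#'   consume independent noise streams derived from `seed`
#' @return a list of class `coupled_trace` with elements `afferent`,
#'   `efferent` (both `sim_trace`) and `w_ext`
#' @export
simulate_coupled <- function(afferent_params, efferent_params,
                             w_ext = efferent_params$w_ext,
                             duration = 300, dt = 0.2, seed = 1,
                             burn_in = 5, record_dt = 2, tau_noise = 200,
                             sigma_i_frac = 0, response_cap = Inf,
                             method = "rk4") {
  stopifnot(w_ext >= 0)
  aff <- simulate_network(afferent_params, duration, dt, seed = seed,
                          burn_in = burn_in, record_dt = record_dt,
                          tau_noise = tau_noise, sigma_i_frac = sigma_i_frac,
                          response_cap = response_cap,
                          method = method, keep_full_e = TRUE)
  e_full <- attr(aff, "E_full")
  eff <- simulate_network(update_params(efferent_params, w_ext = w_ext),
                          duration, dt, seed = seed + 500000L,
                          drive = w_ext * e_full,
                          burn_in = burn_in, record_dt = record_dt,
                          tau_noise = tau_noise, sigma_i_frac = sigma_i_frac,
                          response_cap = response_cap,
                          method = method)
  attr(aff, "E_full") <- NULL
  structure(list(afferent = aff, efferent = eff, w_ext = w_ext),
            class = "coupled_trace")
}

#' @export
print.coupled_trace <- function(x, ...) {
  cat(sprintf("coupled_trace (w_ext = %g)\n", x$w_ext))
  cat("afferent: "); print(x$afferent)
  cat("efferent: "); print(x$efferent)
  invisible(x)
}

#' Fast Up/Down labelling of a simulated trace by hysteresis
#'
#' Grid simulations need state labels orders of magnitude faster than the
#' full EDHMM decoder. The hysteresis rule enters the Up state when the
#' excitatory activity crosses above a high threshold and the Down state
#' when it falls below a low threshold; between the thresholds the label
#' is carried forward, so chatter around a single boundary cannot create
#' spurious states. Default thresholds are placed symmetrically about the
#' midpoint of the Down (E = 0) to Up-fixed-point gap, at midpoint plus
#' or minus a quarter of the gap.
#'
#' @param trace a `sim_trace`
#' @param hi,lo thresholds on E; defaults derived from the trace's own
#'   parameters (0.75 and 0.25 of the Up-point E)
#' @return a [state_sequence()]
#' @export
binarize_states <- function(trace, hi = NULL, lo = NULL) {
  stopifnot(inherits(trace, "sim_trace"), nrow(trace) > 0)
  if (is.null(hi) || is.null(lo)) {
    p <- attr(trace, "params")
    e_up <- NULL
    if (!is.null(p)) {
      fp <- fixed_points(p, "self_consistent")
      if (!is.null(fp$up)) e_up <- fp$up[["E"]]
    }
    if (is.null(e_up)) e_up <- stats::quantile(trace$E, 0.99, names = FALSE)
    if (is.null(hi)) hi <- 0.75 * e_up
    if (is.null(lo)) lo <- 0.25 * e_up
  }
  stopifnot(hi > lo)
  lab <- ifelse(trace$E >= hi, 1L, ifelse(trace$E <= lo, 0L, NA_integer_))
  if (all(is.na(lab))) lab[1] <- 0L
  # carry the last decided label forward; before the first decision,
  # backfill with it
  known <- !is.na(lab)
  first <- which(known)[1]
  lab[seq_len(first - 1)] <- lab[first]
  idx <- cumsum(known)
  lab <- lab[known][pmax(idx, 1)]
  r <- rle(lab)
  n <- length(r$lengths)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1, ends_i[-n] + 1)
  step_s <- attr(trace, "record_dt") / 1000
  seq_df <- data.frame(start = trace$t[starts_i],
                       end = c(trace$t[starts_i[-1]],
                               trace$t[length(trace$t)] + step_s),
                       state = ifelse(r$values == 1, "U", "D"))
  if (n == 1)
    warning("trace shorter than one dwell: single-state sequence")
  state_sequence(seq_df, source = "model")
}
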