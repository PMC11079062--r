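#' Sampled recording channel
#'
#' A `recording` wraps a sampled signal (membrane potential in mV or LFP
#' in arbitrary units) with its sampling rate, channel role and optional
#' ground truth (generating parameters, state labels, spike times,
#' inserted desynchronized epochs).
#'
#' @param signal numeric vector of samples
#' @param fs sampling rate (Hz)
#' @param role `"vm"` or `"lfp"`
#' @param truth optional list with any of `states` (a [state_sequence()]),
#'   `w_ext`, `w_int`, `spikes` (times s), `desync` (an `epoch_set`)
#' @export
recording <- function(signal, fs, role = c("vm", "lfp"), truth = NULL) {
  role <- match.arg(role)
  if (!is.numeric(signal) || !length(signal)) stop("signal must be numeric")
  if (any(!is.finite(signal)))
    stop("non-finite sample at index ", which(!is.finite(signal))[1])
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  structure(list(signal = as.numeric(signal), fs = fs, role = role,
                 truth = truth),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording (%s): %.1f s at %g Hz, range [%.2f, %.2f]\n",
              x$role, length(x$signal) / x$fs, x$fs,
              min(x$signal), max(x$signal)))
  if (!is.null(x$truth$w_ext))
    cat(sprintf("  ground truth: w_ext = %g, w_int = %g\n",
                x$truth$w_ext, x$truth$w_int))
  invisible(x)
}

rec_duration <- function(rec) length(rec$signal) / rec$fs

#' Rendering configuration for surrogate recordings
#'
#' State-conditional membrane potential means default to the depolarized
#' Up (-52.4 mV) and hyperpolarized Down (-74.2 mV) levels typical of
#' medial entorhinal layer-3 neurons under urethane; observation noise,
#' spike and mains-interference settings control how much realistic
#' nuisance structure is layered on top of the model activity.
#'
#' @param up_mv,down_mv state-conditional V_m means (mV); `up_mv` must
#'   exceed `down_mv`
#' @param obs_noise_mv SD of additive Gaussian observation noise (mV)
#' @param spike_rate_gain spikes/s per unit supra-threshold excitatory
#'   activity (0 disables spikes)
#' @param spike_amp_mv spike height (mV) of the 1 ms triangular waveform
#' @param mains_amp amplitude (mV) of the 50 Hz mains series (0 = none)
#' @param fs_vm,fs_lfp sampling rates (Hz)
#' @param lfp_polarity +1 renders Up states as positive LFP deflections
#' @param lfp_noise relative SD of 1/f background added to the LFP
#' @export
render_config <- function(up_mv = -52.4, down_mv = -74.2,
                          obs_noise_mv = 1.0, spike_rate_gain = 30,
                          spike_amp_mv = 40, mains_amp = 0.3,
                          fs_vm = 2000, fs_lfp = 1000,
                          lfp_polarity = 1, lfp_noise = 0.1) {
  stopifnot(up_mv > down_mv, fs_vm > 0, fs_lfp > 0,
            lfp_polarity %in% c(-1, 1))
  if (spike_rate_gain > 0 && fs_vm < 500)
    stop("fs_vm must be at least 500 Hz when spikes are enabled")
  structure(list(up_mv = up_mv, down_mv = down_mv,
                 obs_noise_mv = obs_noise_mv,
                 spike_rate_gain = spike_rate_gain,
                 spike_amp_mv = spike_amp_mv, mains_amp = mains_amp,
                 fs_vm = fs_vm, fs_lfp = fs_lfp,
                 lfp_polarity = lfp_polarity, lfp_noise = lfp_noise),
            class = "render_config")
}

label_at_states <- function(sq, t) {
  i <- findInterval(t, sq$start)
  out <- rep(NA_character_, length(t))
  ok <- i >= 1
  out[ok] <- sq$state[i[ok]]
  out
}

resample_to <- function(x, t_in, fs_out, duration) {
  t_out <- seq(0, duration - 1 / fs_out, by = 1 / fs_out)
  stats::approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}

# 1/f ("pink") noise of unit SD via spectral shaping
pink_noise <- function(n, fs) {
  n2 <- stats::nextn(n, c(2, 3, 5))  # keep the FFT length smooth
  white <- stats::rnorm(n2)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n2 - 1))  # avoid DC blow-up
  f <- pmin(f, n2 - f + 1)    # two-sided frequency index
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE))[seq_len(n)] / n2
  shaped / stats::sd(shaped)
}

#' Render a simulated trace as a surrogate membrane-potential recording
#'
#' Applies the affine map sending model activity E = 0 to the Down-state
#' potential and E = E_up (the Up fixed point of the trace's own
#' parameters) to the Up-state potential, resamples to the target rate,
#' and optionally adds Gaussian observation noise, action-potential
#' waveforms (1 ms triangular spikes at inhomogeneous Poisson times with
#' rate `spike_rate_gain * max(E - theta_e, 0)`), and a 50 Hz mains
#' sinusoid. Ground-truth state labels (hysteresis labelling of the
#' source trace), spike times and generating parameters are carried in
#' `truth`.
#'
#' @param trace a `sim_trace`
#' @param cfg a [render_config()]
#' @param seed integer seed for observation noise and spikes
#' @return a [recording()] with `role = "vm"`
#' @export
render_vm <- function(trace, cfg = render_config(), seed = 1) {
  stopifnot(inherits(trace, "sim_trace"), inherits(cfg, "render_config"),
            nrow(trace) > 0)
  p <- attr(trace, "params")
  fp <- fixed_points(p, "self_consistent")
  e_up <- if (!is.null(fp$up)) fp$up[["E"]] else max(trace$E)
  truth_states <- suppressWarnings(binarize_states(trace))
  # anchor the Up level at the realized mean Up-state activity (for a
  # trace sitting exactly on the fixed point this IS the fixed point);
  # adaptation drags activity below the nominal Up point over a dwell,
  # and the mV anchor should reflect the depolarized level actually held
  up_lab <- label_at_states(truth_states, trace$t)
  e_in_up <- trace$E[up_lab == "U"]
  if (length(e_in_up) > 10 && stats::sd(e_in_up) > 1e-9)
    e_up <- mean(e_in_up)
  dur <- max(trace$t) + attr(trace, "record_dt") / 1000
  set.seed(as.integer(seed %% 2147483647))
  e_rs <- resample_to(trace$E, trace$t, cfg$fs_vm, dur)
  v <- cfg$down_mv + (cfg$up_mv - cfg$down_mv) * e_rs / e_up
  n <- length(v)
  tt <- (seq_len(n) - 1) / cfg$fs_vm
  if (cfg$obs_noise_mv > 0) v <- v + stats::rnorm(n, 0, cfg$obs_noise_mv)
  spikes <- numeric(0)
  if (cfg$spike_rate_gain > 0) {
    rate <- cfg$spike_rate_gain * pmax(e_rs - p$theta_e, 0)  # spikes/s
    lambda_max <- max(rate)
    if (lambda_max > 0) {  # thinning
      cand <- cumsum(stats::rexp(ceiling(lambda_max * dur * 1.5) + 10,
                                 lambda_max))
      cand <- cand[cand < dur]
      keep <- stats::runif(length(cand)) <
        rate[pmin(floor(cand * cfg$fs_vm) + 1, n)] / lambda_max
      spikes <- cand[keep]
      half <- round(cfg$fs_vm * 0.0005)  # 1 ms triangular waveform
      wave <- cfg$spike_amp_mv *
        (1 - abs(seq(-half, half)) / max(half, 1))
      for (s in spikes) {
        i0 <- round(s * cfg$fs_vm) + 1
        idx <- (i0 - half):(i0 + half)
        ok <- idx >= 1 & idx <= n
        v[idx[ok]] <- v[idx[ok]] + wave[ok]
      }
    }
  }
  if (cfg$mains_amp > 0) v <- v + cfg$mains_amp * sin(2 * pi * 50 * tt)
  truth <- list(states = truth_states,
                spikes = spikes,
                w_int = p$w_ee, w_ext = p$w_ext,
                e_up_anchor = e_up)
  recording(v, cfg$fs_vm, "vm", truth = truth)
}

#' Render a simulated afferent trace as a surrogate LFP recording
#'
#' The afferent excitatory activity is resampled, polarity-signed,
#' z-scored and mixed with optional 1/f background noise, emulating a
#' cortical LFP channel that tracks the population Up/Down state.
#'
#' @param trace a `sim_trace` (typically the afferent of a coupled pair)
#' @param cfg a [render_config()]
#' @param seed integer seed for the background noise
#' @return a [recording()] with `role = "lfp"` (z-scored a.u.)
#' @export
render_lfp <- function(trace, cfg = render_config(), seed = 1) {
  stopifnot(inherits(trace, "sim_trace"), inherits(cfg, "render_config"),
            nrow(trace) > 0)
  dur <- max(trace$t) + attr(trace, "record_dt") / 1000
  set.seed(as.integer(seed %% 2147483647))
  x <- resample_to(trace$E, trace$t, cfg$fs_lfp, dur)
  x <- cfg$lfp_polarity * scale(x)[, 1]
  if (cfg$lfp_noise > 0)
    x <- x + cfg$lfp_noise * pink_noise(length(x), cfg$fs_lfp)
  p <- attr(trace, "params")
  truth <- list(states = binarize_states(trace),
                w_int = p$w_ee, w_ext = p$w_ext)
  recording(scale(x)[, 1], cfg$fs_lfp, "lfp", truth = truth)
}

#' Generate a dataset of paired surrogate recordings
#'
#' Stands in for a population of simultaneously recorded cells: for each
#' ground-truth `(w_ext, w_int)` pair, one coupled simulation is run and
#' rendered as a paired V_m/LFP recording with full ground truth.
#' Optionally a desynchronized epoch — both channels replaced by
#' low-amplitude 1/f noise, which suppresses the 0.05-2 Hz UDS band —
#' is inserted and logged in `truth$desync`.
#'
#' @param truth_list list of `c(w_ext, w_int)` pairs (or a 2-column
#'   matrix/data.frame)
#' @param duration seconds of simulation per cell
#' @param cfg a [render_config()]
#' @param seeds integer seeds, one per cell (default `seq_along` + offset)
#' @param params base parameter set, [sim_params()] by default
#' @param desync `NULL`, or `c(start, end)` seconds of a desynchronized
#'   epoch inserted into every cell
#' @param desync_amp amplitude of the desynchronized 1/f surrogate
#'   relative to each channel's UDS SD (default 0.2)
#' @return list of cells; each cell is a list `(vm, lfp, w_ext, w_int,
#'   seed)`
#' @export
make_cell_dataset <- function(truth_list, duration = 300,
                              cfg = render_config(), seeds = NULL,
                              params = sim_params(), desync = NULL,
                              desync_amp = 0.2) {
  if (is.matrix(truth_list) || is.data.frame(truth_list))
    truth_list <- lapply(seq_len(nrow(truth_list)),
                         function(i) unlist(truth_list[i, 1:2]))
  if (!length(truth_list)) stop("truth_list must not be empty")
  if (is.null(seeds)) seeds <- 1000L + seq_along(truth_list)
  stopifnot(length(seeds) == length(truth_list))
  lapply(seq_along(truth_list), function(i) {
    tv <- truth_list[[i]]
    w_ext <- tv[[1]]; w_int <- tv[[2]]
    ct <- simulate_coupled(params, update_params(params, w_ee = w_int),
                           w_ext = w_ext, duration = duration,
                           seed = seeds[i])
    vm <- render_vm(ct$efferent, cfg, seed = seeds[i] + 1L)
    lfp <- render_lfp(ct$afferent, cfg, seed = seeds[i] + 2L)
    if (!is.null(desync)) {
      vm <- insert_desync(vm, desync, desync_amp)
      lfp <- insert_desync(lfp, desync, desync_amp)
    }
    list(vm = vm, lfp = lfp, w_ext = w_ext, w_int = w_int, seed = seeds[i])
  })
}

insert_desync <- function(rec, interval, amp = 0.2) {
  i0 <- max(1, round(interval[1] * rec$fs) + 1)
  i1 <- min(length(rec$signal), round(interval[2] * rec$fs))
  if (i1 <= i0) stop("desynchronized interval outside the recording")
  seg <- i0:i1
  base <- mean(rec$signal)
  rec$signal[seg] <- base +
    amp * stats::sd(rec$signal) * pink_noise(length(seg), rec$fs)
  rec$truth$desync <- epoch_set(data.frame(start = interval[1],
                                           end = interval[2],
                                           label = "desynchronized"))
  rec
}
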