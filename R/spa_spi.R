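#' Greedy assignment of efferent state transitions to afferent triggers
#'
#' Each efferent state initiation (the start of an Up or Down interval)
#' is linked, in temporal order, to the nearest afferent initiation of
#' the same type (tie toward the earlier one); matches that would break
#' temporal order, as happens around transient desynchronizations, are
#' dropped rather than forced onto a distant neighbour, so the matched
#' initiations always advance through the afferent sequence. The
#' afferent states between consecutive matched initiations form a
#' state's trigger set (`n_trigger`). Persistence is classified from the
#' definition directly: an efferent state is persistent when at least
#' one complete opposite-label afferent state lies wholly inside it
#' (`n_contained`) — an Up state spanning a complete afferent Down state
#' is spontaneous persistent activity (SPA), a Down state spanning a
#' complete afferent Up state is spontaneous persistent inactivity
#' (SPI). Under tight locking `n_trigger == 1 + 2 * n_contained`; when
#' locking loosens the containment count remains well defined while
#' initiation matching degrades, so the rates are built on containment.
#'
#' States truncated by the recording boundaries (the first and last
#' efferent states) are assigned but flagged `edge` and excluded from all
#' downstream rate and delay statistics.
#'
#' @param efferent,afferent `state_sequence` objects covering overlapping
#'   time spans
#' @return a list of class `transition_assignment` with a per-efferent
#'   state table (`state`, `start`, `end`, `matched_afferent_time`,
#'   `n_trigger`, `delay`, `persistent`, `edge`) and the two input
#'   sequences
#' @export
assign_transitions <- function(efferent, afferent) {
  stopifnot(inherits(efferent, "state_sequence"),
            inherits(afferent, "state_sequence"))
  if (nrow(efferent) == 0 || nrow(afferent) == 0)
    stop("empty state sequence")
  ne <- nrow(efferent)
  match_idx <- rep(NA_integer_, ne)
  for (k in seq_len(ne)) {
    cand <- which(afferent$state == efferent$state[k])
    if (!length(cand)) next
    dist <- abs(efferent$start[k] - afferent$start[cand])
    match_idx[k] <- cand[which(dist == min(dist))[1]]  # tie -> earlier
  }
  # trigger sets must partition the afferent sequence in temporal order:
  # when two efferent initiations grab the same or out-of-order afferent
  # initiations (transient desynchronization), the later one is dropped
  # from the assignment rather than forced onto a distant neighbour
  last <- 0L
  for (k in seq_len(ne)) {
    if (is.na(match_idx[k])) next
    if (match_idx[k] <= last) match_idx[k] <- NA_integer_
    else last <- match_idx[k]
  }
  n_trigger <- rep(NA_integer_, ne)
  for (k in seq_len(ne - 1)) {
    if (!is.na(match_idx[k]) && !is.na(match_idx[k + 1]))
      n_trigger[k] <- match_idx[k + 1] - match_idx[k]
  }
  delay <- ifelse(is.na(match_idx), NA_real_,
                  efferent$start - afferent$start[match_idx])
  # persistence bookkeeping follows the definition directly: the number
  # of complete opposite-label afferent states wholly contained in the
  # efferent interval (a state "outlasts an entire afferent state").
  # The matched-initiation trigger count agrees with 1 + 2*n_contained
  # under tight locking but degrades when transitions desynchronize;
  # containment does not.
  n_contained <- vapply(seq_len(ne), function(k) {
    opp <- afferent[afferent$state != efferent$state[k], , drop = FALSE]
    sum(opp$start >= efferent$start[k] - 1e-12 &
        opp$end <= efferent$end[k] + 1e-12)
  }, integer(1))
  edge <- seq_len(ne) %in% c(1L, ne)
  tab <- data.frame(state = efferent$state,
                    start = efferent$start, end = efferent$end,
                    matched_afferent_time = ifelse(is.na(match_idx), NA_real_,
                                                   afferent$start[match_idx]),
                    matched_afferent_idx = match_idx,
                    n_trigger = n_trigger, delay = delay,
                    n_contained = n_contained,
                    persistent = n_contained >= 1,
                    edge = edge)
  structure(list(table = tab, efferent = efferent, afferent = afferent),
            class = "transition_assignment")
}

#' @export
print.transition_assignment <- function(x, ...) {
  tb <- x$table[!x$table$edge, ]
  cat(sprintf("transition_assignment: %d efferent states (%d usable), %d persistent\n",
              nrow(x$table), nrow(tb), sum(tb$persistent)))
  invisible(x)
}

#' SPA and SPI rates
#'
#' The SPA rate \eqn{\phi_{SPA}} is the proportion of (non-edge) efferent
#' Up states that outlast an entire afferent Down state, i.e. whose
#' trigger set contains at least one complete afferent Down state;
#' \eqn{\phi_{SPI}} is the symmetric proportion of efferent Down states.
#' The alternate, afferent-side metric counts the proportion of afferent
#' Down (Up) states skipped, i.e. contained entirely within a single
#' efferent Up (Down) interval.
#'
#' @param assignment a [assign_transitions()] result
#' @return list of class `spa_spi_summary` with `phi_spa`, `phi_spi`
#'   (NA and flagged when the corresponding state count is zero),
#'   `skipped_down_frac`, `skipped_up_frac`, `n_up`, `n_down`
#' @export
spa_spi_rates <- function(assignment) {
  stopifnot(inherits(assignment, "transition_assignment"))
  tb <- assignment$table[!assignment$table$edge, ]
  up <- tb[tb$state == "U", ]
  dn <- tb[tb$state == "D", ]
  phi_spa <- if (nrow(up) == 0) NA_real_ else mean(up$persistent)
  phi_spi <- if (nrow(dn) == 0) NA_real_ else mean(dn$persistent)
  aff <- assignment$afferent
  eff <- assignment$efferent
  skipped <- function(aff_state, eff_state) {
    a <- aff[aff$state == aff_state, ]
    e <- eff[eff$state == eff_state, ]
    if (nrow(a) == 0) return(NA_real_)
    cov <- vapply(seq_len(nrow(a)), function(i)
      any(e$start <= a$start[i] & e$end >= a$end[i]), TRUE)
    mean(cov)
  }
  structure(list(phi_spa = phi_spa, phi_spi = phi_spi,
                 skipped_down_frac = skipped("D", "U"),
                 skipped_up_frac = skipped("U", "D"),
                 n_up = nrow(up), n_down = nrow(dn),
                 flagged_spa = nrow(up) == 0, flagged_spi = nrow(dn) == 0),
            class = "spa_spi_summary")
}

#' @export
print.spa_spi_summary <- function(x, ...) {
  cat(sprintf("SPA rate %.3f (n_up = %d), SPI rate %.3f (n_down = %d)\n",
              x$phi_spa, x$n_up, x$phi_spi, x$n_down))
  cat(sprintf("  skipped afferent Down %.3f, Up %.3f\n",
              x$skipped_down_frac, x$skipped_up_frac))
  invisible(x)
}

#' Quantized and cycle-rescaled state durations
#'
#' Each efferent state's quantized duration counts the afferent states
#' that fit inside it, each contributing half a UDS cycle:
#' `0.5 + n_contained` cycles, so a non-persistent state scores 0.5, an
#' Up state spanning afferent Up-Down-Up (one contained Down) scores
#' 1.5, and all values lie exactly on the half-integer comb. The continuous companion rescales
#' physical time so that each afferent state spans 0.5 cycle units (a
#' piecewise-linear clock), giving real-valued durations that cluster
#' around the half-integers to the extent that efferent transitions lock
#' to afferent transitions.
#'
#' @param assignment a [assign_transitions()] result
#' @return data.frame with `state`, `quantized` (half-integer cycles) and
#'   `rescaled` (continuous cycles), one row per usable efferent state
#' @export
quantized_durations <- function(assignment) {
  stopifnot(inherits(assignment, "transition_assignment"))
  tb <- assignment$table
  keep <- !tb$edge
  aff <- assignment$afferent
  # afferent clock: each afferent state spans 0.5 cycle units
  knots_t <- c(aff$start, aff$end[nrow(aff)])
  knots_c <- 0.5 * (seq_along(knots_t) - 1)
  to_cycles <- function(t) {
    t <- pmin(pmax(t, knots_t[1]), knots_t[length(knots_t)])
    stats::approx(knots_t, knots_c, xout = t)$y
  }
  data.frame(state = tb$state[keep],
             quantized = 0.5 + tb$n_contained[keep],
             rescaled = to_cycles(tb$end[keep]) - to_cycles(tb$start[keep]))
}

#' Transition delays and cross-correlation lag
#'
#' Signed per-transition delays (efferent initiation minus matched
#' afferent initiation, s) split by transition type: Down-to-Up
#' transitions are Up-state initiations, Up-to-Down transitions are
#' Down-state initiations. Optionally, when the two band-limited signals
#' are supplied, the lag of the maximum cross-correlation within a window
#' is reported as a model-free companion measure.
#'
#' @param assignment a [assign_transitions()] result
#' @param efferent_signal,afferent_signal optional numeric vectors (same
#'   sampling rate `fs`), z-scored internally
#' @param fs sampling rate (Hz) of the optional signals
#' @param max_lag cross-correlation search window (s)
#' @return list with `down_up` and `up_down` delay vectors, their means,
#'   and `xcorr_lag` (s, positive = efferent lags afferent; NA when the
#'   signals are not supplied)
#' @export
transition_delays <- function(assignment, efferent_signal = NULL,
                              afferent_signal = NULL, fs = NULL,
                              max_lag = 2) {
  stopifnot(inherits(assignment, "transition_assignment"))
  tb <- assignment$table[!assignment$table$edge, ]
  du <- tb$delay[tb$state == "U"]
  ud <- tb$delay[tb$state == "D"]
  xl <- NA_real_
  if (!is.null(efferent_signal) && !is.null(afferent_signal)) {
    stopifnot(!is.null(fs), length(efferent_signal) == length(afferent_signal))
    x <- scale(afferent_signal)[, 1]
    y <- scale(efferent_signal)[, 1]
    lag_max <- round(max_lag * fs)
    cc <- stats::ccf(y, x, lag.max = lag_max, plot = FALSE)
    # ccf(y, x) at lag k estimates cor(y[t+k], x[t]): an efferent y
    # trailing the afferent x by L samples peaks at k = +L
    xl <- cc$lag[which.max(cc$acf)] / fs
  }
  list(down_up = du, up_down = ud,
       mean_down_up = mean(du, na.rm = TRUE),
       mean_up_down = mean(ud, na.rm = TRUE),
       xcorr_lag = xl)
}

#' History dependence of persistence: p1 and p2
#'
#' Pooled quantized durations are binned on the half-integer comb (bin k
#' collects durations in `[k - 0.5, k + 0.5)` cycles for k = 0.5, 1.5,
#' ...). With `m1` the mass of the first mode and `m2` the second,
#' `p1 = 1 - m1` is the probability of a first persistence event and
#' `p2 = 1 - m2 / p1` the probability of a second given the first. A
#' memoryless (Bernoulli) process has `p1 = p2`; adaptation makes a
#' second consecutive persistence event rarer than the first, `p1 > p2`.
#'
#' @param durations numeric vector of quantized durations (cycles), or
#'   the data.frame from [quantized_durations()] (its `quantized` column
#'   is used)
#' @param min_states minimum number of states required (default 20)
#' @return list of class `history_stats` with `p1`, `p2` (NA and flagged
#'   when `p1` is 0), `mode_masses`, `n`
#' @export
history_probabilities <- function(durations, min_states = 20) {
  if (is.data.frame(durations)) durations <- durations$quantized
  durations <- durations[is.finite(durations)]
  n <- length(durations)
  if (n < min_states)
    stop("need at least ", min_states, " states for history statistics")
  k <- pmax(floor(durations) , 0) # bin index: [k, k+1) holds mode k + 0.5
  kmax <- max(k)
  masses <- tabulate(k + 1L, nbins = kmax + 1L) / n
  names(masses) <- format(seq_len(kmax + 1L) - 0.5)
  p1 <- 1 - masses[[1]]
  flagged <- p1 <= 0
  p2 <- if (flagged) NA_real_ else 1 - (if (length(masses) > 1) masses[[2]] else 0) / p1
  structure(list(p1 = p1, p2 = p2, mode_masses = masses, n = n,
                 flagged = flagged),
            class = "history_stats")
}

#' @export
print.history_stats <- function(x, ...) {
  cat(sprintf("history_stats: p1 = %.3f, p2 = %s (n = %d)\n",
              x$p1, ifelse(is.na(x$p2), "undefined", sprintf("%.3f", x$p2)),
              x$n))
  invisible(x)
}

#' Half-integer comb statistic
#'
#' Fraction of (continuous, cycle-rescaled) duration mass lying within
#' `tol` of a half-integer; a sharply quantized distribution concentrates
#' near 1. Used instead of a named dip test to assess multimodality on
#' the half-integer comb.
#'
#' @param rescaled numeric vector of cycle-unit durations
#' @param tol half-width of the comb teeth (cycles)
#' @export
comb_fraction <- function(rescaled, tol = 0.1) {
  rescaled <- rescaled[is.finite(rescaled)]
  if (!length(rescaled)) return(NA_real_)
  mean(abs((rescaled %% 1) - 0.5) <= tol)
}
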