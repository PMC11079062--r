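#' Alternating Up/Down state sequence
#'
#' A `state_sequence` is a data.frame of contiguous half-open intervals
#' `[start, end)` in seconds with strictly alternating labels `"U"` and
#' `"D"`. It is the common currency of the detection pipeline: both the
#' hysteresis labeller for simulations and the EDHMM decoder for
#' recordings emit it, and all persistence statistics consume it.
#'
#' @param intervals data.frame with columns `start`, `end` (s) and
#'   `state` (`"U"`/`"D"`)
#' @param source provenance tag: `"vm"`, `"lfp"` or `"model"`
#' @return a validated `state_sequence`
#' @export
state_sequence <- function(intervals, source = "model") {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "state") %in% names(intervals)))
  intervals <- intervals[, c("start", "end", "state")]
  intervals$state <- as.character(intervals$state)
  if (!all(intervals$state %in% c("U", "D")))
    stop("states must be 'U' or 'D'")
  if (any(intervals$end <= intervals$start))
    stop("all intervals must have positive duration")
  n <- nrow(intervals)
  if (n > 1) {
    if (any(abs(intervals$start[-1] - intervals$end[-n]) > 1e-9))
      stop("intervals must be contiguous")
    if (any(intervals$state[-1] == intervals$state[-n]))
      stop("labels must strictly alternate")
  }
  class(intervals) <- c("state_sequence", "data.frame")
  attr(intervals, "source") <- source
  intervals
}

#' @export
print.state_sequence <- function(x, ...) {
  durs <- x$end - x$start
  cat(sprintf("state_sequence (%s): %d states over %.1f s; median Up %.2f s, Down %.2f s\n",
              attr(x, "source") %||% "?", nrow(x), sum(durs),
              stats::median(durs[x$state == "U"]),
              stats::median(durs[x$state == "D"])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Swap Up and Down labels
#'
#' Activity inversion: relabels every `U` as `D` and vice versa. Useful
#' for symmetry checks (SPA statistics of the swapped pair equal SPI
#' statistics of the original).
#' @param seq a `state_sequence`
#' @export
swap_labels <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  seq$state <- ifelse(seq$state == "U", "D", "U")
  state_sequence(seq, source = attr(seq, "source"))
}

#' Per-sequence summaries: duty cycle and UDS frequency
#'
#' Duty cycle is the fraction of covered time spent in the Up state;
#' frequency is the number of full UDS cycles (counted as Down-to-Up
#' transitions) per second.
#'
#' @param seq a `state_sequence`; needs at least 3 full cycles for the
#'   estimates to be meaningful, otherwise they are flagged
#' @return list with `duty_cycle`, `frequency_hz`, `n_cycles`, `flagged`
#' @export
sequence_summaries <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  durs <- seq$end - seq$start
  total <- sum(durs)
  duty <- sum(durs[seq$state == "U"]) / total
  # Down-to-Up transitions = Up states not starting at the boundary
  n_cycles <- sum(seq$state == "U" & seq$start > seq$start[1])
  flagged <- n_cycles < 3
  list(duty_cycle = duty,
       frequency_hz = if (flagged) NA_real_ else n_cycles / total,
       n_cycles = n_cycles, flagged = flagged)
}

#' Read/write state sequences and epoch sets as interval files
#'
#' Three-column tab-separated text, one row per interval, times in
#' seconds, half-open `[start, end)`.
#'
#' @param x a `state_sequence` or `epoch_set`
#' @param path file path
#' @export
write_intervals <- function(x, path) {
  df <- as.data.frame(x)
  names(df)[3] <- "label"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @param kind `"states"` or `"epochs"`
#' @param source passed to the constructor for `kind = "states"`
#' @export
read_intervals <- function(path, kind = c("states", "epochs"),
                           source = "model") {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[3] <- if (kind == "states") "state" else "label"
  if (kind == "states") state_sequence(df, source = source)
  else epoch_set(df)
}
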