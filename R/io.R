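#' Read and write recordings
#'
#' A recording persists as a two-column CSV (`time`, `value`) next to a
#' JSON sidecar `<path>.json` holding the sampling rate, channel role
#' and any ground truth; the round trip is lossless.
#'
#' @param rec a [recording()]
#' @param path CSV file path (sidecar written at `paste0(path, ".json")`)
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$signal)
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs, value = rec$signal)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = rec$fs, role = rec$role)
  if (!is.null(rec$truth)) {
    tr <- rec$truth
    meta$truth <- list(
      w_ext = tr$w_ext, w_int = tr$w_int, spikes = tr$spikes,
      states = if (!is.null(tr$states)) as.data.frame(tr$states),
      states_source = if (!is.null(tr$states)) attr(tr$states, "source"),
      desync = if (!is.null(tr$desync)) as.data.frame(tr$desync))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @return `read_recording` returns the restored [recording()]
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks the sampling rate (fs)")
  if (is.null(meta$role) || !meta$role %in% c("vm", "lfp"))
    stop("sidecar lacks a valid channel role (vm/lfp)")
  df <- utils::read.csv(path)
  if (any(!is.finite(df$value)))
    stop("non-finite sample at index ", which(!is.finite(df$value))[1])
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- meta$truth
    if (!is.null(truth$states) && length(truth$states))
      truth$states <- state_sequence(as.data.frame(truth$states),
                                     source = truth$states_source %||% meta$role)
    if (!is.null(truth$desync) && length(truth$desync))
      truth$desync <- epoch_set(as.data.frame(truth$desync))
  }
  recording(df$value, meta$fs, meta$role, truth = truth)
}

#' Analyze one paired V_m/LFP recording
#'
#' The single-cell core of the pipeline: spike removal (V_m), mains
#' notching, desynchronized-epoch rejection (from the LFP),
#' explicit-duration HMM segmentation of both channels, transition
#' assignment, and the persistence/delay/history statistics.
#'
#' @param vm,lfp paired [recording()]s of equal duration
#' @param detect_desync run the desynchronization detector (default TRUE)
#' @param edhmm_cfg overrides for `edhmm_config()`
#' @return list with `summary` ([spa_spi_rates()]), `delays`,
#'   `durations`, `history` (or NULL if too few states), `vm_seq`,
#'   `lfp_seq`, `epochs`, `spikes`
#' @export
analyze_pair <- function(vm, lfp, detect_desync = TRUE,
                         edhmm_cfg = list()) {
  stopifnot(inherits(vm, "recording"), vm$role == "vm",
            inherits(lfp, "recording"), lfp$role == "lfp")
  if (abs(rec_duration(vm) - rec_duration(lfp)) > 0.5)
    stop("V_m and LFP durations differ; refusing to analyze")
  sp <- remove_spikes(vm)
  vm_clean <- notch_mains(sp$recording)
  lfp_clean <- notch_mains(lfp)
  epochs <- NULL
  if (detect_desync) epochs <- find_desynchronized(lfp_clean)$epochs
  cfg <- do.call(edhmm_config, edhmm_cfg)
  vm_model <- fit_edhmm(vm_clean, epochs, cfg)
  lfp_model <- fit_edhmm(lfp_clean, epochs, cfg)
  vm_seq <- viterbi_decode(vm_model, vm_clean, epochs)
  lfp_seq <- viterbi_decode(lfp_model, lfp_clean, epochs)
  vm_segs <- if (inherits(vm_seq, "state_sequence_list")) vm_seq else list(vm_seq)
  lfp_segs <- if (inherits(lfp_seq, "state_sequence_list")) lfp_seq else list(lfp_seq)
  stopifnot(length(vm_segs) == length(lfp_segs))
  asgs <- Map(assign_transitions, vm_segs, lfp_segs)
  pooled <- pool_pair_stats(asgs)
  list(summary = pooled$summary, delays = pooled$delays,
       durations = pooled$durations, history = pooled$history,
       vm_seq = vm_seq, lfp_seq = lfp_seq,
       epochs = epochs, spikes = sp$spikes, assignment = asgs)
}

longest_seq <- function(x) {
  if (inherits(x, "state_sequence_list"))
    x[[which.max(vapply(x, function(s) sum(s$end - s$start), numeric(1)))]]
  else x
}

# pool per-segment transition assignments of one cell into one set of
# summary statistics (rates weighted by state counts, delays and
# durations concatenated)
pool_pair_stats <- function(asgs) {
  summs <- lapply(asgs, spa_spi_rates)
  durs <- do.call(rbind, lapply(asgs, quantized_durations))
  n_up <- sum(vapply(summs, `[[`, numeric(1), "n_up"))
  n_down <- sum(vapply(summs, `[[`, numeric(1), "n_down"))
  wmean <- function(field, w_field) {
    v <- vapply(summs, `[[`, numeric(1), field)
    w <- vapply(summs, `[[`, numeric(1), w_field)
    ok <- is.finite(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  summary <- structure(list(
    phi_spa = wmean("phi_spa", "n_up"),
    phi_spi = wmean("phi_spi", "n_down"),
    skipped_down_frac = wmean("skipped_down_frac", "n_down"),
    skipped_up_frac = wmean("skipped_up_frac", "n_up"),
    n_up = n_up, n_down = n_down,
    flagged_spa = n_up == 0, flagged_spi = n_down == 0),
    class = "spa_spi_summary")
  du <- unlist(lapply(asgs, function(a)
    transition_delays(a)$down_up))
  ud <- unlist(lapply(asgs, function(a)
    transition_delays(a)$up_down))
  delays <- list(down_up = du, up_down = ud,
                 mean_down_up = mean(du, na.rm = TRUE),
                 mean_up_down = mean(ud, na.rm = TRUE),
                 xcorr_lag = NA_real_)
  history <- tryCatch(history_probabilities(durs), error = function(e) NULL)
  list(summary = summary, delays = delays, durations = durs,
       history = history)
}

#' Run the full surrogate-to-connectivity pipeline
#'
#' Generates (or loads) a set of paired recordings, analyzes each, fits
#' every cell against a simulation grid library, and returns a tidy
#' per-cell table plus a manifest sufficient to reproduce the run.
#'
#' @param config nested list (or path to a YAML/JSON file) with blocks:
#'   `cells` — list of `c(w_ext, w_int)` ground-truth pairs (surrogates
#'   are generated) or a list of `(vm=, lfp=)` file paths; `duration` —
#'   seconds per surrogate; `seed` — root seed; `render` — overrides for
#'   [render_config()]; `grid` — overrides for [build_grid_library()];
#'   `detect_desync` — logical; `edhmm` — overrides for the detector.
#' @param library optional pre-built [build_grid_library()] result (the
#'   grid block is ignored if given)
#' @param progress print stage messages
#' @return list with `table` (one row per cell), `fits`, `analyses`,
#'   `library`, `manifest`
#' @export
run_pipeline <- function(config, library = NULL, progress = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$cells))
  seed <- config$seed %||% 1
  duration <- config$duration %||% 300
  rcfg <- do.call(render_config, config$render %||% list())
  cells <- config$cells
  from_files <- is.list(cells[[1]]) && !is.null(cells[[1]]$vm)
  if (from_files) {
    data <- lapply(cells, function(cl)
      list(vm = read_recording(cl$vm), lfp = read_recording(cl$lfp),
           w_ext = NA, w_int = NA))
  } else {
    data <- make_cell_dataset(cells, duration = duration, cfg = rcfg,
                              seeds = seed * 1000L + seq_along(cells))
  }
  if (is.null(library)) {
    gargs <- config$grid %||% list()
    gargs$seed0 <- gargs$seed0 %||% seed
    library <- do.call(build_grid_library, gargs)
  }
  analyses <- list(); fits <- list(); rows <- list()
  for (i in seq_along(data)) {
    if (progress) message("analyzing cell ", i, "/", length(data))
    an <- analyze_pair(data[[i]]$vm, data[[i]]$lfp,
                       detect_desync = config$detect_desync %||% FALSE,
                       edhmm_cfg = config$edhmm %||% list())
    ft <- fit_cell(an$summary, library, cell_id = i)
    pd <- predict_delays(ft, library,
                         observed = list(down_up = an$delays$mean_down_up,
                                         up_down = an$delays$mean_up_down))
    analyses[[i]] <- an; fits[[i]] <- ft
    rows[[i]] <- data.frame(
      cell = i,
      truth_w_ext = data[[i]]$w_ext, truth_w_int = data[[i]]$w_int,
      phi_spa = an$summary$phi_spa, phi_spi = an$summary$phi_spi,
      fit_w_ext = ft$w_ext, fit_w_int = ft$w_int, distance = ft$distance,
      du_delay = an$delays$mean_down_up, ud_delay = an$delays$mean_up_down,
      pred_du_delay = pd$pred_down_up, pred_ud_delay = pd$pred_up_down,
      p1 = if (!is.null(an$history)) an$history$p1 else NA_real_,
      p2 = if (!is.null(an$history)) an$history$p2 else NA_real_,
      duty = sequence_summaries(longest_seq(an$vm_seq))$duty_cycle,
      uds_freq = sequence_summaries(longest_seq(an$lfp_seq))$frequency_hz,
      n_up = an$summary$n_up, n_down = an$summary$n_down,
      coverage_warning = ft$coverage_warning)
  }
  table <- do.call(rbind, rows)
  manifest <- list(package_version = as.character(utils::packageVersion("udsnet")),
                   seed = seed, n_cells = length(data),
                   config = config,
                   coverage_warnings = which(table$coverage_warning))
  list(table = table, fits = fits, analyses = analyses,
       library = library, manifest = manifest)
}

#' Write pipeline results
#'
#' Emits the per-cell table as TSV and the manifest as JSON.
#'
#' @param result a [run_pipeline()] result
#' @param dir output directory
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$table, file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
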