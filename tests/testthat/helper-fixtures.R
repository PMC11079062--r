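# Shared, lazily built fixtures. The grid library and the surrogate-cell
# cohort are expensive (minutes), are used by several acceptance checks,
# and are therefore built once per test run and cached in this
# environment.
.fixtures <- new.env(parent = emptyenv())

# Desk-scale grid library: 12 x 12 points, 3 seeds x 200 s each.
get_test_library <- function() {
  if (is.null(.fixtures$library)) {
    .fixtures$library <- build_grid_library(
      w_ext_values = seq(0.18, 0.30, length.out = 12),
      w_int_values = seq(1.00, 1.12, length.out = 12),
      n_seeds = 3, duration = 200, seed0 = 20240601)
  }
  .fixtures$library
}

# Cohort of surrogate cells with ground truth on the library grid,
# analyzed by the full detection pipeline.
get_test_cells <- function(n = 20, duration = 480) {
  key <- paste0("cells_", n)
  if (is.null(.fixtures[[key]])) {
    lib <- get_test_library()
    # deterministic spread over the lattice: every w_int column visited,
    # w_ext rows restricted to the lower 2/3 where both rates move
    wi_idx <- rep(seq(1, 12), length.out = n)
    we_idx <- rep(c(2, 4, 6, 8), length.out = n)
    truths <- lapply(seq_len(n), function(i)
      c(lib$w_ext_values[we_idx[i]], lib$w_int_values[wi_idx[i]]))
    ds <- make_cell_dataset(truths, duration = duration,
                            seeds = 7000L + seq_len(n))
    analyses <- lapply(ds, function(cell)
      suppressWarnings(analyze_pair(cell$vm, cell$lfp,
                                    detect_desync = FALSE)))
    .fixtures[[key]] <- list(data = ds, analyses = analyses,
                             truths = truths)
  }
  .fixtures[[key]]
}

# per-sample label lookup for accuracy checks
label_at <- function(sq, t) {
  if (inherits(sq, "state_sequence_list"))
    sq <- sq[[which.max(vapply(sq, function(s) sum(s$end - s$start),
                               numeric(1)))]]
  i <- findInterval(t, sq$start)
  out <- rep(NA_character_, length(t))
  ok <- i >= 1 & t < max(sq$end)
  out[ok] <- sq$state[i[ok]]
  out
}

# quick toy state sequence from interval triples
make_seq <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  state_sequence(data.frame(start = as.numeric(m[, 1]),
                            end = as.numeric(m[, 2]),
                            state = m[, 3]))
}
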