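test_that("identical sequences map one-to-one with zero delays", {
  s <- make_seq(0, 1, "D", 1, 2, "U", 2, 3, "D", 3, 4, "U", 4, 5, "D")
  a <- assign_transitions(s, s)
  tb <- a$table[!a$table$edge, ]
  expect_true(all(tb$delay == 0))
  expect_true(all(tb$n_trigger == 1))
  r <- spa_spi_rates(a)
  expect_equal(r$phi_spa, 0)
  expect_equal(r$phi_spi, 0)
})

test_that("a uniform shift appears as a constant signed delay", {
  aff <- make_seq(0, 1, "D", 1, 2, "U", 2, 3, "D", 3, 4, "U", 4, 5, "D",
                  5, 6, "U", 6, 7, "D")
  eff <- aff
  eff$start <- eff$start + 0.1
  eff$end <- eff$end + 0.1
  eff <- state_sequence(eff)
  a <- assign_transitions(eff, aff)
  tb <- a$table[!a$table$edge, ]
  expect_true(all(abs(tb$delay - 0.1) < 1e-12))
  d <- transition_delays(a)
  expect_equal(d$mean_down_up, 0.1, tolerance = 1e-12)
  expect_equal(d$mean_up_down, 0.1, tolerance = 1e-12)
  expect_error(assign_transitions(eff[0, ], aff), "empty")
})

test_that("cross-correlation recovers the lag of a shifted copy", {
  fs <- 100
  set.seed(51)
  x <- as.numeric(stats::filter(rnorm(3000), rep(1, 30) / 30,
                                circular = TRUE))
  y <- c(rep(0, 10), x[1:2990])  # y lags x by 100 ms
  aff <- make_seq(0, 1, "D", 1, 2, "U", 2, 3, "D", 3, 4, "U", 4, 5, "D")
  eff <- aff; eff$start <- eff$start + 0.1; eff$end <- eff$end + 0.1
  a <- assign_transitions(state_sequence(eff), aff)
  d <- transition_delays(a, efferent_signal = y, afferent_signal = x,
                         fs = fs)
  expect_equal(d$xcorr_lag, 0.1, tolerance = 1e-6)
})

test_that("an Up state spanning afferent Up-Down-Up is persistent and scores 1.5", {
  aff <- make_seq(0, 1, "D", 1, 2, "U", 2, 3, "D", 3, 4, "U",
                  4, 5, "D", 5, 6, "U", 6, 7, "D")
  # efferent Up from 1 to 4.1 covers afferent U(1-2), D(2-3), U(3-4)
  eff <- make_seq(0, 1, "D", 1, 4.1, "U", 4.1, 5, "D", 5, 6, "U",
                  6, 7, "D")
  a <- assign_transitions(eff, aff)
  up_row <- a$table[a$table$state == "U" & !a$table$edge, ][1, ]
  expect_equal(up_row$n_trigger, 3)
  expect_true(up_row$persistent)
  q <- quantized_durations(a)
  expect_equal(q$quantized[q$state == "U"][1], 1.5)
  r <- spa_spi_rates(a)
  expect_equal(r$phi_spa, 0.5)  # one persistent of two usable Up states
  expect_equal(r$skipped_down_frac, 1 / 4)
})

test_that("quantized durations live exactly on the half-integer comb", {
  lib_cells <- make_cell_dataset(list(c(0.22, 1.08)), duration = 150,
                                 seeds = 61)
  a <- assign_transitions(lib_cells[[1]]$vm$truth$states,
                          lib_cells[[1]]$lfp$truth$states)
  q <- quantized_durations(a)
  expect_true(all(q$quantized >= 0.5))
  expect_true(all(abs(q$quantized * 2 - round(q$quantized * 2)) < 1e-12))
  # rescaled (continuous) durations agree with quantized within half a cycle
  expect_lt(max(abs(q$rescaled - q$quantized)), 0.75)
})

test_that("rate bookkeeping matches hand counts and flags empty classes", {
  # 4 usable efferent Up states, exactly one persistent
  aff <- make_seq(0, 1, "D", 1, 2, "U", 2, 3, "D", 3, 4, "U", 4, 5, "D",
                  5, 6, "U", 6, 7, "D", 7, 8, "U", 8, 9, "D", 9, 10, "U",
                  10, 11, "D")
  eff <- make_seq(0, 1, "D", 1, 4.1, "U", 4.1, 5, "D", 5, 6, "U",
                  6, 7, "D", 7, 8, "U", 8, 9, "D", 9, 10, "U", 10, 11, "D")
  r <- spa_spi_rates(assign_transitions(eff, aff))
  expect_equal(r$phi_spa, 0.25)
  # all-Up efferent: no usable Down states -> SPI undefined and flagged
  eff_up <- make_seq(0, 11, "U")
  r2 <- spa_spi_rates(assign_transitions(eff_up, aff))
  expect_true(r2$flagged_spi)
  expect_true(is.na(r2$phi_spi))
})

test_that("phi_SPA equals the fraction of quantized Up durations >= 1.5", {
  ds <- make_cell_dataset(list(c(0.21, 1.09)), duration = 200, seeds = 62)
  a <- assign_transitions(ds[[1]]$vm$truth$states,
                          ds[[1]]$lfp$truth$states)
  r <- spa_spi_rates(a)
  q <- quantized_durations(a)
  expect_equal(r$phi_spa, mean(q$quantized[q$state == "U"] >= 1.5))
  expect_equal(r$phi_spi, mean(q$quantized[q$state == "D"] >= 1.5))
})

test_that("swapping Up/Down labels in both sequences swaps SPA and SPI", {
  ds <- make_cell_dataset(list(c(0.20, 1.06)), duration = 200, seeds = 63)
  eff <- ds[[1]]$vm$truth$states
  aff <- ds[[1]]$lfp$truth$states
  r <- spa_spi_rates(assign_transitions(eff, aff))
  r_sw <- spa_spi_rates(assign_transitions(swap_labels(eff),
                                           swap_labels(aff)))
  expect_equal(r_sw$phi_spa, r$phi_spi)
  expect_equal(r_sw$phi_spi, r$phi_spa)
  expect_equal(r_sw$skipped_down_frac, r$skipped_up_frac)
})

test_that("history probabilities reproduce the mode-mass arithmetic", {
  # masses (0.8, 0.15, 0.05) over modes 0.5, 1.5, 2.5
  q <- rep(c(0.5, 1.5, 2.5), times = c(80, 15, 5))
  h <- history_probabilities(q)
  expect_equal(h$p1, 0.2)
  expect_equal(h$p2, 0.25)
  expect_equal(unname(h$mode_masses), c(0.8, 0.15, 0.05))
  expect_error(history_probabilities(rep(0.5, 5)), "at least")
  h0 <- history_probabilities(rep(0.5, 30))
  expect_true(h0$flagged)
  expect_true(is.na(h0$p2))
})

test_that("a memoryless construction yields p1 = p2", {
  set.seed(52)
  p <- 0.3
  n_extra <- rgeom(1000, 1 - p)   # extra cycles beyond the first
  q <- 0.5 + n_extra
  h <- history_probabilities(q)
  expect_lt(abs(h$p1 - p), 0.05)
  expect_lt(abs(h$p2 - p), 0.05)
})

test_that("duty cycle and UDS frequency follow their definitions", {
  s <- make_seq(0, 1, "U", 1, 2, "D", 2, 3, "U", 3, 4, "D", 4, 5, "U",
                5, 6, "D", 6, 7, "U", 7, 8, "D")
  sm <- sequence_summaries(s)
  expect_equal(sm$duty_cycle, 0.5)
  expect_equal(sm$frequency_hz, 3 / 8)  # 3 Down-to-Up transitions in 8 s
  all_up <- make_seq(0, 10, "U")
  sm2 <- sequence_summaries(all_up)
  expect_equal(sm2$duty_cycle, 1)
  expect_true(sm2$flagged)
  # simulated sequence lands in a physiological duty range
  tr <- simulate_network(sim_params(), 150, seed = 64)
  sm3 <- sequence_summaries(binarize_states(tr))
  expect_gt(sm3$duty_cycle, 0.2)
  expect_lt(sm3$duty_cycle, 0.8)
})

test_that("interval files round-trip state sequences and epoch sets", {
  s <- make_seq(0, 1.5, "D", 1.5, 3.25, "U", 3.25, 4, "D")
  f <- tempfile(fileext = ".tsv")
  write_intervals(s, f)
  s2 <- read_intervals(f, "states")
  expect_equal(as.data.frame(s2), as.data.frame(s))
  e <- epoch_set(data.frame(start = c(0, 50), end = c(10, 60),
                            label = "desynchronized"))
  write_intervals(e, f)
  e2 <- read_intervals(f, "epochs")
  expect_equal(e2$start, e$start)
  unlink(f)
  expect_error(state_sequence(data.frame(start = 0, end = 1, state = "X")),
               "must be")
  expect_error(make_seq(0, 1, "U", 1, 2, "U"), "alternate")
  expect_error(make_seq(0, 1, "U", 1.5, 2, "D"), "contiguous")
})
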