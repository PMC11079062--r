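make_vm <- function(x, fs = 2000) recording(x, fs, "vm")

test_that("inserted spikes are detected and removed below 1 mV residual", {
  set.seed(31)
  fs <- 2000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  base <- -70 + 5 * sin(2 * pi * 0.7 * t) + rnorm(length(t), 0, 0.15)
  spike_times <- sort(runif(50, 1, 59))
  x <- base
  half <- fs * 0.0005
  wave <- 40 * (1 - abs(seq(-half, half)) / half)
  for (s in spike_times) {
    i0 <- round(s * fs) + 1
    idx <- (i0 - half):(i0 + half)
    x[idx] <- x[idx] + wave
  }
  out <- suppressWarnings(remove_spikes(make_vm(x, fs)))
  # every inserted spike has a detection within 2 ms
  hits <- vapply(spike_times,
                 function(s) any(abs(out$spikes - s) < 0.002), logical(1))
  expect_true(all(hits))
  expect_lt(max(abs(out$recording$signal - base)), 1)
})

test_that("spike removal is idempotent and a no-op on clean traces", {
  set.seed(32)
  x <- -70 + 4 * sin(2 * pi * 0.5 * seq(0, 30, by = 5e-4)) +
    rnorm(60001, 0, 0.15)
  r1 <- suppressWarnings(remove_spikes(make_vm(x)))
  expect_length(r1$spikes, 0)
  expect_equal(r1$recording$signal, x)
  expect_error(remove_spikes(make_vm(x, fs = 500)), "1 kHz")
})

test_that("near-coincident spikes merge into one interpolation window", {
  fs <- 2000
  x <- rep(-70, 10 * fs)
  # two spikes 1 ms apart
  for (s in c(5.000, 5.001)) {
    i0 <- round(s * fs) + 1
    x[i0 + 0:1] <- x[i0 + 0:1] + c(40, 20)
  }
  out <- suppressWarnings(remove_spikes(make_vm(x, fs)))
  expect_gte(length(out$spikes), 1)
  # everything flattened back to baseline by one merged window
  expect_lt(max(abs(out$recording$signal - (-70))), 1e-6)
})

test_that("mains notching removes 50 Hz, passes 10 Hz, preserves DC", {
  fs <- 2000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mid <- seq_along(t) > 2 * fs & seq_along(t) < 18 * fs
  rms <- function(x) sqrt(mean(x[mid]^2))
  s50 <- notch_mains(recording(sin(2 * pi * 50 * t), fs, "lfp"))
  expect_lt(20 * log10(rms(s50$signal) / rms(sin(2 * pi * 50 * t))), -40)
  s10 <- notch_mains(recording(sin(2 * pi * 10 * t), fs, "lfp"))
  expect_lt(abs(20 * log10(rms(s10$signal) / rms(sin(2 * pi * 10 * t)))), 1)
  dc <- notch_mains(recording(rep(3, length(t)), fs, "lfp"))
  expect_lt(max(abs(dc$signal[mid] - 3)), 1e-4)
})

test_that("notch bank skips bands above Nyquist with a warning", {
  x <- rnorm(30 * 610)
  expect_warning(notch_mains(recording(x, 610, "lfp")), "Nyquist")
})

test_that("the UDS band filter passes 1 Hz, rejects 10 Hz, is zero-phase", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq_along(t) > 10 * fs & seq_along(t) < 110 * fs  # skip edges
  p1 <- uds_band_filter(recording(sin(2 * pi * 1 * t), fs, "lfp"))
  expect_lt(abs(20 * log10(rms(p1$signal[mid]) / rms(sin(2 * pi * t)[mid]))), 1)
  p10 <- uds_band_filter(recording(sin(2 * pi * 10 * t), fs, "lfp"))
  expect_lt(20 * log10(rms(p10$signal[mid]) / rms(sin(2 * pi * 10 * t)[mid])), -20)
  z <- uds_band_filter(recording(rep(0, length(t)), fs, "lfp"))
  expect_equal(z$signal, rep(0, length(t)))
  # zero phase: filtering the reversed signal equals reversing the filtered
  set.seed(33)
  x <- rnorm(length(t))
  a <- uds_band_filter(recording(x, fs, "lfp"))$signal
  b <- rev(uds_band_filter(recording(rev(x), fs, "lfp"))$signal)
  expect_equal(a, b, tolerance = 1e-10)
  expect_error(uds_band_filter(recording(rnorm(100), 500, "lfp")), "60 s")
})

test_that("desynchronization detector: clean, inserted-epoch and degenerate cases", {
  ds <- make_cell_dataset(list(c(0.25, 1.04)), duration = 240, seeds = 51)
  clean <- find_desynchronized(ds[[1]]$lfp)
  expect_equal(nrow(clean$epochs), 0)

  ds2 <- make_cell_dataset(list(c(0.25, 1.04)), duration = 240, seeds = 52,
                           desync = c(90, 150))
  det <- find_desynchronized(ds2[[1]]$lfp)
  expect_equal(nrow(det$epochs), 1)
  ov <- min(det$epochs$end[1], 150) - max(det$epochs$start[1], 90)
  expect_gte(ov / 60, 0.8)
  # intervals disjoint and sorted by construction of epoch_set
  expect_true(all(diff(det$epochs$start) > 0))

  set.seed(34)
  pink <- recording(udsnet:::pink_noise(240 * 1000, 1000), 1000, "lfp")
  allf <- find_desynchronized(pink)
  expect_gte(sum(allf$epochs$end - allf$epochs$start), 0.95 * 240)
  expect_error(find_desynchronized(recording(rnorm(1000), 100, "lfp")),
               "two windows")
})

test_that("synchronized_epochs complements a desynchronized set", {
  de <- epoch_set(data.frame(start = c(30, 100), end = c(60, 120),
                             label = "desynchronized"))
  sy <- synchronized_epochs(de, 200)
  expect_equal(sy$start, c(0, 60, 120))
  expect_equal(sy$end, c(30, 100, 200))
  expect_equal(nrow(synchronized_epochs(epoch_set(
    data.frame(start = numeric(0), end = numeric(0),
               label = character(0))), 50)), 1)
})
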