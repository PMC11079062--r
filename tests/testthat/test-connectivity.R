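# a tiny synthetic library for structural tests (no simulation)
toy_library <- function() {
  grid <- expand.grid(w_ext = c(0.2, 0.25, 0.3), w_int = c(1.0, 1.05, 1.1))
  st <- data.frame(grid,
                   xi_spa = c(0.05, 0.04, 0.03, 0.15, 0.12, 0.10,
                              0.40, 0.35, 0.30),
                   xi_spi = c(0.20, 0.05, 0.01, 0.22, 0.06, 0.012,
                              0.25, 0.07, 0.015))
  st$skipped_down <- st$xi_spa * 0.9
  st$skipped_up <- st$xi_spi * 0.9
  st$du_delay <- 0.4 - st$w_ext
  st$ud_delay <- st$w_int - 0.7
  st$n_up <- 100; st$n_down <- 100; st$comb_frac <- 0.5
  structure(list(stats = st, per_seed = st, qdur = list(),
                 w_ext_values = c(0.2, 0.25, 0.3),
                 w_int_values = c(1.0, 1.05, 1.1),
                 n_seeds = 1, duration = 100, dt = 0.2, seed0 = 1,
                 params = sim_params()),
            class = "grid_library")
}

test_that("the rate distance is a metric on rate pairs", {
  set.seed(71)
  for (i in 1:50) {
    x <- runif(2); y <- runif(2); z <- runif(2)
    expect_equal(rate_distance(x, x), 0)
    expect_equal(rate_distance(x, y), rate_distance(y, x))
    expect_lte(rate_distance(x, z),
               rate_distance(x, y) + rate_distance(y, z) + 1e-12)
  }
  expect_equal(rate_distance(c(0.2, 0), c(0.17, 0.04)), 0.05)
})

test_that("fitting a library entry's own rates returns that entry with d = 0", {
  lib <- toy_library()
  for (i in c(1, 5, 9)) {
    obs <- list(phi_spa = lib$stats$xi_spa[i], phi_spi = lib$stats$xi_spi[i],
                skipped_down_frac = NA, skipped_up_frac = NA)
    ft <- fit_cell(obs, lib)
    expect_equal(ft$w_ext, lib$stats$w_ext[i])
    expect_equal(ft$w_int, lib$stats$w_int[i])
    expect_equal(ft$distance, 0)
  }
})

test_that("ties break toward smaller w_int then smaller w_ext", {
  lib <- toy_library()
  lib$stats$xi_spa <- rep(0.1, 9)
  lib$stats$xi_spi <- rep(0.1, 9)
  ft <- fit_cell(list(phi_spa = 0.1, phi_spi = 0.1,
                      skipped_down_frac = NA, skipped_up_frac = NA), lib)
  expect_equal(ft$w_int, 1.0)
  expect_equal(ft$w_ext, 0.2)
})

test_that("observations outside the library coverage raise a warning", {
  lib <- toy_library()
  expect_warning(fit_cell(list(phi_spa = 0.9, phi_spi = 0.9,
                               skipped_down_frac = NA,
                               skipped_up_frac = NA), lib),
                 "coverage")
  lib$stats <- lib$stats[0, ]
  expect_error(fit_cell(list(phi_spa = 0.1, phi_spi = 0.1), lib), "empty")
})

test_that("exponential_trend recovers an exact exponential and flags constants", {
  x <- seq(0, 0.1, length.out = 20)
  st <- data.frame(w_int = x, xi_spa = exp(x / 0.01), xi_spi = 1)
  tr <- exponential_trend(st, "w_int", "spa")
  expect_equal(tr$efold, 0.01, tolerance = 1e-10)
  expect_equal(tr$spearman_r, 1)
  flat <- exponential_trend(st, "w_int", "spi")
  expect_lt(abs(flat$slope), 1e-10)
  st0 <- data.frame(w_ext = x, xi_spi = 0 * x)
  expect_true(exponential_trend(st0, "w_ext", "spi")$flagged)
})

test_that("predicted delays read from the matched entry; residuals subtract", {
  lib <- toy_library()
  obs <- list(phi_spa = lib$stats$xi_spa[4], phi_spi = lib$stats$xi_spi[4],
              skipped_down_frac = NA, skipped_up_frac = NA)
  ft <- fit_cell(obs, lib)
  pd <- predict_delays(ft, lib)
  expect_equal(pd$pred_down_up, lib$stats$du_delay[ft$grid_index])
  pd2 <- predict_delays(ft, lib,
                        observed = list(down_up = pd$pred_down_up,
                                        up_down = pd$pred_up_down))
  expect_equal(pd2$resid_down_up, 0)
  expect_equal(pd2$resid_up_down, 0)
})

test_that("group comparison calibrates under the null and flags tiny groups", {
  set.seed(72)
  mk_fit <- function(w_int, w_ext) {
    structure(list(cell_id = NA, phi_spa = runif(1), phi_spi = runif(1),
                   w_int = w_int, w_ext = w_ext, distance = 0,
                   grid_index = 1, coverage_warning = FALSE),
              class = "fit_result")
  }
  # identical truth: p-values uniform, so > 0.05 in most repetitions
  null_p <- replicate(20, {
    fits <- lapply(1:12, function(i) mk_fit(rnorm(1, 1.05, 0.02),
                                            rnorm(1, 0.25, 0.02)))
    gc <- group_compare(fits, rep(c("a", "b"), each = 6))
    gc$pairwise$p_value[gc$pairwise$parameter == "w_int"]
  })
  expect_gte(mean(null_p > 0.05), 0.75)
  # separated groups are detected
  fits <- c(lapply(1:8, function(i) mk_fit(rnorm(1, 1.02, 0.005), 0.25)),
            lapply(1:8, function(i) mk_fit(rnorm(1, 1.09, 0.005), 0.25)))
  gc <- group_compare(fits, rep(c("lo", "hi"), each = 8))
  expect_lt(gc$pairwise$p_value[gc$pairwise$parameter == "w_int"], 0.05)
  # single group: empty pairwise table
  gc1 <- group_compare(fits[1:4], rep("only", 4))
  expect_null(gc1$pairwise)
  # tiny group flagged
  gc2 <- group_compare(fits[c(1, 2, 9:14)],
                       c("a", "a", rep("b", 6)))
  expect_true(all(gc2$pairwise$flagged))
})

test_that("a grid library round-trips through its on-disk form", {
  lib <- build_grid_library(w_ext_values = c(0.22, 0.26),
                            w_int_values = c(1.02, 1.08),
                            n_seeds = 1, duration = 60, seed0 = 3)
  expect_equal(nrow(lib$stats), 4)
  expect_equal(nrow(lib$per_seed), 4)
  d <- tempfile()
  save_grid_library(lib, d)
  lib2 <- load_grid_library(d)
  expect_equal(lib2$stats, lib$stats, tolerance = 1e-12)
  expect_equal(lib2$w_ext_values, lib$w_ext_values)
  expect_equal(unclass(lib2$params), unclass(lib$params))
  unlink(d, recursive = TRUE)
})

test_that("library rebuild with the same seed is identical", {
  a <- build_grid_library(w_ext_values = 0.24, w_int_values = c(1.0, 1.1),
                          n_seeds = 1, duration = 60, seed0 = 9)
  b <- build_grid_library(w_ext_values = 0.24, w_int_values = c(1.0, 1.1),
                          n_seeds = 1, duration = 60, seed0 = 9)
  expect_identical(a$stats, b$stats)
})
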