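#' Build the (W_EXT, W_INT) simulation grid library
#'
#' For every point of a rectangular grid over the afferent-to-efferent
#' weight `w_ext` and the efferent recurrent excitation `w_int`, the
#' coupled pair is simulated for `n_seeds` independent noise
#' realizations, both networks are labelled by hysteresis, transitions
#' are assigned, and the per-point persistence statistics (`xi_spa`,
#' `xi_spi`, skipped-state fractions, mean transition delays, quantized
#' duration masses) are averaged over seeds. The afferent trajectory is
#' shared across all grid points of one seed (it does not depend on the
#' efferent), which keeps the library O(grid) rather than O(grid^2).
#'
#' Default bounds place the four qualitative regimes — phase locking,
#' persistent activity, persistent inactivity, and their coexistence —
#' inside the grid: the locking boundary sits where the afferent drive
#' swing `w_ext * E_up` matches the Up-state escape threshold.
#'
#' @param w_ext_values,w_int_values grid axes
#' @param n_seeds independent simulations per point
#' @param duration seconds per simulation
#' @param dt integration step (ms)
#' @param seed0 root seed; everything is deterministic given it
#' @param params base parameter set ([sim_params()] defaults)
#' @param progress print one line per seed
#' @return a `grid_library`: list with `stats` (one row per grid point),
#'   `per_seed` (one row per point x seed), `qdur` (pooled quantized
#'   durations per point), axes, and provenance
#' @export
build_grid_library <- function(w_ext_values = seq(0.18, 0.30, length.out = 12),
                               w_int_values = seq(1.00, 1.12, length.out = 12),
                               n_seeds = 3, duration = 200, dt = 0.2,
                               seed0 = 1, params = sim_params(),
                               progress = FALSE) {
  stopifnot(duration >= 30, n_seeds >= 1)
  grid <- expand.grid(w_ext = w_ext_values, w_int = w_int_values)
  acc <- vector("list", nrow(grid))
  per_seed <- list()
  for (s in seq_len(n_seeds)) {
    aseed <- (seed0 * 97 + s * 131) %% 2000000000
    aff <- simulate_network(params, duration, dt, seed = aseed,
                            keep_full_e = TRUE)
    e_full <- attr(aff, "E_full")
    aff_seq <- binarize_states(aff)
    eseed <- (seed0 * 97 + s * 131 + 55555) %% 2000000000
    for (g in seq_len(nrow(grid))) {
      ep <- update_params(params, w_ee = grid$w_int[g],
                          w_ext = grid$w_ext[g])
      eff <- simulate_network(ep, duration, dt, seed = eseed,
                              drive = grid$w_ext[g] * e_full)
      eff_seq <- binarize_states(eff)
      asg <- assign_transitions(eff_seq, aff_seq)
      r <- spa_spi_rates(asg)
      d <- transition_delays(asg)
      q <- quantized_durations(asg)
      row <- data.frame(seed = s, w_ext = grid$w_ext[g],
                        w_int = grid$w_int[g],
                        xi_spa = r$phi_spa, xi_spi = r$phi_spi,
                        skipped_down = r$skipped_down_frac,
                        skipped_up = r$skipped_up_frac,
                        du_delay = d$mean_down_up,
                        ud_delay = d$mean_up_down,
                        n_up = r$n_up, n_down = r$n_down)
      per_seed[[length(per_seed) + 1]] <- row
      acc[[g]] <- c(acc[[g]], list(list(row = row, q = q)))
    }
    if (progress) message("seed ", s, "/", n_seeds, " done")
  }
  per_seed <- do.call(rbind, per_seed)
  stats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    rows <- do.call(rbind, lapply(acc[[g]], `[[`, "row"))
    qall <- do.call(rbind, lapply(acc[[g]], `[[`, "q"))
    data.frame(w_ext = grid$w_ext[g], w_int = grid$w_int[g],
               xi_spa = mean(rows$xi_spa, na.rm = TRUE),
               xi_spi = mean(rows$xi_spi, na.rm = TRUE),
               skipped_down = mean(rows$skipped_down, na.rm = TRUE),
               skipped_up = mean(rows$skipped_up, na.rm = TRUE),
               du_delay = mean(rows$du_delay, na.rm = TRUE),
               ud_delay = mean(rows$ud_delay, na.rm = TRUE),
               n_up = sum(rows$n_up), n_down = sum(rows$n_down),
               comb_frac = comb_fraction(qall$rescaled))
  }))
  qdur <- lapply(seq_len(nrow(grid)), function(g)
    do.call(rbind, lapply(acc[[g]], `[[`, "q")))
  structure(list(stats = stats, per_seed = per_seed, qdur = qdur,
                 w_ext_values = w_ext_values, w_int_values = w_int_values,
                 n_seeds = n_seeds, duration = duration, dt = dt,
                 seed0 = seed0, params = params),
            class = "grid_library")
}

#' @export
print.grid_library <- function(x, ...) {
  cat(sprintf("grid_library: %d x %d points, %d seeds x %g s (seed0 %d)\n",
              length(x$w_ext_values), length(x$w_int_values),
              x$n_seeds, x$duration, x$seed0))
  cat(sprintf("  xi_spa in [%.3f, %.3f], xi_spi in [%.3f, %.3f]\n",
              min(x$stats$xi_spa), max(x$stats$xi_spa),
              min(x$stats$xi_spi), max(x$stats$xi_spi)))
  invisible(x)
}

#' Persist / restore a grid library
#'
#' The library is written as a directory holding two TSV tables (`stats`,
#' `per_seed`), one TSV of pooled quantized durations, and a JSON
#' manifest with axes, seeds and parameters; `load_grid_library`
#' restores a bit-identical object.
#'
#' @param library a `grid_library`
#' @param path directory to create/read
#' @export
save_grid_library <- function(library, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(library$stats, file.path(path, "stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(library$per_seed, file.path(path, "per_seed.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  qd <- do.call(rbind, lapply(seq_along(library$qdur), function(g) {
    q <- library$qdur[[g]]
    if (is.null(q) || !nrow(q)) return(NULL)
    cbind(point = g, q)
  }))
  utils::write.table(qd, file.path(path, "qdur.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(w_ext_values = library$w_ext_values,
                   w_int_values = library$w_int_values,
                   n_seeds = library$n_seeds, duration = library$duration,
                   dt = library$dt, seed0 = library$seed0,
                   params = unclass(library$params))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_grid_library
#' @export
load_grid_library <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  stats <- utils::read.table(file.path(path, "stats.tsv"), sep = "\t",
                             header = TRUE)
  per_seed <- utils::read.table(file.path(path, "per_seed.tsv"),
                                sep = "\t", header = TRUE)
  qd <- utils::read.table(file.path(path, "qdur.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  npts <- nrow(stats)
  qdur <- lapply(seq_len(npts), function(g) {
    q <- qd[qd$point == g, -1, drop = FALSE]
    rownames(q) <- NULL
    q
  })
  pars <- man$params
  sn <- isTRUE(pars$shared_noise)
  pars$shared_noise <- NULL
  params <- do.call(uds_params, c(pars, list(shared_noise = sn)))
  structure(list(stats = stats, per_seed = per_seed, qdur = qdur,
                 w_ext_values = man$w_ext_values,
                 w_int_values = man$w_int_values,
                 n_seeds = man$n_seeds, duration = man$duration,
                 dt = man$dt, seed0 = man$seed0, params = params),
            class = "grid_library")
}

#' Rate-space distance between an observation and a simulation
#'
#' Euclidean distance between (SPA, SPI) rate pairs,
#' \eqn{d = \sqrt{(\phi_{SPA}-\xi_{SPA})^2 + (\phi_{SPI}-\xi_{SPI})^2}}.
#'
#' @param phi,xi length-2 numeric vectors (SPA, SPI)
#' @export
rate_distance <- function(phi, xi) {
  sqrt(sum((phi - xi)^2))
}

#' Fit a cell's connectivity by exhaustive grid matching
#'
#' Finds the grid point whose simulated persistence rates are closest
#' (in [rate_distance()]) to the observed ones. Ties break toward
#' smaller `w_int`, then smaller `w_ext`. Both the primary metric
#' (efferent-side SPA/SPI proportions) and the alternate metric
#' (afferent-side skipped-state proportions) are fitted; the alternate
#' result is reported in `alt`.
#'
#' @param summary a [spa_spi_rates()] result (or a list with `phi_spa`,
#'   `phi_spi`, and for the alternate metric `skipped_down_frac`,
#'   `skipped_up_frac`)
#' @param library a [build_grid_library()] result
#' @param cell_id optional identifier carried through
#' @return a `fit_result`: observed rates, best `(w_ext, w_int)`,
#'   distance, matched-simulation delays, the alternate fit, and a
#'   boundary-coverage flag
#' @export
fit_cell <- function(summary, library, cell_id = NA) {
  stopifnot(inherits(library, "grid_library"))
  st <- library$stats
  if (!nrow(st)) stop("empty grid library")
  pick <- function(phi, xi_a, xi_b) {
    d <- sqrt((phi[1] - xi_a)^2 + (phi[2] - xi_b)^2)
    ord <- order(d, st$w_int, st$w_ext)
    list(idx = ord[1], d = d[ord[1]])
  }
  phi <- c(summary$phi_spa, summary$phi_spi)
  if (any(!is.finite(phi))) stop("observed rates must be finite to fit")
  main <- pick(phi, st$xi_spa, st$xi_spi)
  alt_phi <- c(summary$skipped_down_frac, summary$skipped_up_frac)
  alt <- if (all(is.finite(alt_phi)))
    pick(alt_phi, st$skipped_down, st$skipped_up) else NULL
  on_boundary <- phi[1] > max(st$xi_spa) || phi[2] > max(st$xi_spi)
  if (on_boundary)
    warning("observed rates outside library coverage; nearest point returned")
  structure(list(cell_id = cell_id,
                 phi_spa = phi[1], phi_spi = phi[2],
                 w_ext = st$w_ext[main$idx], w_int = st$w_int[main$idx],
                 distance = main$d,
                 pred_du_delay = st$du_delay[main$idx],
                 pred_ud_delay = st$ud_delay[main$idx],
                 alt = if (!is.null(alt))
                   list(w_ext = st$w_ext[alt$idx], w_int = st$w_int[alt$idx],
                        distance = alt$d) else NULL,
                 grid_index = main$idx,
                 coverage_warning = isTRUE(on_boundary)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result%s: phi=(%.3f, %.3f) -> (w_ext=%.4f, w_int=%.4f), d=%.4f\n",
              if (is.na(x$cell_id)) "" else paste0(" [", x$cell_id, "]"),
              x$phi_spa, x$phi_spi, x$w_ext, x$w_int, x$distance))
  invisible(x)
}

#' Exponential trend of a persistence rate along a grid axis
#'
#' Least-squares fit of `log(response)` against the predictor over grid
#' points with nonzero response, plus the Spearman rank correlation. The
#' e-folding scale is `1/|slope|`: the predictor change that multiplies
#' the rate by e.
#'
#' @param library a `grid_library` (or a data.frame with the columns
#'   named below)
#' @param predictor `"w_int"` or `"w_ext"`
#' @param response `"spa"` or `"spi"`
#' @return list with `efold`, `slope`, `spearman_r`, `spearman_p`, `n`
#' @export
exponential_trend <- function(library, predictor = c("w_int", "w_ext"),
                              response = c("spa", "spi")) {
  predictor <- match.arg(predictor)
  response <- match.arg(response)
  st <- if (inherits(library, "grid_library")) library$stats else library
  y <- st[[paste0("xi_", response)]]
  x <- st[[predictor]]
  ok <- is.finite(y) & y > 0 & is.finite(x)
  if (sum(ok) < 10) {
    if (all(y[is.finite(y)] == 0))
      return(list(efold = NA_real_, slope = NA_real_,
                  spearman_r = NA_real_, spearman_p = NA_real_,
                  n = 0, flagged = TRUE))
    warning("fewer than 10 nonzero points; trend unreliable")
  }
  fit <- stats::lm(log(y[ok]) ~ x[ok])
  slope <- unname(stats::coef(fit)[2])
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(efold = 1 / abs(slope), slope = slope,
       spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
       n = sum(ok), flagged = FALSE)
}

#' Predicted transition delays from a matched simulation
#'
#' Reads the mean Down-Up and Up-Down delays stored at the fitted grid
#' point and, when observed delays are supplied, the propagation
#' residuals (observed minus predicted), the quantity attributed to
#' conduction/integration outside the model.
#'
#' @param fit a [fit_cell()] result
#' @param library the `grid_library` used for the fit
#' @param observed optional list with `down_up`, `up_down` (s)
#' @return list with predicted delays and (optionally) residuals
#' @export
predict_delays <- function(fit, library, observed = NULL) {
  stopifnot(inherits(fit, "fit_result"), inherits(library, "grid_library"))
  st <- library$stats[fit$grid_index, ]
  out <- list(pred_down_up = st$du_delay, pred_up_down = st$ud_delay)
  if (!is.null(observed)) {
    out$resid_down_up <- observed$down_up - st$du_delay
    out$resid_up_down <- observed$up_down - st$ud_delay
  }
  out
}

#' Compare fitted connectivity between groups of cells
#'
#' Two-sided Wilcoxon rank-sum tests for equal medians of fitted `w_int`
#' and `w_ext` between every pair of groups, plus Spearman correlations
#' of the fitted parameters against observed rates and delays across all
#' cells.
#'
#' @param fits list of [fit_cell()] results
#' @param groups character/factor of group labels, one per fit
#' @param observed optional data.frame with per-cell `du_delay`,
#'   `ud_delay` columns for the correlation block
#' @return list with `pairwise` (data.frame of rank-sum tests) and
#'   `correlations` (data.frame of Spearman tests)
#' @export
group_compare <- function(fits, groups, observed = NULL) {
  stopifnot(length(fits) == length(groups))
  df <- data.frame(group = as.character(groups),
                   w_int = vapply(fits, `[[`, numeric(1), "w_int"),
                   w_ext = vapply(fits, `[[`, numeric(1), "w_ext"),
                   phi_spa = vapply(fits, `[[`, numeric(1), "phi_spa"),
                   phi_spi = vapply(fits, `[[`, numeric(1), "phi_spi"))
  gs <- unique(df$group)
  pairwise <- NULL
  if (length(gs) >= 2) {
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (j <= i) next
      a <- df[df$group == gs[i], ]; b <- df[df$group == gs[j], ]
      flagged <- nrow(a) < 3 || nrow(b) < 3
      for (par in c("w_int", "w_ext")) {
        p <- if (flagged) NA_real_ else
          suppressWarnings(stats::wilcox.test(a[[par]], b[[par]])$p.value)
        pairwise <- rbind(pairwise,
                          data.frame(group1 = gs[i], group2 = gs[j],
                                     parameter = par, p_value = p,
                                     n1 = nrow(a), n2 = nrow(b),
                                     flagged = flagged))
      }
    }
  }
  correlations <- NULL
  vars <- list(c("w_int", "phi_spa"), c("w_ext", "phi_spi"))
  if (!is.null(observed)) {
    df$du_delay <- observed$du_delay
    df$ud_delay <- observed$ud_delay
    vars <- c(vars, list(c("w_ext", "du_delay"), c("w_int", "ud_delay")))
  }
  for (v in vars) {
    ok <- is.finite(df[[v[1]]]) & is.finite(df[[v[2]]])
    if (sum(ok) >= 4) {
      ct <- suppressWarnings(stats::cor.test(df[[v[1]]][ok], df[[v[2]]][ok],
                                             method = "spearman",
                                             exact = FALSE))
      correlations <- rbind(correlations,
                            data.frame(x = v[1], y = v[2],
                                       spearman_r = unname(ct$estimate),
                                       p_value = ct$p.value, n = sum(ok)))
    }
  }
  list(pairwise = pairwise, correlations = correlations, cells = df)
}
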