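## Count prominent local maxima of x(t) restricted to a window.  A point is
## a peak when it exceeds both neighbours and stands out from the lower of
## the two flanking minima by at least `prominence` times the window range.
count_peaks <- function(t, x, window, prominence = 0.05) {
  sel <- t >= window[1] & t <= window[2]
  x <- x[sel]
  n <- length(x)
  if (n < 3) return(0L)
  rng <- max(x) - min(x)
  if (rng <= 0) return(0L)
  peaks <- 0L
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      left <- min(x[1:i])
      right <- min(x[i:n])
      if (x[i] - max(left, right) >= prominence * rng) peaks <- peaks + 1L
    }
  }
  peaks
}

#' Initial-condition ensemble
#'
#' Repeats the reference simulation with the immune baselines
#' `(H0, C0, M0)` drawn uniformly from stated ranges while every rate
#' parameter stays fixed, to probe insensitivity of the disease course to
#' the starting immune state.  The verdict is `TRUE` when every run shares
#' the reference run's long-run mode label and the peak times of the
#' watched variables agree with the reference within one week.
#'
#' @param n number of draws (`>= 1`).
#' @param ranges named list of length-2 ranges for `H0`, `C0`, `M0`
#'   (cells/mm^3).  Defaults span reported wild-type baselines (T cells up
#'   to ~100, macrophages up to ~1000 cells/mm^3).
#' @param seed integer seed for the draws.
#' @param p rate parameters shared by all runs.
#' @param cfg simulation settings (default 50-week horizon so the mode
#'   window is covered).
#' @param mode_window,peak_window windows (weeks) for mode classification
#'   and for peak-time comparison.
#' @param peak_vars variables whose peak times are compared.
#' @return List with `draws` (data frame of sampled baselines, labels and
#'   peak times), `reference` (label and peak times of the reference run),
#'   `verdict` (logical), and `trajectories` (list of `mdx_trajectory`).
#' @export
initial_condition_ensemble <- function(n = 125,
                                       ranges = list(H0 = c(0, 10),
                                                     C0 = c(1, 100),
                                                     M0 = c(100, 1000)),
                                       seed = 1, p = mdx_parameters(),
                                       cfg = simulation_settings(
                                         t_end = 50, output_step = 0.1),
                                       mode_window = c(40, 50),
                                       peak_window = c(0, 12),
                                       peak_vars = c("M", "D")) {
  stopifnot(n >= 1, all(c("H0", "C0", "M0") %in% names(ranges)))
  ref <- simulate_mdx(p, cfg = cfg)
  ref_label <- classify_mode(ref, mode_window)
  ref_peaks <- vapply(peak_vars,
                      function(v) peak_value(ref, v, peak_window)$t_peak,
                      numeric(1))
  set.seed(as.integer(seed))
  draws <- data.frame(H0 = stats::runif(n, ranges$H0[1], ranges$H0[2]),
                      C0 = stats::runif(n, ranges$C0[1], ranges$C0[2]),
                      M0 = stats::runif(n, ranges$M0[1], ranges$M0[2]))
  trajectories <- vector("list", n)
  labels <- character(n)
  pk <- matrix(NA_real_, n, length(peak_vars),
               dimnames = list(NULL, peak_vars))
  for (i in seq_len(n)) {
    pi <- p
    pi$H0 <- draws$H0[i]; pi$C0 <- draws$C0[i]; pi$M0 <- draws$M0[i]
    tr <- simulate_mdx(pi, cfg = cfg)
    trajectories[[i]] <- tr
    labels[i] <- classify_mode(tr, mode_window)
    pk[i, ] <- vapply(peak_vars,
                      function(v) peak_value(tr, v, peak_window)$t_peak,
                      numeric(1))
  }
  draws$label <- labels
  for (v in peak_vars) draws[[paste0("t_peak_", v)]] <- pk[, v]
  verdict <- all(labels == ref_label) &&
    all(abs(sweep(pk, 2, ref_peaks)) <= 1)
  list(draws = draws,
       reference = list(label = ref_label, peak_times = ref_peaks),
       verdict = verdict, trajectories = trajectories)
}

#' Two-level factorial ensemble over the sensitivity ranges
#'
#' Enumerates every combination of the lower and upper bound of each
#' parameter in `ranges` (2^10 = 1024 combinations for the default ten
#' ranges), simulates each to the stated horizon, classifies its long-run
#' mode, and checks the early-phase shape: a single prominent macrophage
#' rise and a single damage peak within the first seven weeks.  Integrator
#' failures are recorded per combination rather than aborting the census.
#'
#' @param ranges named list of length-2 ranges
#'   (default [sensitivity_ranges()]).
#' @param horizon simulation horizon in weeks.
#' @param p template parameters for everything not in `ranges`.
#' @param output_step,rel_tol,abs_tol integration control for the census
#'   (defaults trade accuracy for the 1024-fold workload).
#' @param mode_window window for mode classification.
#' @param early_window window for the qualitative shape check.
#' @return List with `results` (one row per combination: levels, label,
#'   tail mean/amplitude of `N`, early peak counts, `failed`),
#'   `mode_counts` (table), and `n_combinations`.
#' @export
factorial_ensemble <- function(ranges = sensitivity_ranges(), horizon = 50,
                               p = mdx_parameters(), output_step = 0.25,
                               rel_tol = 1e-6, abs_tol = 1e-8,
                               mode_window = c(40, 50),
                               early_window = c(0, 7)) {
  stopifnot(length(ranges) >= 1,
            all(vapply(ranges, length, 0L) == 2L))
  cfg <- simulation_settings(t_end = horizon, output_step = output_step,
                             rel_tol = rel_tol, abs_tol = abs_tol)
  levels <- expand.grid(lapply(ranges, function(r) c(1L, 2L)))
  n <- nrow(levels)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- p
    for (nm in names(ranges)) pi[[nm]] <- ranges[[nm]][levels[i, nm]]
    row <- as.list(vapply(names(ranges),
                          function(nm) ranges[[nm]][levels[i, nm]],
                          numeric(1)))
    tr <- tryCatch(simulate_mdx(pi, cfg = cfg), error = function(e) NULL)
    if (is.null(tr)) {
      row <- c(row, label = NA_character_, tail_mean_N = NA_real_,
               tail_amp_N = NA_real_, peaks_M = NA_integer_,
               peaks_D = NA_integer_, failed = TRUE)
    } else {
      ts <- tail_statistics(tr, mode_window)
      row <- c(row, label = classify_mode(tr, mode_window),
               tail_mean_N = ts["N", "mean"],
               tail_amp_N = ts["N", "amplitude"],
               peaks_M = count_peaks(tr$time, tr$M, early_window),
               peaks_D = count_peaks(tr$time, tr$D, early_window),
               failed = FALSE)
    }
    res[[i]] <- as.data.frame(row)
  }
  results <- do.call(rbind, res)
  list(results = results,
       mode_counts = table(results$label, useNA = "ifany"),
       n_combinations = n)
}

#' One-dimensional parameter sweep
#'
#' Simulates the model over a grid of values of one parameter, all others
#' fixed, and records tail summaries and the mode label per grid point.
#'
#' @param param name of a free parameter (commonly `k1`, `k2`, `k4`, `k5`).
#' @param grid numeric vector of values (non-empty).
#' @param horizon simulation horizon in weeks.
#' @param p template parameters.
#' @param window tail window for the summaries.
#' @param cfg optional simulation settings overriding `horizon`.
#' @return Data frame, one row per grid point: `param`, `value`, per-fiber
#'   tail means (`mean_N`, `mean_D`, `mean_R`), `amp_N` and `label`.
#' @export
sweep_1d <- function(param, grid, horizon = 50, p = mdx_parameters(),
                     window = c(40, 50), cfg = NULL) {
  stopifnot(param %in% FREE_PARAMETERS, length(grid) >= 1)
  if (is.null(cfg))
    cfg <- simulation_settings(t_end = horizon, output_step = 0.1)
  rows <- lapply(grid, function(v) {
    pi <- p
    pi[[param]] <- v
    tr <- simulate_mdx(pi, cfg = cfg)
    ts <- tail_statistics(tr, window)
    data.frame(param = param, value = v,
               mean_N = ts["N", "mean"], mean_D = ts["D", "mean"],
               mean_R = ts["R", "mean"], amp_N = ts["N", "amplitude"],
               label = classify_mode(tr, window))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-parameter asymptotic heat map
#'
#' Simulates every `(k1, k2)`-style grid combination (all other parameters
#' fixed) and records the value of one variable at a stated week — the
#' "asymptotic at week `week`" snapshot used for regime maps.
#'
#' @param grid1,grid2 numeric grids for the two parameters.
#' @param params names of the two varied parameters
#'   (default `c("k1", "k2")`).
#' @param variable state variable to map.
#' @param week week at which the variable is sampled (also the horizon).
#' @param p template parameters.
#' @param output_step,rel_tol,abs_tol integration control.
#' @return Numeric matrix `length(grid1) x length(grid2)` with the grids as
#'   dimnames; attribute `long` holds the long-format data frame.
#' @export
heatmap_2d <- function(grid1, grid2, params = c("k1", "k2"),
                       variable = "N", week = 50, p = mdx_parameters(),
                       output_step = 0.25, rel_tol = 1e-6, abs_tol = 1e-8) {
  stopifnot(length(params) == 2, all(params %in% FREE_PARAMETERS),
            variable %in% STATE_VARS, length(grid1) >= 1, length(grid2) >= 1)
  cfg <- simulation_settings(t_end = week, output_step = output_step,
                             rel_tol = rel_tol, abs_tol = abs_tol)
  m <- matrix(NA_real_, length(grid1), length(grid2),
              dimnames = list(format(grid1, digits = 8),
                              format(grid2, digits = 8)))
  long <- list()
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      pi <- p
      pi[[params[1]]] <- grid1[i]
      pi[[params[2]]] <- grid2[j]
      tr <- simulate_mdx(pi, cfg = cfg)
      m[i, j] <- tr[[variable]][nrow(tr)]
      long[[length(long) + 1L]] <-
        data.frame(p1 = grid1[i], p2 = grid2[j], variable = variable,
                   week = week, value = m[i, j])
    }
  }
  long <- do.call(rbind, long)
  names(long)[1:2] <- params
  attr(m, "long") <- long
  m
}

#' Grid search for the regeneration rate maximizing long-run normal tissue
#'
#' Sweeps `k4` over a range and returns the grid value maximizing the
#' tail-mean normal-fiber percentage.  Deterministic; ties broken toward
#' the smallest `k4`.
#'
#' @param range length-2 numeric range of `k4` (per week).
#' @param resolution grid spacing (per week).
#' @param horizon simulation horizon in weeks.
#' @param p template parameters.
#' @param window tail window for the mean of `N`.
#' @return List with `k4_star`, `tail_mean_N` at the optimum, and `sweep`
#'   (the full [sweep_1d()] table).
#' @export
find_optimal_k4 <- function(range = c(0.05, 0.25), resolution = 0.005,
                            horizon = 50, p = mdx_parameters(),
                            window = c(40, 50)) {
  stopifnot(length(range) == 2, range[2] >= range[1], resolution > 0)
  grid <- seq(range[1], range[2], by = resolution)
  sw <- sweep_1d("k4", grid, horizon = horizon, p = p, window = window)
  i <- which.max(sw$mean_N)
  list(k4_star = sw$value[i], tail_mean_N = sw$mean_N[i], sweep = sw)
}
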