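#' Default literature-style sampling design
#'
#' Emulates the sampling of the published mdx time courses: weekly
#' observations from 14 to 84 days of age (11 time points per dataset),
#' with macrophages sampled soleus-style, CD4+ and CD8+ T cells
#' quadriceps-style, and the three fiber-state percentages
#' histopathology-style.
#'
#' @return Data frame with columns `dataset_id`, `variable`, `time_days`.
#' @export
default_mdx_design <- function() {
  days <- seq(14, 84, by = 7)
  sets <- data.frame(
    dataset_id = c("soleus_macrophages", "quadriceps_cd4", "quadriceps_cd8",
                   "fibers_normal", "fibers_damaged", "fibers_regenerating"),
    variable = c("M", "H", "C", "N", "D", "R"))
  out <- merge(sets, data.frame(time_days = days))
  out[order(out$dataset_id, out$time_days),
      c("dataset_id", "variable", "time_days")]
}

#' Generate noisy literature-style observations from known parameters
#'
#' Simulates the model at the design's sampling times and applies the noise
#' model: multiplicative lognormal noise (coefficient of variation `cv`,
#' unit mean) on cell counts, additive Gaussian noise (standard deviation
#' `sd` percentage points, truncated to `[0, 100]`) on fiber percentages.
#' With both scales zero the exact trajectory values are returned.  Noise
#' is independent across observations; fiber triplets therefore need not
#' sum to 100 after perturbation.
#'
#' @param p generating `mdx_parameters`.
#' @param design data frame with columns `dataset_id`, `variable` and
#'   either `time_days` or `time` (weeks); default [default_mdx_design()].
#' @param cv coefficient of variation of count noise (`>= 0`).
#' @param sd standard deviation of percentage noise, percentage points.
#' @param seed integer seed; the full generation is reproducible from it.
#' @param cfg simulation settings; the horizon must cover the design.
#' @param weight fitting weight attached to every dataset.
#' @return Observation data frame (`dataset_id`, `variable`, `time` in
#'   weeks, `value`, `weight`).
#' @examples
#' obs <- generate_observations(mdx_parameters(), cv = 0, sd = 0, seed = 1)
#' head(obs)
#' @export
generate_observations <- function(p = mdx_parameters(),
                                  design = default_mdx_design(),
                                  cv = 0.2, sd = 3, seed = 1,
                                  cfg = NULL, weight = 1) {
  validate_parameters(p)
  stopifnot(cv >= 0, sd >= 0)
  if (is.null(design[["time"]])) {
    stopifnot(!is.null(design[["time_days"]]))
    design$time <- design[["time_days"]] / 7
  }
  stopifnot(all(c("dataset_id", "variable") %in% names(design)),
            all(design$variable %in% STATE_VARS))
  horizon <- max(design$time)
  if (is.null(cfg))
    cfg <- simulation_settings(t_end = horizon, output_step = 0.05)
  stopifnot(cfg$t_end >= horizon)

  times <- sort(unique(design$time))
  tr <- simulate_mdx(p, cfg = simulation_settings(
    t_start = 0, t_end = cfg$t_end, output_step = cfg$output_step,
    rel_tol = cfg$rel_tol, abs_tol = cfg$abs_tol))
  sim_at <- function(v, t)
    stats::approx(tr$time, tr[[v]], xout = t, rule = 2)$y

  set.seed(as.integer(seed))
  counts <- c("H", "C", "M")
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  out <- design[order(design$dataset_id, design$time),
                c("dataset_id", "variable", "time")]
  truth <- mapply(sim_at, out$variable, out$time)
  is_count <- out$variable %in% counts
  value <- truth
  if (cv > 0 && any(is_count)) {
    # unit-mean multiplier: E[lognormal(-sdlog^2/2, sdlog)] = 1
    value[is_count] <- truth[is_count] *
      stats::rlnorm(sum(is_count), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (sd > 0 && any(!is_count)) {
    value[!is_count] <- pmin(100, pmax(0,
      truth[!is_count] + stats::rnorm(sum(!is_count), 0, sd)))
  }
  out$value <- as.numeric(value)
  out$weight <- weight
  rownames(out) <- NULL
  validate_observations(out)
}
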