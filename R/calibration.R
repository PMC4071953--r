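## Fast internal solve used inside objective evaluations: output only at the
## observation times, fitting-grade tolerances, no class dressing.
sim_at_times <- function(p, times, cfg) {
  tt <- sort(unique(c(0, times)))
  out <- integrate_segment(baseline_state(p), tt, p, cfg)
  out[match(tt, out[, "time"]), , drop = FALSE]
}

#' Calibration objective: max-normalized weighted least squares
#'
#' Simulates the model from the baseline initial state and scores it
#' against a long-format observation table.  Each dataset contributes its
#' sum of squared residuals divided by the square of its largest observed
#' value (so cell counts of order 1e5 and percentages of order 1e2 are
#' commensurate), multiplied by the dataset weight.  The value is a
#' deterministic function of `(p, obs, cfg)`.  If the integrator fails, a
#' large finite penalty (1e8) is returned and a message is emitted, so
#' population-based searches continue unharmed.
#'
#' @param p an `mdx_parameters` object.
#' @param obs observation data frame (see [observation_set()]).
#' @param cfg simulation settings; the horizon must cover all observation
#'   times.  Defaults to the observation span with fitting-grade
#'   tolerances.
#' @param normalize set `FALSE` to skip the per-dataset max-normalization
#'   (plain weighted sum of squares).
#' @return Non-negative scalar.
#' @export
fit_objective <- function(p, obs, cfg = NULL, normalize = TRUE) {
  r <- fit_residuals(p, obs, cfg, normalize)
  sum(r^2)
}

#' @rdname fit_objective
#' @details `fit_residuals()` returns the signed, scaled residual vector
#'   whose sum of squares is the objective; it is the least-squares
#'   interface used by the local refinement stage.
#' @export
fit_residuals <- function(p, obs, cfg = NULL, normalize = TRUE) {
  validate_observations(obs)
  if (is.null(cfg))
    cfg <- simulation_settings(t_end = max(obs$time), output_step = 1,
                               rel_tol = 1e-6, abs_tol = 1e-8)
  stopifnot(all(obs$time <= cfg$t_end + 1e-12))
  out <- tryCatch(sim_at_times(p, obs$time, cfg), error = function(e) {
    message("integrator penalty during objective evaluation: ",
            conditionMessage(e))
    NULL
  })
  if (is.null(out))
    return(rep(sqrt(1e8 / nrow(obs)), nrow(obs)))
  tt <- out[, "time"]
  res <- numeric(nrow(obs))
  for (id in unique(obs$dataset_id)) {
    sel <- obs$dataset_id == id
    v <- obs$variable[sel][1]
    sim <- out[match(obs$time[sel], tt), v]
    scale <- if (normalize) max(obs$value[sel], 1e-12) else 1
    w <- obs$weight[sel][1]
    res[sel] <- sqrt(w) * (obs$value[sel] - sim) / scale
  }
  res
}

#' Default fitting bounds around a reference parameter set
#'
#' Rate parameters are bounded in `[x/2, 2x]` (the convention of the
#' published sensitivity ranges); the damage parameters `h`, `m`, `sigma`
#' in `[0, 2x]`.
#'
#' @param p reference `mdx_parameters`.
#' @return List with named numeric vectors `lower` and `upper` over the 13
#'   free parameters.
#' @export
default_fit_bounds <- function(p = mdx_parameters()) {
  theta <- parameter_vector(p)
  lower <- theta / 2
  upper <- theta * 2
  lower[c("h", "m", "sigma")] <- 0
  # sigma = 0 is singular; keep the box interior
  lower["sigma"] <- 1e-6
  list(lower = lower, upper = upper)
}

new_fit_result <- function(p_template, theta, value, evaluations, seed,
                           converged, obs, cfg, bounds, budget, stage) {
  est <- set_parameter_vector(p_template, theta)
  per <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$dataset_id),
    function(ii) {
      r <- fit_residuals(est, obs[ii, , drop = FALSE], cfg)
      data.frame(dataset_id = obs$dataset_id[ii[1]],
                 n = length(ii), rss = sum(r^2))
    }))
  rownames(per) <- NULL
  structure(list(parameters = est, theta = theta, objective = value,
                 evaluations = evaluations, seed = as.integer(seed),
                 converged = converged, residual_summary = per,
                 bounds = bounds, budget = budget, stage = stage),
            class = "mdx_fit")
}

#' @export
print.mdx_fit <- function(x, ...) {
  cat(sprintf("mdx fit (%s): objective %.6g after %d evaluations%s\n",
              x$stage, x$objective, x$evaluations,
              if (x$converged) ", converged" else ""))
  print(signif(x$theta, 6))
  invisible(x)
}

#' Global calibration stage (seeded differential evolution)
#'
#' Population-based stochastic search over the 13 free parameters inside
#' finite box bounds, minimizing [fit_objective()].  Fully reproducible:
#' the same `(obs, bounds, seed, budget)` give a bit-identical result.
#'
#' @param obs observation data frame.
#' @param bounds list with `lower`/`upper` named vectors
#'   (default [default_fit_bounds()]).
#' @param seed integer seed for the search.
#' @param budget objective evaluations allowed after the initial
#'   population; `budget = 0` scores the initial sample only and returns
#'   its best member with `converged = FALSE`.
#' @param p_template parameter set supplying the fixed baselines
#'   `H0, C0, M0`.
#' @param cfg simulation settings for objective evaluations.
#' @param ... further arguments to [optimize_de()].
#' @return An `mdx_fit` object.
#' @export
fit_global <- function(obs, bounds = default_fit_bounds(), seed = 1,
                       budget = 2000, p_template = mdx_parameters(),
                       cfg = NULL, ...) {
  validate_observations(obs)
  if (is.null(cfg))
    cfg <- simulation_settings(t_end = max(obs$time), output_step = 1,
                               rel_tol = 1e-6, abs_tol = 1e-8)
  fn <- function(theta)
    fit_objective(set_parameter_vector(p_template, theta), obs, cfg)
  res <- optimize_de(fn, bounds$lower, bounds$upper, seed = seed,
                     budget = budget, ...)
  theta <- res$par
  names(theta) <- FREE_PARAMETERS
  new_fit_result(p_template, theta, res$value, res$evaluations, seed,
                 res$converged, obs, cfg, bounds, budget, "global")
}

#' Local calibration stage (bounded Levenberg-Marquardt)
#'
#' Least-squares refinement of a starting point with `minpack.lm::nls.lm`
#' on the scaled residual vector, subject to the same box bounds as the
#' global stage.  The returned objective never exceeds the starting one:
#' if the refinement fails to improve, the start is returned unchanged.
#'
#' @param start an `mdx_fit` (typically from [fit_global()]) or an
#'   `mdx_parameters` object inside the bounds.
#' @param obs observation data frame.
#' @param bounds list with `lower`/`upper` named vectors.
#' @param cfg simulation settings for objective evaluations.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return An `mdx_fit` object.
#' @export
fit_local <- function(start, obs, bounds = default_fit_bounds(),
                      cfg = NULL, maxiter = 60) {
  validate_observations(obs)
  if (inherits(start, "mdx_fit")) {
    p_template <- start$parameters
    theta0 <- start$theta
    seed <- start$seed
    ev0 <- start$evaluations
  } else {
    p_template <- start
    theta0 <- parameter_vector(start)
    seed <- NA_integer_
    ev0 <- 0L
  }
  stopifnot(all(theta0 >= bounds$lower - 1e-12),
            all(theta0 <= bounds$upper + 1e-12))
  if (is.null(cfg))
    cfg <- simulation_settings(t_end = max(obs$time), output_step = 1,
                               rel_tol = 1e-6, abs_tol = 1e-8)
  resfn <- function(theta) {
    names(theta) <- FREE_PARAMETERS
    fit_residuals(set_parameter_vector(p_template, theta), obs, cfg)
  }
  lm <- minpack.lm::nls.lm(par = theta0, lower = bounds$lower,
                           upper = bounds$upper, fn = resfn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter))
  f0 <- sum(resfn(theta0)^2)
  f1 <- sum(lm$fvec^2)
  if (is.finite(f1) && f1 <= f0) {
    theta <- lm$par
    value <- f1
    converged <- lm$info %in% 1:4
  } else {                       # descent contract: never worse than start
    theta <- theta0
    value <- f0
    converged <- FALSE
  }
  names(theta) <- FREE_PARAMETERS
  theta <- pmin(pmax(theta, bounds$lower), bounds$upper)
  new_fit_result(p_template, theta, value,
                 ev0 + as.integer(lm$niter) * (length(theta0) + 1L),
                 seed, converged, obs, cfg, bounds, NA_integer_, "local")
}

#' Serialize / restore a fit result
#'
#' @param fit an `mdx_fit` object.
#' @param path JSON file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` the
#'   restored list (parameter estimates re-typed, residual summary as a
#'   data frame).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mdx_fit"))
  out <- list(parameters = unclass(fit$parameters), theta = as.list(fit$theta),
              objective = fit$objective, evaluations = fit$evaluations,
              seed = fit$seed, converged = fit$converged,
              residual_summary = fit$residual_summary,
              bounds = lapply(fit$bounds, as.list),
              budget = fit$budget, stage = fit$stage)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$parameters <- do.call(mdx_parameters, as.list(raw$parameters))
  raw$theta <- unlist(raw$theta)
  raw$bounds <- lapply(raw$bounds, unlist)
  class(raw) <- "mdx_fit"
  raw
}

#' Parameter-recovery assessment on synthetic data
#'
#' Validates the two-stage calibration pipeline end to end: for each
#' replicate, noisy observations are generated from known parameters, the
#' global then local stages are run, and per-parameter relative errors are
#' recorded.  Replicate seeds are derived deterministically from `seed`.
#'
#' @param true_p generating `mdx_parameters`.
#' @param noise_cv count-noise coefficient of variation handed to
#'   [generate_observations()] (fiber noise defaults to 3 pp, scaled to 0
#'   when `noise_cv = 0`).
#' @param n_replicates number of independent replicates (`>= 1`).
#' @param seed master integer seed.
#' @param budget global-stage evaluation budget per replicate.
#' @param design sampling design for the synthetic observations.
#' @return List with `errors` (long data frame: replicate, parameter, true,
#'   estimated, rel_error, converged), `summary` (per-parameter median and
#'   90% quantile of `|rel_error|`), and `fits` (the final `mdx_fit` per
#'   replicate).
#' @export
parameter_recovery_report <- function(true_p = mdx_parameters(),
                                      noise_cv = 0.2, n_replicates = 5,
                                      seed = 1, budget = 3000,
                                      design = default_mdx_design()) {
  stopifnot(n_replicates >= 1)
  bounds <- default_fit_bounds(true_p)
  theta_true <- parameter_vector(true_p)
  sd_pp <- if (noise_cv == 0) 0 else 3
  rows <- list()
  fits <- list()
  for (i in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed) * 1000L + i
    obs <- generate_observations(true_p, design = design, cv = noise_cv,
                                 sd = sd_pp, seed = rep_seed)
    g <- fit_global(obs, bounds = bounds, seed = rep_seed, budget = budget,
                    p_template = true_p)
    l <- fit_local(g, obs, bounds = bounds)
    fits[[i]] <- l
    rows[[i]] <- data.frame(replicate = i, parameter = FREE_PARAMETERS,
                            true = unname(theta_true),
                            estimated = unname(l$theta),
                            rel_error = unname((l$theta - theta_true) /
                                                 theta_true),
                            converged = l$converged)
  }
  errors <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(errors, errors$parameter),
    function(d) data.frame(parameter = d$parameter[1],
                           median_abs_rel_error = stats::median(abs(d$rel_error)),
                           q90_abs_rel_error = stats::quantile(abs(d$rel_error),
                                                               0.9))))
  summary <- summary[match(FREE_PARAMETERS, summary$parameter), ]
  rownames(summary) <- NULL
  list(errors = errors, summary = summary, fits = fits)
}
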