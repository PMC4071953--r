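#' Seeded bound-constrained differential evolution
#'
#' Minimal, fully reproducible rand/1/bin differential evolution for the
#' global stage of calibration.  The population is initialized by Latin-ish
#' uniform sampling inside the bounds; trial vectors are clipped back to
#' the box.  The evaluation budget counts objective calls made after the
#' initial population, so `budget = 0` returns the best member of the
#' initial sample with `converged = FALSE`.
#'
#' @param fn objective function of a numeric vector, returning a finite
#'   scalar (large penalty values are fine).
#' @param lower,upper numeric bounds, equal length.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param budget objective evaluations allowed after initialization.
#' @param pop_size population size (default `10 * d`, at least 20).
#' @param F_weight,crossover differential weight and crossover probability.
#' @param reltol relative improvement under which the search is declared
#'   converged (checked over the last 20 generations).
#' @return List with `par`, `value`, `evaluations` (total objective calls),
#'   `converged`, `seed`.
#' @export
optimize_de <- function(fn, lower, upper, seed = 1, budget = 2000,
                        pop_size = NULL, F_weight = 0.7, crossover = 0.9,
                        reltol = 1e-10) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), budget >= 0)
  if (is.null(pop_size)) pop_size <- max(20L, 10L * d)
  pop_size <- as.integer(pop_size)
  set.seed(as.integer(seed))

  pop <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                             rep(upper, each = pop_size)),
                nrow = pop_size, ncol = d)
  fit <- apply(pop, 1L, fn)
  evals <- pop_size
  used <- 0L
  gens <- if (budget > 0) budget %/% pop_size else 0L
  best_hist <- min(fit)
  converged <- FALSE

  for (g in seq_len(gens)) {
    for (i in seq_len(pop_size)) {
      if (used + 1L > budget) break
      idx <- sample(seq_len(pop_size)[-i], 3L)
      mutant <- pop[idx[1L], ] +
        F_weight * (pop[idx[2L], ] - pop[idx[3L], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- stats::runif(d) < crossover
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      ft <- fn(trial)
      used <- used + 1L
      if (ft <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
      }
    }
    best_hist <- c(best_hist, min(fit))
    nh <- length(best_hist)
    if (nh > 20L) {
      prev <- best_hist[nh - 20L]
      if (prev - best_hist[nh] <= reltol * (abs(prev) + reltol)) {
        converged <- TRUE
        break
      }
    }
  }
  i <- which.min(fit)
  list(par = pop[i, ], value = fit[i], evaluations = evals + used,
       converged = converged, seed = as.integer(seed))
}
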