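test_that("objective vanishes on noise-free self-consistent data", {
  obs <- generate_observations(p_mdx, cv = 0, sd = 0, seed = 1)
  expect_lt(fit_objective(p_mdx, obs), 1e-8)
})

test_that("unnormalized objective counts unit offsets exactly", {
  obs <- generate_observations(p_mdx, cv = 0, sd = 0, seed = 1)
  one <- obs[obs$dataset_id == "fibers_normal", ]
  one$value <- one$value + 1
  # equality up to the integration tolerance of the simulated values
  expect_equal(fit_objective(p_mdx, one, normalize = FALSE), nrow(one),
               tolerance = 1e-3)
})

test_that("noise pushes the objective above the noise-free floor", {
  noisy <- generate_observations(p_mdx, cv = 0.2, sd = 3, seed = 5)
  expect_gt(fit_objective(p_mdx, noisy), 0.1)
})

test_that("objective is deterministic and respects the horizon precondition", {
  obs <- generate_observations(p_mdx, cv = 0.2, sd = 3, seed = 9)
  expect_identical(fit_objective(p_mdx, obs), fit_objective(p_mdx, obs))
  cfg <- simulation_settings(t_end = 6)
  expect_error(fit_residuals(p_mdx, obs, cfg))
})

test_that("single-parameter perturbations raise the noise-free objective", {
  obs <- generate_observations(p_mdx, cv = 0, sd = 0, seed = 1)
  f0 <- fit_objective(p_mdx, obs)
  for (pm in c("k1", "k2", "k4", "k5")) {
    theta <- parameter_vector(p_mdx)
    theta[pm] <- theta[pm] * 1.1
    expect_gt(fit_objective(set_parameter_vector(p_mdx, theta), obs), f0)
  }
})

test_that("differential evolution recovers an analytic minimum", {
  centre <- c(1.3, 0.4, 2.5, 0.9)
  fn <- function(x) sum((x - centre)^2)
  res <- optimize_de(fn, lower = rep(0, 4), upper = rep(4, 4),
                     seed = 7, budget = 4000)
  expect_true(all(abs(res$par - centre) / centre < 0.05))
  expect_lt(res$value, 1e-3)
})

test_that("zero budget returns the best initial sample, unconverged", {
  fn <- function(x) sum(x^2)
  res <- optimize_de(fn, lower = c(-1, -1), upper = c(1, 1),
                     seed = 3, budget = 0)
  expect_false(res$converged)
  expect_equal(res$evaluations, 20)     # just the initial population
  expect_true(all(abs(res$par) <= 1))
})

test_that("the global stage is bit-reproducible from its seed", {
  obs <- generate_observations(p_mdx, cv = 0.2, sd = 3, seed = 2)
  a <- fit_global(obs, seed = 42, budget = 150)
  b <- fit_global(obs, seed = 42, budget = 150)
  expect_identical(a$theta, b$theta)
  expect_identical(a$objective, b$objective)
  c <- fit_global(obs, seed = 43, budget = 150)
  expect_false(identical(a$theta, c$theta))
})

test_that("fits never leave their bounds", {
  obs <- generate_observations(p_mdx, cv = 0.2, sd = 3, seed = 2)
  bounds <- default_fit_bounds(p_mdx)
  g <- fit_global(obs, bounds = bounds, seed = 8, budget = 200)
  l <- fit_local(g, obs, bounds = bounds)
  for (fit in list(g, l)) {
    expect_true(all(fit$theta >= bounds$lower - 1e-12))
    expect_true(all(fit$theta <= bounds$upper + 1e-12))
  }
})

test_that("local refinement never increases the objective", {
  obs <- generate_observations(p_mdx, cv = 0, sd = 0, seed = 1)
  # start at the optimum: essentially unchanged
  l0 <- fit_local(p_mdx, obs)
  expect_lt(l0$objective, 1e-8)
  expect_equal(l0$theta, parameter_vector(p_mdx), tolerance = 1e-3)
  # start 10% off: objective must decrease
  start <- set_parameter_vector(p_mdx, parameter_vector(p_mdx) * 1.1)
  f_start <- fit_objective(start, obs)
  l1 <- fit_local(start, obs)
  expect_lt(l1$objective, f_start)
  # the identifiable regeneration rate comes back to the truth
  expect_equal(l1$theta[["k4"]], p_mdx$k4, tolerance = 0.05)
})

test_that("fit results round-trip through JSON", {
  obs <- generate_observations(p_mdx, cv = 0.2, sd = 3, seed = 2)
  g <- fit_global(obs, seed = 4, budget = 60)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(g, f)
  back <- read_fit(f)
  expect_equal(back$theta, g$theta, tolerance = 1e-12)
  expect_identical(back$seed, g$seed)
  expect_identical(back$converged, g$converged)
  expect_equal(back$residual_summary$rss, g$residual_summary$rss,
               tolerance = 1e-12)
})

test_that("noise-free recovery is exact for identifiable parameters", {
  rep <- parameter_recovery_report(p_mdx, noise_cv = 0, n_replicates = 1,
                                   seed = 2, budget = 1500)
  e <- rep$errors
  for (pm in c("k1", "k2", "k3", "k4", "k5", "k6", "dC"))
    expect_lt(abs(e$rel_error[e$parameter == pm]), 0.05)
})

test_that("observation tables ingest day-based ages as weeks", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dataset_id,variable,time_days,value,weight",
               "soleus_macrophages,M,14,1200,1",
               "soleus_macrophages,M,28,80000,1",
               "fibers_normal,N,84,40,2"), f)
  obs <- read_observations(f)
  expect_equal(obs$time, c(2, 4, 12))
  expect_equal(obs$weight, c(1, 1, 2))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, f2)
  expect_equal(read_observations(f2), obs, tolerance = 1e-12)
})
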