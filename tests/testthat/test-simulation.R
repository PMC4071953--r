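test_that("compiled integrator agrees with the pure-R derivative oracle", {
  # one explicit RK4 step of the R-side derivatives vs a short lsoda run
  p <- p_mdx
  s0 <- baseline_state(p)
  h <- 1e-4
  k1 <- mdx_derivatives(1, s0, p)
  k2 <- mdx_derivatives(1 + h / 2, s0 + h / 2 * k1, p)
  k3 <- mdx_derivatives(1 + h / 2, s0 + h / 2 * k2, p)
  k4 <- mdx_derivatives(1 + h, s0 + h * k3, p)
  manual <- s0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  tr <- simulate_mdx(p, init = s0, cfg = simulation_settings(
    t_start = 1, t_end = 1 + h, output_step = h))
  expect_equal(unlist(tr[nrow(tr), c("H", "C", "M", "N", "D", "R")]),
               manual, tolerance = 1e-8)
})

test_that("fixed-point configurations give constant trajectories", {
  # no damage, no cytotoxic cells: every source balances its sink
  p <- mdx_parameters(h = 0, C0 = 0)
  tr <- simulate_mdx(p, cfg = simulation_settings(t_end = 12))
  for (v in c("H", "C", "M", "N", "D", "R"))
    expect_equal(tr[[v]], rep(tr[[v]][1], nrow(tr)), tolerance = 1e-7)
  # fully zeroed sources
  p0 <- mdx_parameters(h = 0, H0 = 0, C0 = 0, M0 = 0)
  tr0 <- simulate_mdx(p0, cfg = simulation_settings(t_end = 12))
  expect_equal(tr0$N, rep(100, nrow(tr0)), tolerance = 1e-8)
  expect_equal(max(abs(tr0$M)), 0, tolerance = 1e-8)
})

test_that("fiber conservation holds along trajectories of random parameters", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_parameters()
    tr <- simulate_mdx(p, cfg = simulation_settings(t_end = 20,
                                                    output_step = 0.25))
    expect_lt(max_conservation_error(tr), 1e-5)
    expect_true(all(tr[-1, -1] > -1e-5))   # non-negativity within tolerance
  }
})

test_that("tightening tolerances or refining output changes states < 0.1%", {
  p <- p_mdx
  a <- simulate_mdx(p, cfg = simulation_settings(t_end = 12,
                                                 output_step = 0.25))
  b <- simulate_mdx(p, cfg = simulation_settings(t_end = 12,
                                                 output_step = 0.05,
                                                 rel_tol = 1e-10,
                                                 abs_tol = 1e-12))
  common <- match(a$time, b$time)
  for (v in c("H", "C", "M", "N", "D", "R")) {
    scale <- max(abs(b[[v]]))
    expect_lt(max(abs(a[[v]] - b[[v]][common])) / scale, 1e-3)
  }
})

test_that("tail statistics summarize only the requested window", {
  tr <- fake_trajectory(0:50, N = 100)
  ts <- tail_statistics(tr, c(40, 50))
  expect_equal(ts["N", "amplitude"], 0)
  expect_equal(ts["N", "mean"], 100)
  # mean always within [min, max] on a real trajectory
  real <- simulate_mdx(p_mdx, cfg = simulation_settings(t_end = 12))
  ts2 <- tail_statistics(real, c(6, 12))
  expect_true(all(ts2$mean >= ts2$min & ts2$mean <= ts2$max))
  expect_true(all(ts2$amplitude >= 0))
  expect_error(tail_statistics(real, c(20, 30)), "window")
})

test_that("mode classification separates the three regimes", {
  expect_identical(classify_mode(fake_trajectory(0:50, N = 100)),
                   "disease_free")
  expect_identical(classify_mode(fake_trajectory(0:50, N = 40)),
                   "quiescent_low")
  osc <- fake_trajectory(seq(0, 50, 0.1),
                         N = 50 + 5 * sin(seq(0, 50, 0.1)))
  expect_identical(classify_mode(osc), "oscillatory")
  # threshold edges are honored
  expect_identical(classify_mode(fake_trajectory(0:50, N = 89.9)),
                   "quiescent_low")
  expect_identical(
    classify_mode(fake_trajectory(0:50, N = 89.9), normal_threshold = 85),
    "disease_free")
})

test_that("peak location breaks ties toward the earliest time", {
  flat <- fake_trajectory(0:50, M = 7)
  pk <- peak_value(flat, "M", c(10, 20))
  expect_equal(pk$t_peak, 10)
  expect_equal(pk$value, 7)
  rising <- fake_trajectory(0:50, C = 0:50)
  expect_equal(peak_value(rising, "C", c(5, 30))$t_peak, 30)
  expect_error(peak_value(rising, "C", c(60, 70)), "window")
})

test_that("trajectories round-trip through CSV with metadata sidecar", {
  tr <- simulate_mdx(p_mdx, cfg = simulation_settings(t_end = 3,
                                                       output_step = 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_identical(readLines(f, n = 1), "t,H,C,M,N,D,R")
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(unlist(attr(back, "parameters")), unlist(p_mdx))
  meta <- jsonlite::read_json(paste0(f, ".meta.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$units$M, "cells/mm^3")
  expect_identical(meta$units$N, "percent")
})
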