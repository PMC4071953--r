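test_that("damage hazard matches the lognormal density oracle", {
  p <- p_mdx
  # independent oracle: alpha(t) = h * dlnorm(t, m, sigma)
  tt <- c(0.1, 0.5, 1, 2, 5, 12, 50)
  expect_equal(damage_rate(tt, p),
               p$h * dlnorm(tt, meanlog = p$m, sdlog = p$sigma),
               tolerance = 1e-12)
  # frozen spot value at t = 1 week, Table-1 damage parameters
  expect_equal(damage_rate(1, p), 0.024593, tolerance = 1e-4)
})

test_that("damage hazard edge cases and validation", {
  expect_identical(damage_rate(0, p_mdx), 0)          # continuity limit
  p0 <- mdx_parameters(h = 0)
  expect_identical(damage_rate(c(0, 1, 7), p0), c(0, 0, 0))
  expect_true(all(damage_rate(seq(0, 60, 0.5), p_mdx) >= 0))
  expect_error(damage_rate(1, list(h = 1, m = 0, sigma = -1)), "sigma")
  expect_error(mdx_parameters(sigma = 0), "sigma")
})

test_that("damage hazard mass over all positive time equals the amplitude", {
  p <- p_mdx
  mass <- integrate(damage_rate, 0, Inf, p = p, rel.tol = 1e-10)$value
  expect_equal(mass, p$h, tolerance = 1e-6)
  wt <- wild_type_parameters(p)
  expect_equal(integrate(damage_rate, 0, Inf, p = wt,
                         rel.tol = 1e-10)$value, p$h / 10,
               tolerance = 1e-6)
})

test_that("derived sources are the death-rate/baseline products", {
  src <- derived_sources(p_mdx)
  expect_identical(src[["bH"]], 0)                 # H0 = 0 forces bH = 0
  expect_equal(src[["bC"]], 6.46044, tolerance = 1e-6)
  expect_equal(src[["bM"]], 312.462, tolerance = 1e-6)
  p <- mdx_parameters(H0 = 10)
  expect_equal(derived_sources(p)[["bH"]], 10 * p$dH)
})

test_that("fiber derivatives sum to zero exactly on random states", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_parameters()
    s <- random_state()
    d <- mdx_derivatives(runif(1, 0, 20), s, p)
    # dR is defined as -(dN + dD), so the identity is exact in floating point
    expect_identical(d[["N"]] + d[["D"]] + d[["R"]], 0)
  }
})

test_that("immune baseline is a fixed point when no damage is present", {
  set.seed(12)
  for (i in 1:25) {
    p <- random_parameters()
    p$H0 <- runif(1, 0, 50); p$C0 <- runif(1, 0, 50)
    p$M0 <- runif(1, 0, 2000)
    s <- c(H = p$H0, C = p$C0, M = p$M0, N = 70, D = 0, R = 30)
    d <- mdx_derivatives(runif(1, 0, 20), s, p)
    expect_equal(unname(d[c("H", "C", "M")]), c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("all-zero configuration is a full fixed point", {
  p <- mdx_parameters(h = 0, H0 = 0, C0 = 0, M0 = 0)
  s <- c(H = 0, C = 0, M = 0, N = 100, D = 0, R = 0)
  expect_equal(unname(mdx_derivatives(3, s, p)), rep(0, 6))
})

test_that("zero-valued components are never driven negative", {
  set.seed(13)
  for (i in 1:50) {
    p <- random_parameters()
    s <- random_state()
    z <- sample(names(s), 2)
    s[z] <- 0
    d <- mdx_derivatives(runif(1, 0, 20), s, p)
    expect_true(all(d[z] >= 0))
  }
})

test_that("wild-type variant only rescales the damage amplitude", {
  wt <- wild_type_parameters(p_mdx)
  expect_equal(wt$h, p_mdx$h / 10)
  expect_equal(wt$h, 0.0511657, tolerance = 1e-12)
  same <- setdiff(names(unlist(p_mdx)), "h")
  expect_identical(unlist(wt)[same], unlist(p_mdx)[same])
})

test_that("parameters round-trip through flat JSON essentially exactly", {
  p <- random_parameters()
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, f)
  keys <- names(jsonlite::read_json(f))
  expect_setequal(keys, c("k1", "k2", "k3", "k4", "k5", "k6", "dH", "dC",
                          "dM", "dD", "h", "m", "sigma", "H0", "C0", "M0"))
  p2 <- read_parameters(f)
  expect_equal(unlist(p2), unlist(p), tolerance = 1e-12)
})

test_that("parameter vector extraction and replacement are inverses", {
  p <- p_mdx
  theta <- parameter_vector(p)
  expect_length(theta, 13)
  expect_identical(unlist(set_parameter_vector(p, theta)), unlist(p))
  q <- set_parameter_vector(p, c(k4 = 0.2))
  expect_equal(q$k4, 0.2)
  expect_identical(q$k1, p$k1)
  expect_error(set_parameter_vector(p, c(H0 = 5)), "not free")
})
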