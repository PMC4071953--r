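# Shared fixtures: all built in code at test time.

p_mdx <- mdx_parameters()

# Hand-built trajectory object for summary/classifier tests.
fake_trajectory <- function(time, ...) {
  vals <- list(...)
  df <- data.frame(time = time)
  for (v in c("H", "C", "M", "N", "D", "R")) {
    x <- vals[[v]]
    df[[v]] <- if (is.null(x)) 0 else rep_len(x, length(time))
  }
  structure(df, class = c("mdx_trajectory", "data.frame"))
}

# Random admissible state on the scales the model visits.
random_state <- function() {
  f <- runif(3)
  f <- 100 * f / sum(f)
  c(H = runif(1, 0, 5000), C = runif(1, 0, 2000), M = runif(1, 0, 1e5),
    N = f[1], D = f[2], R = f[3])
}

# Calibrated values scaled coordinate-wise by U(0.5, 2) — the bounds used for
# fitting and sensitivity work.
random_parameters <- function() {
  theta <- parameter_vector(p_mdx) * runif(13, 0.5, 2)
  set_parameter_vector(p_mdx, theta)
}

max_conservation_error <- function(tr) max(abs(tr$N + tr$D + tr$R - 100))
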