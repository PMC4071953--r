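#' Lognormal mechanical damage input
#'
#' Per-week hazard of mechanical failure of normal fibers at age `t` weeks.
#' Accumulated multiplicative micro-damage makes the time to fiber failure
#' lognormal, so the hazard is an amplitude-scaled lognormal density,
#'
#' \deqn{\alpha(t) = \frac{h}{t \sigma \sqrt{2\pi}}
#'       e^{-(\ln t - m)^2 / (2\sigma^2)},}
#'
#' with `alpha(0) = 0` by continuity (the density vanishes as `t -> 0+`).
#' Integrated over all positive time the hazard mass equals the amplitude
#' `h`.
#'
#' @param t age in weeks (vectorized, `>= 0`).
#' @param p an `mdx_parameters` object, or any list with elements `h`, `m`,
#'   `sigma`.
#' @return Numeric vector of hazards (per week), same length as `t`.
#' @examples
#' damage_rate(1, mdx_parameters())
#' @export
damage_rate <- function(t, p) {
  if (is.null(p$sigma) || !is.finite(p$sigma) || p$sigma <= 0)
    stop("sigma must be strictly positive")
  if (is.null(p$h) || p$h < 0)
    stop("h must be non-negative")
  stopifnot(all(is.finite(t)), all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- p$h / (tp * p$sigma * sqrt(2 * pi)) *
    exp(-(log(tp) - p$m)^2 / (2 * p$sigma^2))
  out
}

#' State derivatives of the immune-muscle model
#'
#' Pure right-hand side of the six ordinary differential equations.  Immune
#' cells (cells/mm^3): CD4+ helpers `H` are activated by macrophages in the
#' presence of damage (`k1*D*M`), CD8+ cytotoxic cells `C` by damage under
#' helper licensing (`k2*D*H`), macrophages `M` infiltrate in response to
#' damage alone (`k3*M*D`); each is replenished at its derived constant
#' source and dies at its per-capita rate.  Fiber percentages: normal fibers
#' `N` are regenerated at `k4*R` and lost to cytotoxic attack (`k5*C*N`) and
#' mechanical damage (`alpha(t)*N`); damaged fibers `D` are cleared by
#' macrophages (`k6*D*M`) and physiologically (`dD*D`); regenerating fibers
#' `R` close the balance, so `dN + dD + dR = 0` identically and
#' `N + D + R` is conserved.
#'
#' @param t time in weeks.
#' @param state named numeric vector with elements `H`, `C`, `M`, `N`, `D`,
#'   `R`.
#' @param p an `mdx_parameters` object.
#' @return Named numeric vector of the six derivatives, in state order
#'   (`H`, `C`, `M` in cells/mm^3/week; `N`, `D`, `R` in percentage points
#'   per week).
#' @examples
#' mdx_derivatives(0, baseline_state(), mdx_parameters())
#' @export
mdx_derivatives <- function(t, state, p) {
  validate_parameters(p)
  stopifnot(all(c("H", "C", "M", "N", "D", "R") %in% names(state)),
            all(is.finite(state)))
  a <- damage_rate(t, p)
  H <- state[["H"]]; C <- state[["C"]]; M <- state[["M"]]
  N <- state[["N"]]; D <- state[["D"]]; R <- state[["R"]]
  dH <- p$dH * p$H0 + p$k1 * D * M - p$dH * H
  dC <- p$dC * p$C0 + p$k2 * D * H - p$dC * C
  dM <- p$dM * p$M0 + p$k3 * M * D - p$dM * M
  dN <- p$k4 * R - p$k5 * C * N - a * N
  dD <- p$k5 * C * N + a * N - p$k6 * D * M - p$dD * D
  dR <- -(dN + dD)                     # fiber conservation, exact
  c(H = dH, C = dC, M = dM, N = dN, D = dD, R = dR)
}

#' Baseline initial state
#'
#' Disease-onset initial condition: all fibers normal (`N = 100`,
#' `D = R = 0`) and immune populations at their wild-type baselines
#' (`H0`, `C0`, `M0`).
#'
#' @param p an `mdx_parameters` object supplying the immune baselines.
#' @return Named numeric state vector `c(H, C, M, N, D, R)`.
#' @export
baseline_state <- function(p = mdx_parameters()) {
  validate_parameters(p)
  c(H = p$H0, C = p$C0, M = p$M0, N = 100, D = 0, R = 0)
}
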