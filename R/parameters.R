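#' Model parameters for the mdx immune-muscle model
#'
#' Constructs the full parameter set of the six-variable model: rate
#' constants of the immune equations (`k1`, `k2`, `k3` damage-driven
#' proliferation/infiltration; `dH`, `dC`, `dM` death rates), of the fiber
#' equations (`k4` regeneration-to-normal rate, `k5` cytotoxic degradation,
#' `k6` macrophage cleaning, `dD` physiological cleaning), the lognormal
#' damage input (`h` amplitude, `m` log-time location, `sigma` log-time
#' scale), and the baseline immune counts (`H0`, `C0`, `M0`, in cells per
#' mm^3 of muscle).  All rates are per week; fiber variables are percentages
#' of total fibers, so `k1`, `k2`, `k3` carry units of per percentage point
#' per week.
#'
#' Defaults are the published calibrated values for the mdx mouse.  The
#' constant immune source terms are never free parameters: they are derived
#' as `bH = dH * H0`, `bC = dC * C0`, `bM = dM * M0`, which makes the
#' baseline `(H0, C0, M0)` a fixed point of the immune equations whenever no
#' damage is present.
#'
#' @param k1,k2 damage-driven proliferation rates of CD4+ and CD8+ T cells
#'   (per percentage point of damaged fibers per week).
#' @param k3 damage-driven infiltration rate of macrophages (per percentage
#'   point per week).
#' @param k4 generation rate of healthy fibers from regenerating fibers
#'   (per week).
#' @param k5 cytotoxic degradation rate of normal fibers by CD8+ T cells
#'   (per cell per week).
#' @param k6 cleaning rate of damaged fibers by macrophages (per cell per
#'   week).
#' @param dH,dC,dM death rates of CD4+, CD8+ T cells and macrophages
#'   (per week).
#' @param dD physiological cleaning rate of damaged fibers (per week).
#' @param h amplitude of the lognormal mechanical damage input
#'   (dimensionless; `>= 0`).
#' @param m log-time location of the damage input (log-weeks).
#' @param sigma log-time scale of the damage input (`> 0`).
#' @param H0,C0,M0 baseline immune-cell counts (cells per mm^3).
#' @return An object of class `mdx_parameters`: a named list of the sixteen
#'   quantities above.
#' @seealso [wild_type_parameters()], [derived_sources()], [simulate_mdx()]
#' @examples
#' p <- mdx_parameters()
#' derived_sources(p)
#' @export
mdx_parameters <- function(k1 = 0.0324139,
                           k2 = 0.115375,
                           k3 = 0.766576,
                           k4 = 0.123848,
                           k5 = 4.09948e-3,
                           k6 = 3.23097e-4,
                           dH = 0.83355,
                           dC = 1.61511,
                           dM = 0.781155,
                           dD = 1.34671,
                           h = 0.511657,
                           m = 4.22686,
                           sigma = 2.92815,
                           H0 = 0,
                           C0 = 4,
                           M0 = 400) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            dH = dH, dC = dC, dM = dM, dD = dD,
            h = h, m = m, sigma = sigma,
            H0 = H0, C0 = C0, M0 = M0)
  p <- lapply(p, as.numeric)
  class(p) <- "mdx_parameters"
  validate_parameters(p)
  p
}

#' @export
print.mdx_parameters <- function(x, ...) {
  cat("mdx immune-muscle model parameters (rates per week)\n")
  v <- unlist(x)
  print(signif(v, 6))
  src <- derived_sources(x)
  cat(sprintf("derived sources: bH = %.6g, bC = %.6g, bM = %.6g cells/mm^3/wk\n",
              src[["bH"]], src[["bC"]], src[["bM"]]))
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "mdx_parameters"))
  nm <- c("k1", "k2", "k3", "k4", "k5", "k6", "dH", "dC", "dM", "dD",
          "h", "m", "sigma", "H0", "C0", "M0")
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  v <- unlist(p[nm])
  if (any(!is.finite(v)))
    stop("all parameters must be finite")
  nonneg <- setdiff(nm, "m")          # m is a log-time location, sign-free
  if (any(v[nonneg] < 0))
    stop("negative value for: ",
         paste(nonneg[v[nonneg] < 0], collapse = ", "))
  if (p$sigma <= 0)
    stop("sigma must be strictly positive")
  invisible(p)
}

#' Wild-type (disease-free) parameter variant
#'
#' The wild-type mouse is modeled identically to the mdx mouse except that
#' the mechanical damage amplitude `h` is one tenth of its mdx value: the
#' initial physiological damage is not amplified by the dystrophic process.
#'
#' @param p mdx parameter set to derive from.
#' @return An `mdx_parameters` object with `h` divided by ten.
#' @examples
#' wild_type_parameters()$h
#' @export
wild_type_parameters <- function(p = mdx_parameters()) {
  validate_parameters(p)
  p$h <- p$h / 10
  p
}

#' Derived constant immune source terms
#'
#' The constant replenishment rates of the three immune populations are
#' defined as products of the death rate and the baseline count, so that the
#' baselines are stationary in the absence of damage.
#'
#' @param p an `mdx_parameters` object.
#' @return Named numeric vector `c(bH, bC, bM)` in cells per mm^3 per week.
#' @export
derived_sources <- function(p) {
  validate_parameters(p)
  c(bH = p$dH * p$H0, bC = p$dC * p$C0, bM = p$dM * p$M0)
}

## Names of the thirteen free (fittable) parameters, in canonical order.
## Baseline counts H0, C0, M0 are treated as fixed experimental inputs.
FREE_PARAMETERS <- c("k1", "k2", "k3", "k4", "k5", "k6",
                     "dH", "dC", "dM", "dD", "h", "m", "sigma")

#' Free-parameter vector of a parameter set
#'
#' @param p an `mdx_parameters` object.
#' @return Named numeric vector of the 13 free parameters (`k1..k6`, the four
#'   death/cleaning rates, and the damage parameters `h`, `m`, `sigma`).
#' @export
parameter_vector <- function(p) {
  validate_parameters(p)
  unlist(p[FREE_PARAMETERS])
}

#' Replace free parameters in a parameter set
#'
#' @param p an `mdx_parameters` object used for the fixed baselines.
#' @param theta named (or canonically ordered) numeric vector of some or all
#'   free parameters.
#' @return A new `mdx_parameters` object.
#' @export
set_parameter_vector <- function(p, theta) {
  validate_parameters(p)
  if (is.null(names(theta))) {
    stopifnot(length(theta) == length(FREE_PARAMETERS))
    names(theta) <- FREE_PARAMETERS
  }
  unknown <- setdiff(names(theta), FREE_PARAMETERS)
  if (length(unknown))
    stop("not free parameters: ", paste(unknown, collapse = ", "))
  for (nm in names(theta)) p[[nm]] <- as.numeric(theta[[nm]])
  validate_parameters(p)
  p
}

#' Read / write parameters as flat JSON
#'
#' Parameters round-trip through a flat key-value JSON document with keys
#' `k1..k6`, `dH`, `dC`, `dM`, `dD`, `h`, `m`, `sigma`, `H0`, `C0`, `M0`.
#' Values are serialized at full double precision, so
#' `read_parameters(write_parameters(p, f))` is an exact identity.
#'
#' @param p an `mdx_parameters` object.
#' @param path file path of the JSON document.
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` returns an `mdx_parameters` object.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  jsonlite::write_json(lapply(unclass(p), identity), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mdx_parameters, as.list(raw))
}

#' Published sensitivity ranges for ten model parameters
#'
#' The sensitivity analyses vary ten of the rate parameters between a lower
#' bound of half and an upper bound of twice the calibrated value.  The
#' damage parameters `h`, `m`, `sigma` and the baselines are excluded.
#'
#' @return A named list of length-2 numeric vectors `c(min, max)` for
#'   `k1`, `dH`, `k2`, `dC`, `k3`, `dM`, `k4`, `k5`, `k6`, `dD`.
#' @export
sensitivity_ranges <- function() {
  list(k1 = c(0.0160773, 0.0643092),
       dH = c(0.416775, 1.6671),
       k2 = c(0.0577452, 0.230981),
       dC = c(0.807555, 3.23022),
       k3 = c(0.381371, 1.52549),
       dM = c(0.390577, 1.56231),
       k4 = c(0.061924, 0.247696),
       k5 = c(2.04974e-3, 8.19896e-3),
       k6 = c(1.61548e-4, 6.46194e-4),
       dD = c(0.673355, 2.69342))
}
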