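#' Simulation settings
#'
#' @param t_start,t_end simulation span in weeks (`t_end > t_start >= 0`).
#' @param output_step reporting step in weeks.
#' @param rel_tol,abs_tol integrator tolerances.  The defaults are tight
#'   because the system mixes scales (macrophage counts ~1e5 against fiber
#'   percentages ~1e2) and the fiber-conservation identity is checked on
#'   every reported point.
#' @param max_step maximum internal step in weeks (`Inf` leaves it to the
#'   integrator).
#' @return A list of class `mdx_settings`.
#' @export
simulation_settings <- function(t_start = 0, t_end = 12, output_step = 0.05,
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                max_step = Inf) {
  stopifnot(t_start >= 0, t_end > t_start,
            output_step > 0, rel_tol > 0, abs_tol > 0, max_step > 0)
  structure(list(t_start = t_start, t_end = t_end,
                 output_step = output_step,
                 rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step),
            class = "mdx_settings")
}

STATE_VARS <- c("H", "C", "M", "N", "D", "R")

## One lsoda call over a segment (compiled RHS); returns a matrix whose
## first column is `time`.
integrate_segment <- function(init, times, p, cfg, mask = NULL) {
  mvar <- if (is.null(mask)) 0 else match(mask$var, c("H", "C", "M"))
  mmech <- if (is.null(mask)) 0 else
    match(mask$mechanism, c("clamp_zero", "block_influx"))
  pv <- c(p$k1, p$k2, p$k3, p$k4, p$k5, p$k6, p$dH, p$dC, p$dM, p$dD,
          p$h, p$m, p$sigma, p$H0, p$C0, p$M0, mvar, mmech)
  out <- deSolve::ode(y = unname(init), times = times, func = "mdx_derivs",
                      parms = pv, dllname = "mdximmune",
                      initfunc = "mdx_initmod", method = "lsoda",
                      rtol = cfg$rel_tol, atol = cfg$abs_tol,
                      hmax = if (is.finite(cfg$max_step)) cfg$max_step else NULL)
  if (attr(out, "istate")[1L] < 0 || nrow(out) < length(times))
    stop(sprintf("integration failed near t = %.4g weeks (step-size collapse?)",
                 out[nrow(out), 1L]))
  colnames(out) <- c("time", STATE_VARS)
  out
}

#' Integrate the immune-muscle model
#'
#' Solves the six-variable system with the stiff-capable adaptive `lsoda`
#' integrator and returns a trajectory object.  An optional depletion
#' schedule (see [depletion_schedule()]) is honored by piecewise
#' integration: the state is integrated up to the window start, modified
#' dynamics apply inside the window (with the target population zeroed for
#' the `clamp_zero` mechanism), and the original dynamics resume at the
#' window end from the state the window left behind.
#'
#' Fiber conservation (`N + D + R = 100`) is verified at every reported
#' point; states are reported as computed, and any component undershooting
#' zero beyond tolerance raises a warning rather than being silently
#' clipped.
#'
#' @param p an `mdx_parameters` object.
#' @param init named initial state (default [baseline_state()] of `p`).
#' @param cfg an `mdx_settings` object.
#' @param depletion `NULL` or an `mdx_depletion` schedule.
#' @return An object of class `mdx_trajectory`: a data frame with columns
#'   `time`, `H`, `C`, `M`, `N`, `D`, `R` and attributes `parameters`,
#'   `settings`, `depletion`.
#' @examples
#' tr <- simulate_mdx(mdx_parameters(), cfg = simulation_settings(t_end = 2))
#' head(tr)
#' @export
simulate_mdx <- function(p = mdx_parameters(), init = baseline_state(p),
                         cfg = simulation_settings(), depletion = NULL) {
  validate_parameters(p)
  stopifnot(inherits(cfg, "mdx_settings"),
            all(STATE_VARS %in% names(init)), all(is.finite(init)))
  init <- init[STATE_VARS]
  grid <- seq(cfg$t_start, cfg$t_end, by = cfg$output_step)
  if (grid[length(grid)] < cfg$t_end) grid <- c(grid, cfg$t_end)

  if (is.null(depletion)) {
    segs <- list(list(times = grid, mask = NULL))
  } else {
    stopifnot(inherits(depletion, "mdx_depletion"))
    v <- c(macrophages = "M", CD4 = "H", CD8 = "C")[[depletion$target]]
    mask <- list(var = v, mechanism = depletion$mechanism)
    cuts <- sort(unique(pmin(pmax(c(depletion$t_start, depletion$t_end),
                                  cfg$t_start), cfg$t_end)))
    bounds <- unique(c(cfg$t_start, cuts, cfg$t_end))
    segs <- list()
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i]; b <- bounds[i + 1L]
      if (b <= a) next
      inside <- a >= depletion$t_start - 1e-12 && b <= depletion$t_end + 1e-12
      tt <- unique(sort(c(a, grid[grid > a & grid < b], b)))
      segs[[length(segs) + 1L]] <-
        list(times = tt, mask = if (inside) mask else NULL)
    }
  }

  state <- init
  rows <- NULL
  for (seg in segs) {
    if (!is.null(seg$mask) && seg$mask$mechanism == "clamp_zero")
      state[seg$mask$var] <- 0
    out <- integrate_segment(state, seg$times, p, cfg, seg$mask)
    state <- out[nrow(out), STATE_VARS]
    rows <- if (is.null(rows)) out else rbind(rows, out[-1L, , drop = FALSE])
  }
  tr <- as.data.frame(rows)
  tr <- tr[tr$time %in% grid | seq_len(nrow(tr)) %in%
             c(1L, nrow(tr)), , drop = FALSE]
  tr <- tr[!duplicated(tr$time), , drop = FALSE]
  rownames(tr) <- NULL

  cons <- abs(tr$N + tr$D + tr$R - 100)
  tol <- 10 * cfg$rel_tol * 100
  if (any(cons > tol))
    warning(sprintf("fiber conservation violated by up to %.3g pp", max(cons)))
  neg <- vapply(tr[STATE_VARS], min, numeric(1))
  if (any(neg < -tol))
    warning(sprintf("negative undershoot down to %.3g in %s",
                    min(neg), STATE_VARS[which.min(neg)]))
  structure(tr, parameters = p, settings = cfg, depletion = depletion,
            class = c("mdx_trajectory", "data.frame"))
}

#' @export
print.mdx_trajectory <- function(x, ...) {
  cat(sprintf("mdx trajectory: %d points over weeks %.3g-%.3g\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

window_rows <- function(tr, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  idx <- which(tr$time >= window[1] - 1e-12 & tr$time <= window[2] + 1e-12)
  if (!length(idx))
    stop(sprintf("no trajectory points in window [%g, %g] weeks",
                 window[1], window[2]))
  idx
}

#' Tail summary of a trajectory
#'
#' Per-variable mean, min, max and peak-to-peak amplitude over a stated
#' late window, used to operationalize "asymptotic" behavior in the
#' presence of slowly decaying oscillations.
#'
#' @param tr an `mdx_trajectory`.
#' @param window length-2 numeric, weeks, inside the trajectory span.
#' @return Data frame with one row per state variable and columns
#'   `variable`, `mean`, `min`, `max`, `amplitude`.
#' @export
tail_statistics <- function(tr, window = c(40, 50)) {
  idx <- window_rows(tr, window)
  out <- do.call(rbind, lapply(STATE_VARS, function(v) {
    x <- tr[[v]][idx]
    data.frame(variable = v, mean = mean(x), min = min(x), max = max(x),
               amplitude = max(x) - min(x))
  }))
  rownames(out) <- out$variable
  out
}

#' Classify the long-run regime of a trajectory
#'
#' Labels a trajectory by its late-window behavior of the normal-fiber
#' percentage: `"oscillatory"` when the peak-to-peak amplitude of `N` is at
#' least `amp_threshold` percentage points; otherwise `"disease_free"` when
#' the window mean of `N` is at least `normal_threshold` percent, and
#' `"quiescent_low"` when the system has settled at a low-normal state.
#'
#' @param tr an `mdx_trajectory` spanning `window`.
#' @param window late window in weeks.
#' @param amp_threshold oscillation threshold on `N`, percentage points.
#' @param normal_threshold disease-free threshold on mean `N`, percent.
#' @return One of `"oscillatory"`, `"disease_free"`, `"quiescent_low"`.
#' @export
classify_mode <- function(tr, window = c(40, 50), amp_threshold = 1,
                          normal_threshold = 90) {
  idx <- window_rows(tr, window)
  x <- tr$N[idx]
  amp <- max(x) - min(x)
  if (amp >= amp_threshold) return("oscillatory")
  if (mean(x) >= normal_threshold) return("disease_free")
  "quiescent_low"
}

#' Peak of one variable inside a window
#'
#' @param tr an `mdx_trajectory`.
#' @param variable one of `"H"`, `"C"`, `"M"`, `"N"`, `"D"`, `"R"`.
#' @param window length-2 numeric, weeks (default: whole span).
#' @return List with `t_peak` (weeks; ties broken toward the earliest
#'   reported time) and `value`.
#' @export
peak_value <- function(tr, variable,
                       window = c(tr$time[1], tr$time[nrow(tr)])) {
  variable <- match.arg(variable, STATE_VARS)
  idx <- window_rows(tr, window)
  x <- tr[[variable]][idx]
  i <- which.max(x)                 # which.max returns the first maximum
  list(t_peak = tr$time[idx][i], value = x[i])
}

#' Export / import a trajectory as CSV with a metadata sidecar
#'
#' The trajectory table is written as plain CSV with header
#' `t,H,C,M,N,D,R`; parameters, settings and units go to a sidecar JSON
#' document at `<path>.meta.json`.
#'
#' @param tr an `mdx_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a data frame (with parameters re-attached
#'   when the sidecar is present).
#' @export
write_trajectory <- function(tr, path) {
  stopifnot(inherits(tr, "mdx_trajectory"))
  out <- as.data.frame(tr)
  names(out)[1] <- "t"
  utils::write.csv(format(out, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  p <- attr(tr, "parameters")
  cfg <- attr(tr, "settings")
  meta <- list(
    units = list(t = "weeks", H = "cells/mm^3", C = "cells/mm^3",
                 M = "cells/mm^3", N = "percent", D = "percent",
                 R = "percent"),
    parameters = unclass(p), settings = unclass(cfg),
    depletion = if (!is.null(attr(tr, "depletion")))
      unclass(attr(tr, "depletion")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- utils::read.csv(path)
  names(tr)[1] <- "time"
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    attr(tr, "parameters") <- do.call(mdx_parameters, as.list(meta$parameters))
    if (!is.null(meta$settings)) {
      # JSON has no Inf literal; it round-trips as the string "Inf"
      st <- lapply(meta$settings, function(x)
        if (is.character(x)) as.numeric(x) else x)
      attr(tr, "settings") <- do.call(simulation_settings, st)
    }
    class(tr) <- c("mdx_trajectory", "data.frame")
  }
  tr
}
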