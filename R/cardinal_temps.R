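# plain bisection on the raw (signed) rate; assumes f(a) and f(b) bracket 0
bisect_root <- function(f, a, b, tol = 1e-12, max_iter = 200) {
  fa <- f(a); fb <- f(b)
  if (!is.finite(fa) || !is.finite(fb) || fa * fb > 0) return(NA_real_)
  for (i in seq_len(max_iter)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (!is.finite(fm)) return(NA_real_)
    if (fm == 0 || (b - a) / 2 < tol) return(m)
    if (fa * fm < 0) { b <- m; fb <- fm } else { a <- m; fa <- fm }
  }
  (a + b) / 2
}

#' Optimal temperature of a fitted rate curve (graphical method)
#'
#' Locates the temperature maximizing the development rate by evaluating the
#' curve on a regular grid (default 0.25 degrees C, the resolution at which
#' optima of thermal-performance fits are conventionally read off) and
#' taking the argmax; a golden-section refinement around the grid maximum is
#' reported alongside. The grid value is the headline estimate.
#'
#' @param spec `model_spec` or model name.
#' @param theta parameter vector.
#' @param grid_step grid resolution in degrees C.
#' @param window closed temperature search window, degrees C.
#' @return List with `topt` (grid argmax), `topt_refined` (golden-section,
#'   ~1e-4 degree precision), `rate_max` and `method`. `topt` is `NA` with a
#'   `diagnostic` when the rate is monotone over the window (argmax on the
#'   boundary).
#' @examples
#' find_topt("Briere-1", c(a = 30.51e-5, tmin = 13.48, tmax = 35))
#' @export
find_topt <- function(spec, theta, grid_step = 0.25, window = c(0, 60)) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  grid <- seq(window[1], window[2], by = grid_step)
  # threshold-type models: search between their own thresholds, where the
  # curve is the biological dome (outside, squared factors rise again)
  lo_cl <- if (!is.null(spec$analytic$tmin)) spec$analytic$tmin(theta) else
    -Inf
  hi_cl <- if (!is.null(spec$analytic$tmax)) spec$analytic$tmax(theta) else
    Inf
  keep <- which(grid >= lo_cl & grid <= hi_cl)
  if (length(keep) < 3L) keep <- seq_along(grid)
  vals <- spec$rate(grid, theta)
  ok <- is.finite(vals)
  if (!any(ok[keep])) {
    return(list(topt = NA_real_, topt_refined = NA_real_,
                rate_max = NA_real_, method = "undefined",
                diagnostic = "rate not evaluable on window"))
  }
  masked <- replace(vals, !ok, -Inf)
  i <- keep[which.max(masked[keep])]
  if (i == keep[1L] || i == keep[length(keep)]) {
    return(list(topt = NA_real_, topt_refined = NA_real_,
                rate_max = vals[i], method = "undefined",
                diagnostic = "rate is monotone over the window"))
  }
  ref <- stats::optimize(function(x) spec$rate(x, theta),
                         lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = 1e-6)
  list(topt = grid[i], topt_refined = ref$maximum, rate_max = vals[i],
       method = "grid_argmax", diagnostic = NULL)
}

#' Upper developmental threshold by root-finding
#'
#' The smallest zero of the raw (unclipped) rate curve above the optimum,
#' found by scanning for a sign change and bisecting. Models whose catalog
#' entry carries a closed-form upper threshold (e.g. the Briere and
#' Kontodimas families, where a factor of the rate vanishes at the fitted
#' parameter) report the parameter value with method `"parameter_identity"`;
#' the root and the identity agree by construction.
#'
#' @param spec `model_spec` or model name.
#' @param theta parameter vector.
#' @param upper upper end of the search bracket (degrees C).
#' @param grid_step scan resolution for bracketing the sign change.
#' @return List with `tmax`, `method` (`"root"`, `"parameter_identity"` or
#'   `"undefined"`) and a `diagnostic` when no zero crossing exists in the
#'   bracket (curves that never return to zero above the optimum).
#' @export
find_tmax <- function(spec, theta, upper = 120, grid_step = 0.25) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  to <- find_topt(spec, theta, grid_step = grid_step, window = c(0, upper))
  start <- if (is.na(to$topt)) 0 else to$topt_refined
  if (!is.null(spec$analytic$tmax)) {
    cand <- spec$analytic$tmax(theta)
    if (is.finite(cand) && cand > start &&
        abs(spec$rate(cand, theta)) <= 1e-8) {
      return(list(tmax = cand, method = "parameter_identity",
                  diagnostic = NULL))
    }
  }
  f <- function(x) spec$rate(x, theta)
  grid <- seq(start, upper, by = grid_step)
  vals <- f(grid)
  root <- NA_real_
  for (j in seq_len(length(grid) - 1L)) {
    if (!is.finite(vals[j]) || !is.finite(vals[j + 1L])) next
    if (vals[j] > 0 && vals[j + 1L] <= 0) {
      root <- bisect_root(f, grid[j], grid[j + 1L])
      break
    }
  }
  if (is.na(root)) {
    return(list(tmax = NA_real_, method = "undefined",
                diagnostic = "no zero crossing above the optimum"))
  }
  list(tmax = root, method = "root", diagnostic = NULL)
}

#' Lower developmental threshold by root-finding
#'
#' The largest zero of the raw rate curve below the optimum (scan plus
#' bisection), or the fitted threshold parameter for models where a factor
#' vanishes there (Briere, Kontodimas/Equation-16: the squared factor
#' touches zero without a sign change, so the parameter identity is used).
#' Many catalog curves (Sigmoid, the Logan family, Lactin-1, Janisch,
#' Stinner, Lamb, Taylor, Bieri-2, Sharpe-DeMichele) stay positive at low
#' temperature and have no lower intersection: these return `NA` with a
#' diagnostic.
#'
#' @param spec `model_spec` or model name.
#' @param theta parameter vector.
#' @param lower lower end of the search bracket (degrees C).
#' @param grid_step scan resolution for bracketing the sign change.
#' @return List with `tmin`, `method`, `diagnostic` as in [find_tmax()].
#' @export
find_tmin <- function(spec, theta, lower = -20, grid_step = 0.25) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  to <- find_topt(spec, theta, grid_step = grid_step, window = c(lower, 60))
  start <- if (is.na(to$topt)) 60 else to$topt_refined
  if (!is.null(spec$analytic$tmin)) {
    cand <- spec$analytic$tmin(theta)
    if (is.finite(cand) && cand < start &&
        abs(spec$rate(cand, theta)) <= 1e-8) {
      return(list(tmin = cand, method = "parameter_identity",
                  diagnostic = NULL))
    }
  }
  f <- function(x) spec$rate(x, theta)
  grid <- seq(start, lower, by = -grid_step)
  vals <- f(grid)
  root <- NA_real_
  for (j in seq_len(length(grid) - 1L)) {
    if (!is.finite(vals[j]) || !is.finite(vals[j + 1L])) next
    if (vals[j] > 0 && vals[j + 1L] <= 0) {
      root <- bisect_root(f, grid[j + 1L], grid[j])
      break
    }
  }
  if (is.na(root)) {
    return(list(tmin = NA_real_, method = "undefined",
                diagnostic = "no zero crossing below the optimum"))
  }
  list(tmin = root, method = "root", diagnostic = NULL)
}

#' Cardinal temperatures of a fitted model
#'
#' Bundles the lower threshold, optimum and upper threshold extractions for
#' one parameterized model, with per-field method tags and a biological
#' plausibility flag on the upper threshold (fitted upper thresholds outside
#' 30-50 degrees C are reported but flagged; published fits do produce such
#' values).
#'
#' @param spec `model_spec` or model name.
#' @param theta parameter vector.
#' @param grid_step grid resolution for the optimum (degrees C).
#' @param window search window for the optimum.
#' @return Object of class `cardinal_temps`: list with `t_min`, `t_opt`,
#'   `t_opt_refined`, `t_max`, `methods` (named character vector),
#'   `tmax_plausible` and `model`.
#' @examples
#' cardinal_temps("Briere-1", c(a = 30.51e-5, tmin = 13.48, tmax = 35))
#' @export
cardinal_temps <- function(spec, theta, grid_step = 0.25, window = c(0, 60)) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  to <- find_topt(spec, theta, grid_step = grid_step, window = window)
  tx <- find_tmax(spec, theta)
  tn <- find_tmin(spec, theta)
  structure(list(
    model = spec$name,
    t_min = tn$tmin, t_opt = to$topt, t_opt_refined = to$topt_refined,
    t_max = tx$tmax,
    methods = c(t_min = tn$method, t_opt = to$method, t_max = tx$method),
    tmax_plausible = is.finite(tx$tmax) && tx$tmax >= 30 && tx$tmax <= 50,
    theta = theta), class = "cardinal_temps")
}

#' @export
print.cardinal_temps <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.2f", v))
  cat(sprintf(
    "<cardinal_temps> %s: Tmin = %s (%s), Topt = %s (%s), Tmax = %s (%s%s)\n",
    x$model, fmt(x$t_min), x$methods["t_min"], fmt(x$t_opt),
    x$methods["t_opt"], fmt(x$t_max), x$methods["t_max"],
    if (is.finite(x$t_max) && !x$tmax_plausible) ", implausible" else ""))
  invisible(x)
}
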