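#' Common linear (degree-day) model for development rate
#'
#' Ordinary least squares of development rate on temperature,
#' r(T) = a + b T, over the quasi-linear thermal range. The lower
#' developmental threshold is the temperature-axis intercept T0 = -a/b and
#' the thermal constant is K = 1/b degree-days. Standard errors of T0 and K
#' are first-order delta-method transforms of the OLS coefficient
#' covariance.
#'
#' @param points a `rate_points` data frame (see [dev_rates()]) or any data
#'   frame with columns `temperature` and `rate`.
#' @return A list of class `thermal_constants` with elements `method`
#'   (`"common"`), `slope`, `intercept`, `T0`, `K`, `se_T0`, `se_K`, `r2`,
#'   `r2_adj`, `p_value` (two-sided, of the slope) and `n_points`. When the
#'   fitted slope is not positive, `T0` and `K` are `NA` and
#'   `thresholds_defined` is `FALSE`.
#' @examples
#' pts <- data.frame(temperature = c(15, 20, 25, 27),
#'                   rate = 0.02 * c(15, 20, 25, 27) - 0.1)
#' fit_common_linear(pts)
#' @export
fit_common_linear <- function(points) {
  if (nrow(points) < 3L) {
    stop("insufficient data: common linear model needs >= 3 rate points",
         call. = FALSE)
  }
  fit <- stats::lm(rate ~ temperature, data = points)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  V <- stats::vcov(fit)
  n <- nrow(points)
  sm <- summary(fit)
  r2 <- sm$r.squared
  r2_adj <- sm$adj.r.squared
  p_value <- sm$coefficients["temperature", "Pr(>|t|)"]
  if (b > 0) {
    T0 <- -a / b
    K <- 1 / b
    # delta method: T0 = -a/b, gradient (-1/b, a/b^2); K = 1/b
    g <- c(-1 / b, a / b^2)
    se_T0 <- sqrt(drop(t(g) %*% V %*% g))
    se_K <- sqrt(V[2L, 2L]) / b^2
    defined <- TRUE
  } else {
    T0 <- K <- se_T0 <- se_K <- NA_real_
    defined <- FALSE
  }
  structure(list(method = "common", slope = b, intercept = a, T0 = T0, K = K,
                 se_T0 = se_T0, se_K = se_K, r2 = r2, r2_adj = r2_adj,
                 p_value = p_value, n_points = n,
                 thresholds_defined = defined),
            class = "thermal_constants")
}

#' Ikemoto-Takai linear model for development time
#'
#' The development-time reformulation of the degree-day line: if
#' D = K / (T - t) then D T = K + t D, so ordinary least squares of the
#' product D*T on D yields the lower threshold t as the slope and the
#' thermal constant K as the intercept.
#'
#' @param durations data frame with columns `mean_days` (or `D`) and
#'   `temperature` (degrees C), one row per constant-temperature treatment.
#' @return A `thermal_constants` list with `method = "ikemoto_takai"`; here
#'   `slope` is the lower threshold `T0` and `intercept` is `K`.
#' @examples
#' d <- data.frame(temperature = c(20, 25, 30), mean_days = 100 / (c(20, 25, 30) - 10))
#' fit_ikemoto_takai(d)
#' @export
fit_ikemoto_takai <- function(durations) {
  D <- if ("mean_days" %in% names(durations)) durations$mean_days else
    durations$D
  T <- durations$temperature
  if (length(D) < 3L) {
    stop("insufficient data: Ikemoto-Takai needs >= 3 duration points",
         call. = FALSE)
  }
  if (length(unique(D)) < 2L) {
    stop("singular fit: development times are constant across temperatures",
         call. = FALSE)
  }
  df <- data.frame(x = D, y = D * T)
  fit <- stats::lm(y ~ x, data = df)
  K <- unname(stats::coef(fit)[1L])
  t0 <- unname(stats::coef(fit)[2L])
  V <- stats::vcov(fit)
  sm <- summary(fit)
  structure(list(method = "ikemoto_takai", slope = t0, intercept = K,
                 T0 = t0, K = K,
                 se_T0 = sqrt(V[2L, 2L]), se_K = sqrt(V[1L, 1L]),
                 r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 n_points = length(D), thresholds_defined = TRUE),
            class = "thermal_constants")
}

#' Degree-day accumulation for one constant-temperature treatment
#'
#' The thermal constant implied by a single treatment:
#' K = (T - tb) * Dev degree-days, where Dev is the mean number of days to
#' complete development at constant temperature T and tb the lower
#' threshold.
#'
#' @param T rearing temperature (degrees C).
#' @param tb lower developmental threshold (degrees C).
#' @param dev_days mean development time (days), > 0.
#' @return Degree-days (numeric scalar).
#' @examples
#' degree_day_constant(27, 11.96, 13.3)
#' @export
degree_day_constant <- function(T, tb, dev_days) {
  if (!is.finite(T) || !is.finite(tb) || T <= tb) {
    stop("undefined accumulation: temperature must exceed the threshold",
         call. = FALSE)
  }
  if (!is.finite(dev_days) || dev_days <= 0) {
    stop("dev_days must be > 0", call. = FALSE)
  }
  (T - tb) * dev_days
}

#' @export
print.thermal_constants <- function(x, ...) {
  cat(sprintf(
    "<thermal_constants> %s: T0 = %.3f +/- %.3f C, K = %.2f +/- %.2f DD (n = %d, R2 = %.4f)\n",
    x$method, x$T0, x$se_T0, x$K, x$se_K, x$n_points, x$r2))
  invisible(x)
}

#' Serialize linear-model results to a flat table
#'
#' @param fits list of `thermal_constants` objects, optionally named by
#'   stage.
#' @return Data frame with one row per fit: method, stage, slope, intercept,
#'   T0, K, their SEs, R2, adjusted R2, p-value and n.
#' @export
thermal_constants_table <- function(fits) {
  stages <- names(fits)
  if (is.null(stages)) stages <- rep(NA_character_, length(fits))
  out <- do.call(rbind, Map(function(f, s) {
    data.frame(stage = s, method = f$method, slope = f$slope,
               intercept = f$intercept, T0 = f$T0, se_T0 = f$se_T0,
               K = f$K, se_K = f$se_K, r2 = f$r2, r2_adj = f$r2_adj,
               p_value = f$p_value, n = f$n_points,
               stringsAsFactors = FALSE)
  }, fits, stages))
  rownames(out) <- NULL
  out
}
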