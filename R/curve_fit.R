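# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Akaike information criterion from a residual sum of squares
#'
#' The least-squares form AIC = n ln(SSE/n) + 2p, where p counts all model
#' parameters including any intercept.
#'
#' @param rss residual sum of squares (> 0).
#' @param n_obs number of observations.
#' @param p number of model parameters.
#' @return AIC value; `-Inf` with a warning when `rss = 0` (perfect
#'   interpolation has no finite least-squares AIC).
#' @examples
#' aic_rss(1.1e-5, 6, 3)
#' @export
aic_rss <- function(rss, n_obs, p) {
  if (n_obs <= 0) stop("n_obs must be > 0", call. = FALSE)
  if (rss < 0) stop("rss must be >= 0", call. = FALSE)
  if (rss == 0) {
    warning("rss = 0: AIC is -Inf (exact interpolation)")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * p
}

#' Adjusted coefficient of determination
#'
#' R2_adj = 1 - [(n - 1)/(n - p)] (1 - R2), penalizing R2 for the number of
#' model parameters.
#'
#' @param r2 coefficient of determination.
#' @param n_obs number of observations.
#' @param p number of model parameters.
#' @return Adjusted R2; `NA` when `n_obs = p` (zero denominator, as for a
#'   six-parameter model fitted to six temperature means).
#' @examples
#' r2_adjusted(0.9969, 6, 3)
#' @export
r2_adjusted <- function(r2, n_obs, p) {
  if (n_obs < p) stop("n_obs must be >= p", call. = FALSE)
  if (n_obs == p) return(NA_real_)
  1 - ((n_obs - 1) / (n_obs - p)) * (1 - r2)
}

#' Coefficient of determination from residuals
#'
#' R2 = 1 - RSS / TSS with TSS the centered sum of squares of the observed
#' rates.
#'
#' @param residuals fitted-minus-observed residual vector.
#' @param observed observed rate vector.
#' @return R2; `NA` when the observations have zero variance.
#' @export
r2_score <- function(residuals, observed) {
  if (length(observed) < 2L) stop("need >= 2 observations", call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    warning("zero variance in observations: R2 undefined")
    return(NA_real_)
  }
  1 - sum(residuals^2) / tss
}

# map theta to/from the optimizer's working coordinates (log for scale-like
# positive parameters spanning many decades)
to_z <- function(spec, theta) {
  z <- as.numeric(theta)
  z[spec$log_scale] <- log(z[spec$log_scale])
  z
}
from_z <- function(spec, z) {
  th <- as.numeric(z)
  th[spec$log_scale] <- exp(th[spec$log_scale])
  stats::setNames(th, spec$params)
}

# Levenberg-Marquardt with central-difference Jacobian and bound clamping;
# polishes a near-solution to machine precision on noise-free data.
lm_polish <- function(resid_fn, z0, lower, upper, max_iter = 200) {
  z <- pmin(pmax(z0, lower), upper)
  r <- resid_fn(z)
  if (any(!is.finite(r))) return(list(z = z, rss = Inf, converged = FALSE))
  rss <- sum(r^2)
  lambda <- 1e-3
  p <- length(z)
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, length(r), p)
    h <- sqrt(.Machine$double.eps) * pmax(abs(z), 1e-2)
    for (j in seq_len(p)) {
      zp <- z; zm <- z
      zp[j] <- min(z[j] + h[j], upper[j])
      zm[j] <- max(z[j] - h[j], lower[j])
      dj <- zp[j] - zm[j]
      if (dj == 0) next
      J[, j] <- (resid_fn(zp) - resid_fn(zm)) / dj
    }
    if (any(!is.finite(J))) break
    g <- crossprod(J, r)
    A <- crossprod(J)
    improved <- FALSE
    for (k in 1:12) {
      step <- tryCatch(
        solve(A + lambda * diag(pmax(diag(A), 1e-12), p), -g),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      z_new <- pmin(pmax(z + drop(step), lower), upper)
      r_new <- resid_fn(z_new)
      rss_new <- if (any(!is.finite(r_new))) Inf else sum(r_new^2)
      if (rss_new < rss) {
        z <- z_new; r <- r_new
        improved <- TRUE
        conv <- (rss - rss_new) <= 1e-12 * (rss + 1e-300)
        rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        if (conv) return(list(z = z, rss = rss, converged = TRUE))
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
    if (rss == 0) break
  }
  list(z = z, rss = rss, converged = TRUE)
}

# seeded Latin-hypercube sample of n points over [lower, upper]^p
lhs_starts <- function(n, lower, upper) {
  p <- length(lower)
  Z <- vapply(seq_len(p), function(j) {
    u <- (sample.int(n) - stats::runif(n)) / n
    lower[j] + u * (upper[j] - lower[j])
  }, numeric(n))
  if (n == 1L) Z <- matrix(Z, nrow = 1L)
  Z
}

#' Fit a development-rate model by bounded multistart least squares
#'
#' Minimizes the sum of squared deviations between observed development
#' rates and the model curve within the catalog's box bounds. A seeded
#' Latin-hypercube multistart (scale-like parameters sampled on the log
#' scale) is followed by bounded quasi-Newton descent from every start and a
#' damped Gauss-Newton (Levenberg-Marquardt) polish of the best candidates,
#' so the returned optimum is deterministic given the seed and reaches
#' machine-precision residuals on noise-free data. Ties in the final loss
#' are broken toward the smaller parameter norm.
#'
#' @param spec a `model_spec` or model name from [model_registry()].
#' @param points `rate_points` data frame (columns `temperature`, `rate`).
#' @param n_starts number of Latin-hypercube starts (default 64).
#' @param seed integer RNG seed for the multistart design.
#' @param extra_starts optional matrix/list of additional start vectors on
#'   the natural parameter scale (each a full-length theta).
#' @return An object of class `dev_fit`: list with `model`, `theta`, `rss`,
#'   `r2`, `r2_adj`, `aic`, `n_obs`, `p`, `converged`, `n_starts_tried`,
#'   `residuals` (fitted - observed), `temperature`, `observed`.
#'   `r2_adj` is `NA` when `n_obs == p`. A fit that never converged is
#'   returned flagged, not raised as an error.
#' @examples
#' pts <- data.frame(temperature = c(15, 20, 25, 27, 30, 34),
#'                   rate = evaluate_model("Briere-1",
#'                     c(a = 3e-4, tmin = 13, tmax = 35.5),
#'                     c(15, 20, 25, 27, 30, 34)))
#' fit_model("Briere-1", pts, n_starts = 16, seed = 1)
#' @export
fit_model <- function(spec, points, n_starts = 64, seed = 1,
                      extra_starts = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  Tv <- points$temperature
  y <- points$rate
  n_obs <- length(y)
  lo <- to_z(spec, spec$lower)
  hi <- to_z(spec, spec$upper)

  resid_fn <- function(z) {
    th <- from_z(spec, z)
    if (!is.null(spec$valid) && !isTRUE(spec$valid(th))) {
      return(rep(1e6, n_obs))
    }
    spec$rate(Tv, th) - y
  }
  obj <- function(z) {
    r <- resid_fn(z)
    if (any(!is.finite(r))) return(1e12)
    sum(r^2)
  }

  starts <- with_seed(seed, lhs_starts(n_starts, lo, hi))
  starts <- rbind(starts, (lo + hi) / 2)
  if (!is.null(extra_starts)) {
    if (is.list(extra_starts)) {
      extra_starts <- do.call(rbind, lapply(extra_starts, function(th)
        to_z(spec, as_theta(spec, th))))
    }
    starts <- rbind(starts, extra_starts)
  }

  cands <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    z0 <- pmin(pmax(starts[i, ], lo), hi)
    res <- tryCatch(
      stats::nlminb(z0, obj, lower = lo, upper = hi,
                    control = list(eval.max = 10000, iter.max = 1000,
                                   rel.tol = 1e-14, x.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective) && res$objective < 1e12) {
      cands[[i]] <- list(z = res$par, rss = res$objective,
                         converged = res$convergence == 0L)
    }
  }
  cands <- Filter(Negate(is.null), cands)

  if (length(cands) == 0L) {
    return(structure(list(model = spec$name,
                          theta = stats::setNames(rep(NA_real_, spec$p),
                                                  spec$params),
                          rss = NA_real_, r2 = NA_real_, r2_adj = NA_real_,
                          aic = NA_real_, n_obs = n_obs, p = spec$p,
                          converged = FALSE,
                          n_starts_tried = nrow(starts),
                          residuals = rep(NA_real_, n_obs),
                          temperature = Tv, observed = y),
                     class = "dev_fit"))
  }

  ord <- order(vapply(cands, `[[`, 0, "rss"))
  best <- NULL
  for (i in ord[seq_len(min(3L, length(ord)))]) {
    pol <- lm_polish(resid_fn, cands[[i]]$z, lo, hi)
    cand <- list(z = pol$z, rss = pol$rss,
                 converged = cands[[i]]$converged || pol$converged)
    if (is.null(best) ||
        cand$rss < best$rss * (1 - 1e-12) ||
        (abs(cand$rss - best$rss) <= 1e-12 * (best$rss + 1e-300) &&
         sum(from_z(spec, cand$z)^2) < sum(from_z(spec, best$z)^2))) {
      best <- cand
    }
  }

  theta <- from_z(spec, best$z)
  valid_ok <- is.null(spec$valid) || isTRUE(spec$valid(theta))
  resid <- spec$rate(Tv, theta) - y
  rss <- sum(resid^2)
  r2 <- tryCatch(suppressWarnings(r2_score(resid, y)), error = function(e)
    NA_real_)
  r2a <- if (is.na(r2)) NA_real_ else r2_adjusted(r2, n_obs, spec$p)
  aic <- if (rss > 0) aic_rss(rss, n_obs, spec$p) else
    suppressWarnings(aic_rss(rss, n_obs, spec$p))

  structure(list(model = spec$name, theta = theta, rss = rss, r2 = r2,
                 r2_adj = r2a, aic = aic, n_obs = n_obs, p = spec$p,
                 converged = isTRUE(best$converged) && valid_ok,
                 n_starts_tried = nrow(starts), residuals = resid,
                 temperature = Tv, observed = y),
            class = "dev_fit")
}

#' @export
print.dev_fit <- function(x, ...) {
  cat(sprintf("<dev_fit> %s  (n = %d, p = %d, converged: %s)\n", x$model,
              x$n_obs, x$p, x$converged))
  cat("  theta:", paste(sprintf("%s = %.6g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g  R2 = %.4f  R2_adj = %s  AIC = %.2f\n", x$rss,
              x$r2, ifelse(is.na(x$r2_adj), "NA", sprintf("%.4f", x$r2_adj)),
              x$aic))
  invisible(x)
}
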