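# Signed power: |x|^p with the sign of x. Rate models built from fractional
# powers (Briere, Analytis) are extended with it beyond their natural domain
# so that the raw curve crosses zero continuously and bisection can bracket
# thresholds; inside the domain it coincides with the ordinary power.
spow <- function(x, p) sign(x) * abs(x)^p

new_model_spec <- function(name, params, lower, upper, rate,
                           kind = "rate_model", duration = NULL,
                           log_scale = rep(FALSE, length(params)),
                           analytic = list(), valid = NULL) {
  stopifnot(length(params) == length(lower), length(lower) == length(upper))
  structure(list(name = name, params = params, p = length(params),
                 lower = stats::setNames(lower, params),
                 upper = stats::setNames(upper, params),
                 log_scale = stats::setNames(log_scale, params),
                 kind = kind, rate = rate, duration = duration,
                 analytic = analytic, valid = valid),
            class = "model_spec")
}

# ordering constraint shared by the threshold-type models: the fitted lower
# threshold must sit below the upper one (rules out mirrored degenerate
# optima where both factors change sign)
tmin_below_tmax <- function(th) th[["tmin"]] < th[["tmax"]]

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s, p = %d)\n", x$name, x$kind, x$p))
  print(data.frame(param = x$params, lower = x$lower, upper = x$upper,
                   row.names = NULL))
  invisible(x)
}

# optimum of a*T*(T - tmin)*(tmax - T)^(1/m): positive root in (tmin, tmax)
# of the quadratic (2m+1)T^2 - (2m*tmax + (m+1)*tmin)T + m*tmin*tmax = 0
briere_topt <- function(tmin, tmax, m) {
  A <- 2 * m + 1
  B <- 2 * m * tmax + (m + 1) * tmin
  C <- m * tmin * tmax
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NA_real_)
  roots <- (B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots[roots > tmin & roots < tmax]
  if (length(inside) == 0) NA_real_ else max(inside)
}

build_registry <- function() {
  specs <- list(

    new_model_spec("Sigmoid", c("a", "b", "c"),
      lower = c(-60, -5, 1e-6), upper = c(60, 5, 5),
      rate = function(T, th) th[["c"]] / (1 + exp(th[["a"]] + th[["b"]] * T))),

    new_model_spec("Logan-6", c("psi", "rho", "delta", "tmax"),
      lower = c(-10, 1e-4, 0.3, 0), upper = c(10, 2, 60, 120),
      rate = function(T, th) {
        th[["psi"]] * (exp(th[["rho"]] * T) -
          exp(th[["rho"]] * th[["tmax"]] - (th[["tmax"]] - T) / th[["delta"]]))
      },
      analytic = list(tmax = function(th) th[["tmax"]])),

    new_model_spec("Logan-10", c("alpha", "rho", "delta", "k", "TL"),
      lower = c(1e-4, 1e-4, 0.3, 1e-2, 0), upper = c(20, 2, 60, 5e4, 120),
      log_scale = c(FALSE, FALSE, FALSE, TRUE, FALSE),
      rate = function(T, th) {
        th[["alpha"]] * (1 / (1 + th[["k"]] * exp(-th[["rho"]] * T)) -
          exp(-(th[["TL"]] - T) / th[["delta"]]))
      }),

    new_model_spec("Lactin-1", c("rho", "tmax", "delta"),
      lower = c(1e-4, 0, 0.3), upper = c(2, 120, 60),
      rate = function(T, th) {
        exp(th[["rho"]] * T) -
          exp(th[["rho"]] * th[["tmax"]] - (th[["tmax"]] - T) / th[["delta"]])
      },
      analytic = list(tmax = function(th) th[["tmax"]])),

    new_model_spec("Lactin-2", c("rho", "tmax", "delta", "lambda"),
      lower = c(1e-4, 0, 0.3, -5), upper = c(2, 120, 60, 5),
      rate = function(T, th) {
        exp(th[["rho"]] * T) -
          exp(th[["rho"]] * th[["tmax"]] - (th[["tmax"]] - T) / th[["delta"]]) +
          th[["lambda"]]
      }),

    new_model_spec("Briere-1", c("a", "tmin", "tmax"),
      lower = c(1e-12, -30, 0), upper = c(1e-1, 60, 120),
      log_scale = c(TRUE, FALSE, FALSE),
      rate = function(T, th) {
        th[["a"]] * T * (T - th[["tmin"]]) * spow(th[["tmax"]] - T, 0.5)
      },
      analytic = list(
        tmin = function(th) th[["tmin"]],
        tmax = function(th) th[["tmax"]],
        topt = function(th) briere_topt(th[["tmin"]], th[["tmax"]], 2)),
      valid = tmin_below_tmax),

    new_model_spec("Briere-2", c("a", "m", "tmin", "tmax"),
      lower = c(1e-12, 0.05, -30, 0), upper = c(1e-1, 12, 60, 120),
      log_scale = c(TRUE, FALSE, FALSE, FALSE),
      rate = function(T, th) {
        th[["a"]] * T * (T - th[["tmin"]]) *
          spow(th[["tmax"]] - T, 1 / th[["m"]])
      },
      analytic = list(
        tmin = function(th) th[["tmin"]],
        tmax = function(th) th[["tmax"]],
        topt = function(th) briere_topt(th[["tmin"]], th[["tmax"]],
                                        th[["m"]])),
      valid = tmin_below_tmax),

    new_model_spec("Polynomial-3rd", c("a", "b", "c", "d"),
      lower = c(-10, -10, -1, -1), upper = c(10, 10, 1, 1),
      rate = function(T, th) {
        th[["a"]] + th[["b"]] * T + th[["c"]] * T^2 + th[["d"]] * T^3
      }),

    new_model_spec("Kontodimas-16", c("a", "tmin", "tmax"),
      lower = c(1e-12, -30, 0), upper = c(1e-1, 60, 120),
      log_scale = c(TRUE, FALSE, FALSE),
      rate = function(T, th) {
        th[["a"]] * (T - th[["tmin"]])^2 * (th[["tmax"]] - T)
      },
      analytic = list(
        tmin = function(th) th[["tmin"]],
        tmax = function(th) th[["tmax"]],
        topt = function(th) (2 * th[["tmax"]] + th[["tmin"]]) / 3),
      valid = tmin_below_tmax),

    # duration model: D(T) = (Dmin/2) (e^{k(T-Topt)} + e^{-lambda(T-Topt)})
    new_model_spec("Janisch", c("Dmin", "k", "lambda", "Topt"),
      lower = c(0.05, -2, -2, -30), upper = c(500, 2, 2, 120),
      kind = "duration_model",
      duration = function(T, th) {
        u <- T - th[["Topt"]]
        (th[["Dmin"]] / 2) * (exp(th[["k"]] * u) + exp(-th[["lambda"]] * u))
      },
      rate = function(T, th) {
        u <- T - th[["Topt"]]
        2 / (th[["Dmin"]] * (exp(th[["k"]] * u) + exp(-th[["lambda"]] * u)))
      }),

    # Gaussian rate curve; optimum is the location parameter
    new_model_spec("Taylor", c("Rm", "Tm", "Tsig"),
      lower = c(1e-6, -30, 0.5), upper = c(5, 120, 60),
      rate = function(T, th) {
        th[["Rm"]] * exp(-0.5 * ((T - th[["Tm"]]) / th[["Tsig"]])^2)
      },
      duration = function(T, th) {
        1 / (th[["Rm"]] * exp(-0.5 * ((T - th[["Tm"]]) / th[["Tsig"]])^2))
      },
      analytic = list(topt = function(th) th[["Tm"]])),

    # logistic ascent mirrored around Topt on the descending side
    new_model_spec("Stinner", c("a", "b", "c", "Topt"),
      lower = c(-60, -5, 1e-6, -30), upper = c(60, 0, 5, 120),
      rate = function(T, th) {
        Tp <- ifelse(T <= th[["Topt"]], T, 2 * th[["Topt"]] - T)
        th[["c"]] / (1 + exp(th[["a"]] + th[["b"]] * Tp))
      },
      analytic = list(topt = function(th) th[["Topt"]])),

    new_model_spec("Hilbert-Logan", c("psi", "T0", "d", "TL", "delta"),
      lower = c(1e-6, -30, 0.01, -30, 0.3), upper = c(20, 120, 200, 150, 60),
      rate = function(T, th) {
        u <- T - th[["T0"]]
        th[["psi"]] * (u^2 / (u^2 + th[["d"]]^2) -
          exp(-(th[["TL"]] - u) / th[["delta"]]))
      }),

    # as published alongside Taylor the two share one Gaussian family; kept
    # as separate registry entries because the source tables report both
    new_model_spec("Lamb", c("Rm", "Tm", "To"),
      lower = c(1e-6, -30, 0.5), upper = c(5, 120, 60),
      rate = function(T, th) {
        th[["Rm"]] * exp(-0.5 * ((T - th[["Tm"]]) / th[["To"]])^2)
      },
      analytic = list(topt = function(th) th[["Tm"]])),

    new_model_spec("Analytis", c("a", "n", "m", "tmin", "tmax"),
      lower = c(1e-25, 0.1, 0.1, -40, 0), upper = c(1e-1, 15, 15, 60, 120),
      log_scale = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      rate = function(T, th) {
        th[["a"]] * spow(T - th[["tmin"]], th[["n"]]) *
          spow(th[["tmax"]] - T, th[["m"]])
      },
      analytic = list(
        tmin = function(th) th[["tmin"]],
        tmax = function(th) th[["tmax"]],
        topt = function(th) {
          (th[["n"]] * th[["tmax"]] + th[["m"]] * th[["tmin"]]) /
            (th[["n"]] + th[["m"]])
        }),
      valid = tmin_below_tmax),

    new_model_spec("Equation-16", c("a", "tmin", "tmax"),
      lower = c(1e-12, -30, 0), upper = c(1e-1, 60, 120),
      log_scale = c(TRUE, FALSE, FALSE),
      rate = function(T, th) {
        th[["a"]] * (T - th[["tmin"]])^2 * (th[["tmax"]] - T)
      },
      analytic = list(
        tmin = function(th) th[["tmin"]],
        tmax = function(th) th[["tmax"]],
        topt = function(th) (2 * th[["tmax"]] + th[["tmin"]]) / 3),
      valid = tmin_below_tmax),

    new_model_spec("Enkegaard", c("a", "b", "c", "d"),
      lower = c(-2, -0.5, -30, -2), upper = c(2, 0.5, 30, 2),
      rate = function(T, th) {
        (th[["a"]] + th[["b"]] * T) * exp(-(th[["c"]] + th[["d"]] * T))
      }),

    # R(T) = a (T - xmax) - b^(T - xmin); xmax anchors the lower intercept
    new_model_spec("Bieri-1", c("a", "b", "xmax", "xmin"),
      lower = c(1e-6, 1.0001, -30, -30), upper = c(1, 10, 120, 120),
      rate = function(T, th) {
        th[["a"]] * (T - th[["xmax"]]) - th[["b"]]^(T - th[["xmin"]])
      },
      analytic = list(topt = function(th) {
        lb <- log(th[["b"]])
        th[["xmin"]] + log(th[["a"]] / lb) / lb
      })),

    # R(T) = a (T - xmin) b^(xmin - T); zero crossing (upper threshold) at xmin
    new_model_spec("Bieri-2", c("a", "b", "xmin"),
      lower = c(-2, 0.01, -30), upper = c(2, 0.9999, 120),
      rate = function(T, th) {
        th[["a"]] * (T - th[["xmin"]]) * th[["b"]]^(th[["xmin"]] - T)
      },
      analytic = list(
        tmax = function(th) th[["xmin"]],
        topt = function(th) th[["xmin"]] + 1 / log(th[["b"]]))),

    # six-parameter biophysical form; temperatures handled in Kelvin
    # internally, enthalpies in cal/mol (gas constant 1.987 cal/mol/K)
    new_model_spec("Sharpe-DeMichele",
      c("phi", "dHA", "dHL", "TLk", "dHH", "THk"),
      lower = c(1e-6, 1e2, -8e5, 260, 1e2, 280),
      upper = c(50, 1e5, -1e2, 310, 8e5, 340),
      log_scale = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      rate = function(T, th) {
        R <- 1.987
        TK <- T + 273.15
        num <- th[["phi"]] * (TK / 298.15) *
          exp(th[["dHA"]] / R * (1 / 298.15 - 1 / TK))
        den <- 1 + exp(th[["dHL"]] / R * (1 / th[["TLk"]] - 1 / TK)) +
          exp(th[["dHH"]] / R * (1 / th[["THk"]] - 1 / TK))
        num / den
      },
      valid = function(th) th[["TLk"]] < th[["THk"]])
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

.registry_env <- new.env(parent = emptyenv())

#' The catalog of non-linear development-rate models
#'
#' Returns the twenty classical temperature-development-rate models used for
#' thermal-performance analysis of ectotherm development: Sigmoid, Logan-6,
#' Logan-10, Lactin-1, Lactin-2, Briere-1, Briere-2, Polynomial-3rd,
#' Kontodimas-16, Janisch, Taylor, Stinner, Hilbert-Logan, Lamb, Analytis,
#' Equation-16, Enkegaard, Bieri-1, Bieri-2 and Sharpe-DeMichele. Each entry
#' carries ordered parameter names, box bounds wide enough for realistic
#' insect data, the parameter count used by AIC and adjusted R2, and any
#' closed-form cardinal-temperature rules. Janisch is parameterized as a
#' duration model; its `evaluate()` value is the reciprocal rate.
#' Equation-16 and Kontodimas-16 share one functional form (as do Lamb and
#' Taylor); they are kept as distinct catalog entries.
#'
#' @return Named list of `model_spec` objects, length 20.
#' @examples
#' names(model_registry())
#' model_registry()[["Briere-2"]]
#' @export
model_registry <- function() {
  if (is.null(.registry_env$registry)) {
    .registry_env$registry <- build_registry()
  }
  .registry_env$registry
}

#' Look up one model specification by name
#'
#' @param name model name as listed by [model_registry()].
#' @return A `model_spec`.
#' @export
model_spec <- function(name) {
  reg <- model_registry()
  if (!name %in% names(reg)) {
    stop("unknown model name: ", name, "; known: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

as_theta <- function(spec, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != spec$p) {
      stop(sprintf("model %s expects %d parameters, got %d", spec$name,
                   spec$p, length(theta)), call. = FALSE)
    }
    theta <- stats::setNames(as.numeric(theta), spec$params)
  } else {
    missing_p <- setdiff(spec$params, names(theta))
    if (length(missing_p) > 0L) {
      stop(sprintf("model %s missing parameters: %s", spec$name,
                   paste(missing_p, collapse = ", ")), call. = FALSE)
    }
    theta <- stats::setNames(as.numeric(theta[spec$params]), spec$params)
  }
  theta
}

#' Evaluate a development-rate model
#'
#' Vectorized evaluation of a catalog model at temperatures `T`. Duration
#' models are returned on the rate scale (1/D). The raw signed value is
#' returned by default so that root-finding can bracket zero crossings;
#' `clip = TRUE` truncates negative rates to zero.
#'
#' @param spec a `model_spec` or a model name.
#' @param theta numeric parameter vector, named or in catalog order.
#' @param T numeric vector of temperatures (degrees C).
#' @param clip logical, truncate negative rates to 0.
#' @return Numeric vector of development rates (1/day).
#' @examples
#' evaluate_model("Briere-1", c(a = 30.51e-5, tmin = 13.48, tmax = 35), T = 25)
#' @export
evaluate_model <- function(spec, theta, T, clip = FALSE) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  r <- spec$rate(T, theta)
  if (clip) r <- pmax(r, 0)
  r
}

#' Evaluate a duration-form model
#'
#' For models that carry a native duration form (Janisch, Taylor, Lamb) this
#' returns D(T) in days; for every other model it returns the reciprocal of
#' the rate. Wherever D(T) > 0, `D * evaluate_model(...) = 1`.
#'
#' @inheritParams evaluate_model
#' @return Numeric vector of development durations (days).
#' @export
evaluate_duration <- function(spec, theta, T) {
  if (is.character(spec)) spec <- model_spec(spec)
  theta <- as_theta(spec, theta)
  if (!is.null(spec$duration)) spec$duration(T, theta) else
    1 / spec$rate(T, theta)
}

#' Export the model catalog as a machine-readable manifest
#'
#' One row per (model, parameter): model name, kind, parameter count, the
#' parameter's name, order and box bounds. Writable as plain delimited text
#' for interoperability with other tools.
#'
#' @param path optional file to write (tab-separated); when `NULL` the
#'   manifest is only returned.
#' @return A data frame manifest, invisibly when written.
#' @export
model_manifest <- function(path = NULL) {
  reg <- model_registry()
  man <- do.call(rbind, lapply(reg, function(s) {
    data.frame(model = s$name, kind = s$kind, p = s$p, param = s$params,
               order = seq_len(s$p), lower = unname(s$lower),
               upper = unname(s$upper), stringsAsFactors = FALSE)
  }))
  rownames(man) <- NULL
  if (!is.null(path)) {
    utils::write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(man))
  }
  man
}
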