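#' Configuration for the synthetic-cohort generator
#'
#' Describes a simulated constant-temperature development experiment shaped
#' like the classical stage-resolved design: a true rate model, the constant
#' temperatures, a cohort size per temperature, individual-level noise, and
#' optional complete-failure temperatures. Individual durations are drawn
#' lognormal with median 1/rate(T) and a stated coefficient of variation
#' (default 0.1, which reproduces the SE/mean magnitudes seen in published
#' cohort tables).
#'
#' @param model catalog model name (see [model_registry()]).
#' @param theta true parameter vector.
#' @param temps constant temperatures, degrees C (distinct).
#' @param n_per_temp individuals per temperature (>= 1).
#' @param noise `"lognormal_cv"` or `"none"`.
#' @param cv coefficient of variation of individual durations (>= 0).
#' @param failure_temps temperatures emitted as complete-failure records.
#' @param seed integer RNG seed.
#' @param stage,sex labels stamped on the generated observations.
#' @param daily_census logical; when `TRUE`, individual durations are
#'   rounded to whole days to emulate daily observation (off by default:
#'   rounding breaks noise-free recovery).
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(model, theta, temps, n_per_temp = 60,
                       noise = c("lognormal_cv", "none"), cv = 0.1,
                       failure_temps = numeric(0), seed = 1,
                       stage = "total", sex = "pooled",
                       daily_census = FALSE) {
  noise <- match.arg(noise)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (anyDuplicated(temps)) stop("temperatures must be distinct",
                                 call. = FALSE)
  if (n_per_temp < 1L) stop("n_per_temp must be >= 1", call. = FALSE)
  structure(list(model = model, theta = theta, temps = temps,
                 n_per_temp = n_per_temp, noise = noise, cv = cv,
                 failure_temps = failure_temps, seed = seed, stage = stage,
                 sex = sex, daily_census = daily_census),
            class = "sim_config")
}

draw_cohort <- function(median_days, n, noise, cv, daily_census) {
  if (noise == "none") {
    d <- rep(median_days, n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    d <- stats::rlnorm(n, meanlog = log(median_days), sdlog = sdlog)
  }
  if (daily_census) d <- pmax(round(d), 1)
  d
}

#' Simulate a stage-resolved development dataset from a rate model
#'
#' Draws individual development durations at each configured temperature
#' (lognormal around the model's median duration 1/rate(T), or exactly the
#' median when `noise = "none"`), summarizes them as per-temperature mean,
#' SE and n, and emits configured failure temperatures as
#' `developed = FALSE` records. Deterministic for a given seed.
#'
#' @param cfg a [sim_config()].
#' @return A [dev_dataset].
#' @examples
#' cfg <- sim_config("Briere-2",
#'                   c(a = 1.82e-4, m = 1.68, tmin = 11.24, tmax = 38.8),
#'                   temps = c(15, 20, 25, 27, 30, 34), noise = "none")
#' simulate_development(cfg)
#' @export
simulate_development <- function(cfg) {
  rates <- evaluate_model(cfg$model, cfg$theta, cfg$temps)
  bad <- which(!is.finite(rates) | rates <= 0)
  if (length(bad) > 0L) {
    stop("configuration error: rate <= 0 at temperature(s) ",
         paste(cfg$temps[bad], collapse = ", "), call. = FALSE)
  }
  with_seed(cfg$seed, {
    rows <- lapply(seq_along(cfg$temps), function(i) {
      d <- draw_cohort(1 / rates[i], cfg$n_per_temp, cfg$noise, cfg$cv,
                       cfg$daily_census)
      data.frame(stage = cfg$stage, sex = cfg$sex,
                 temperature_C = cfg$temps[i], mean_days = mean(d),
                 se_days = if (length(d) > 1L) stats::sd(d) / sqrt(length(d))
                           else 0,
                 n = length(d), developed = TRUE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (length(cfg$failure_temps) > 0L) {
      df <- rbind(df, data.frame(stage = cfg$stage, sex = cfg$sex,
                                 temperature_C = cfg$failure_temps,
                                 mean_days = NA_real_, se_days = NA_real_,
                                 n = 0L, developed = FALSE,
                                 stringsAsFactors = FALSE))
    }
    dev_dataset(df$stage, df$sex, df$temperature_C, df$mean_days, df$se_days,
                df$n, df$developed,
                label = sprintf("simulated from %s (seed %d)", cfg$model,
                                cfg$seed))
  })
}

#' Simulate development data from an exact degree-day line
#'
#' Durations follow the hyperbola D = K / (T - T0) (so that rate is exactly
#' linear in temperature), with the same individual-level noise options as
#' [simulate_development()]. Useful for exact-recovery tests of the two
#' linear estimators.
#'
#' @param T0 lower threshold, degrees C.
#' @param K thermal constant, degree-days.
#' @param temps constant temperatures, all > `T0`.
#' @param n_per_temp individuals per temperature.
#' @param noise `"none"` or `"lognormal_cv"`.
#' @param cv coefficient of variation of individual durations.
#' @param seed integer RNG seed.
#' @param stage,sex labels for the generated rows.
#' @return A [dev_dataset].
#' @examples
#' simulate_linear_development(11.96, 187.87, temps = c(15, 20, 25, 27),
#'                             noise = "none")
#' @export
simulate_linear_development <- function(T0, K, temps, n_per_temp = 60,
                                        noise = c("none", "lognormal_cv"),
                                        cv = 0.1, seed = 1,
                                        stage = "total", sex = "pooled") {
  noise <- match.arg(noise)
  if (any(temps <= T0)) {
    stop("configuration error: temperature(s) ",
         paste(temps[temps <= T0], collapse = ", "),
         " not above the threshold T0 = ", T0, call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(temps, function(Tc) {
      d <- draw_cohort(K / (Tc - T0), n_per_temp, noise, cv, FALSE)
      data.frame(stage = stage, sex = sex, temperature_C = Tc,
                 mean_days = mean(d),
                 se_days = if (length(d) > 1L) stats::sd(d) / sqrt(length(d))
                           else 0,
                 n = length(d), developed = TRUE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    dev_dataset(df$stage, df$sex, df$temperature_C, df$mean_days, df$se_days,
                df$n, df$developed,
                label = sprintf("simulated degree-day line (T0 = %g, K = %g)",
                                T0, K))
  })
}
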