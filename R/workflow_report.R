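#' Pipeline configuration
#'
#' Assembles the declarative configuration for [run_pipeline()]: which
#' stages and sex slice to analyse, the quasi-linear range used by the two
#' linear estimators, the range for non-linear fits (developmental-failure
#' temperatures are excluded by construction since failure rows carry no
#' duration), the model list, the optimum-grid resolution, the multistart
#' budget and the seed.
#'
#' @param stages life stages to analyse.
#' @param sex `"pooled"` (default: female and male cells are pooled by
#'   cohort-weighted means), `"female"` or `"male"`.
#' @param linear_range closed temperature interval for the linear models;
#'   the default 15-27 degrees C drops the high-temperature treatments where
#'   rate-temperature data leave the linear regime.
#' @param nonlinear_range closed interval for non-linear fits.
#' @param models character vector of catalog model names.
#' @param grid_step optimum-grid resolution, degrees C.
#' @param seed integer seed controlling every multistart design.
#' @param n_starts Latin-hypercube starts per model fit.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("egg", "larva", "pupa", "total"),
                            sex = "pooled",
                            linear_range = c(15, 27),
                            nonlinear_range = c(15, 34),
                            models = names(model_registry()),
                            grid_step = 0.25, seed = 1, n_starts = 64) {
  structure(list(stages = stages, sex = sex, linear_range = linear_range,
                 nonlinear_range = nonlinear_range, models = models,
                 grid_step = grid_step, seed = seed, n_starts = n_starts),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as key-value text
#'
#' Plain `key = value` lines (comma-separated for vectors); unknown keys are
#' rejected.
#'
#' @param path file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  cfg <- pipeline_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown config key: ", k, call. = FALSE)
    v <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(v))
    cfg[[k]] <- if (all(!is.na(num))) num else v
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_starts <- as.integer(cfg$n_starts)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full thermal-development analysis
#'
#' For every requested stage: fits the common degree-day and Ikemoto-Takai
#' linear models over the linear range, fits every catalog model to the
#' stage's rate points over the non-linear range by seeded multistart least
#' squares, extracts cardinal temperatures from each fit, and ranks the
#' models by AIC. Per-model failures are recorded in the fit objects
#' (`converged = FALSE`), never abort the batch. The result is deterministic
#' for a given configuration.
#'
#' @param ds a [dev_dataset].
#' @param config a [pipeline_config()].
#' @return List of class `dev_pipeline` with elements `linear` (list of
#'   stage -> list(common, ikemoto_takai)), `fits` (stage -> model ->
#'   `dev_fit`), `cardinals` (stage -> model -> `cardinal_temps`),
#'   `rankings` (stage -> data frame), and `config`.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(stethorus_table2(),
#'                        pipeline_config(stages = "total", n_starts = 16))
#' bundle$rankings$total
#' }
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  if (length(config$models) == 0L) {
    warning("empty model list: returning empty bundle")
    return(structure(list(linear = list(), fits = list(), cardinals = list(),
                          rankings = list(), config = config),
                     class = "dev_pipeline"))
  }
  df <- as.data.frame(ds)
  if (config$sex == "pooled" && !any(df$sex == "pooled" & df$developed)) {
    ds <- pool_sexes(ds)
  }
  linear <- list(); fits <- list(); cardinals <- list(); rankings <- list()
  for (stage in config$stages) {
    pts_lin <- tryCatch(
      dev_rates(ds, stage, config$sex, range = config$linear_range),
      error = function(e) NULL)
    lin <- list(common = NULL, ikemoto_takai = NULL)
    if (!is.null(pts_lin)) {
      lin$common <- tryCatch(fit_common_linear(pts_lin),
                             error = function(e) e$message)
      lin$ikemoto_takai <- tryCatch(
        fit_ikemoto_takai(data.frame(temperature = pts_lin$temperature,
                                     mean_days = pts_lin$mean_days)),
        error = function(e) e$message)
    }
    linear[[stage]] <- lin

    pts <- tryCatch(
      dev_rates(ds, stage, config$sex, range = config$nonlinear_range),
      error = function(e) NULL)
    stage_fits <- list(); stage_cards <- list()
    if (!is.null(pts)) {
      for (m in config$models) {
        f <- tryCatch(
          fit_model(m, pts, n_starts = config$n_starts, seed = config$seed),
          error = function(e) NULL)
        if (is.null(f)) next
        stage_fits[[m]] <- f
        if (f$converged && all(is.finite(f$theta))) {
          stage_cards[[m]] <- tryCatch(
            cardinal_temps(m, f$theta, grid_step = config$grid_step),
            error = function(e) NULL)
        }
      }
    }
    fits[[stage]] <- stage_fits
    cardinals[[stage]] <- stage_cards
    rankings[[stage]] <- tryCatch(rank_models(stage_fits),
                                  error = function(e) NULL)
  }
  structure(list(linear = linear, fits = fits, cardinals = cardinals,
                 rankings = rankings, config = config),
            class = "dev_pipeline")
}

#' Rank fitted models by AIC
#'
#' Converged fits sorted by ascending AIC; ties are broken by fewer
#' parameters, then by model name. The adjusted-R2 ranking is attached as a
#' secondary column.
#'
#' @param fits named list of `dev_fit` objects for one stage.
#' @return Data frame with columns `model`, `p`, `rss`, `r2`, `r2_adj`,
#'   `aic`, `rank_aic`, `rank_r2adj`, sorted by `rank_aic`.
#' @export
rank_models <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$rss), fits)
  if (length(fits) == 0L) {
    warning("no converged fits to rank")
    return(data.frame(model = character(0), p = integer(0), rss = numeric(0),
                      r2 = numeric(0), r2_adj = numeric(0), aic = numeric(0),
                      rank_aic = integer(0), rank_r2adj = integer(0)))
  }
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, p = f$p, rss = f$rss, r2 = f$r2,
               r2_adj = f$r2_adj, aic = f$aic, stringsAsFactors = FALSE)
  }))
  ord <- order(df$aic, df$p, df$model)
  df <- df[ord, , drop = FALSE]
  df$rank_aic <- seq_len(nrow(df))
  df$rank_r2adj <- rank(-df$r2_adj, ties.method = "min", na.last = "keep")
  rownames(df) <- NULL
  df
}

#' Forecast stage completion by degree-day accumulation
#'
#' Accumulates daily degree-days above the lower threshold with the simple
#' daily-average method, `max(T_d - T0, 0)` per day and no upper cutoff, and
#' reports the first day on which the running total reaches the thermal
#' constant K.
#'
#' @param T0 lower developmental threshold, degrees C.
#' @param K thermal constant, degree-days (> 0).
#' @param temps numeric vector of daily mean temperatures, degrees C.
#' @return Object of class `emergence_forecast`: list with `T0`, `K`,
#'   `temps`, `dd` (daily increments), `accumulated`, `completion_day`
#'   (`NA` when the series is exhausted first) and `total`.
#' @examples
#' forecast_emergence(11.96, 187.87, rep(27, 20))
#' @export
forecast_emergence <- function(T0, K, temps) {
  if (!is.finite(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  dd <- pmax(temps - T0, 0)
  acc <- cumsum(dd)
  idx <- which(acc >= K)
  structure(list(T0 = T0, K = K, temps = temps, dd = dd, accumulated = acc,
                 completion_day = if (length(idx)) idx[1L] else NA_integer_,
                 total = if (length(acc)) acc[length(acc)] else 0),
            class = "emergence_forecast")
}

#' @export
print.emergence_forecast <- function(x, ...) {
  if (is.na(x$completion_day)) {
    cat(sprintf(
      "<emergence_forecast> not reached: %.1f of %.1f DD after %d days\n",
      x$total, x$K, length(x$temps)))
  } else {
    cat(sprintf(
      "<emergence_forecast> completion on day %d (%.1f DD accumulated, K = %.1f)\n",
      x$completion_day, x$accumulated[x$completion_day], x$K))
  }
  invisible(x)
}

#' Write pipeline report tables
#'
#' Emits four delimited tables mirroring the conventional reporting layout
#' of thermal-development studies: `table3.csv` (linear-model constants per
#' stage), `table4.csv` (long-format non-linear parameter estimates),
#' `table5.csv` (goodness-of-fit per model and stage) and `table6.csv`
#' (cardinal-temperature summary), plus optional per-stage overlay plots of
#' observed rates and fitted curves (`<stage>.png`).
#'
#' @param bundle a `dev_pipeline` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @param plots logical; write per-stage PNG overlays.
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(bundle, out_dir, plots = FALSE) {
  if (length(bundle$fits) == 0L) stop("empty bundle", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  lin <- list()
  for (stage in names(bundle$linear)) {
    for (m in c("common", "ikemoto_takai")) {
      f <- bundle$linear[[stage]][[m]]
      if (inherits(f, "thermal_constants")) lin[[paste(stage, m)]] <- f
    }
  }
  t3 <- thermal_constants_table(lin)
  t3$stage <- vapply(strsplit(names(lin), " "), `[[`, "", 1L)
  p3 <- file.path(out_dir, "table3.csv")
  utils::write.csv(t3, p3, row.names = FALSE)
  files <- c(files, p3)

  t4 <- do.call(rbind, lapply(names(bundle$fits), function(stage) {
    do.call(rbind, lapply(bundle$fits[[stage]], function(f) {
      data.frame(stage = stage, model = f$model, parameter = names(f$theta),
                 estimate = unname(f$theta), stringsAsFactors = FALSE)
    }))
  }))
  p4 <- file.path(out_dir, "table4.csv")
  utils::write.csv(t4, p4, row.names = FALSE)
  files <- c(files, p4)

  t5 <- do.call(rbind, lapply(names(bundle$fits), function(stage) {
    do.call(rbind, lapply(bundle$fits[[stage]], function(f) {
      data.frame(stage = stage, model = f$model, p = f$p, n = f$n_obs,
                 rss = f$rss, r2 = f$r2, r2_adj = f$r2_adj, aic = f$aic,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
  }))
  p5 <- file.path(out_dir, "table5.csv")
  utils::write.csv(t5, p5, row.names = FALSE)
  files <- c(files, p5)

  t6 <- do.call(rbind, lapply(names(bundle$cardinals), function(stage) {
    do.call(rbind, lapply(bundle$cardinals[[stage]], function(ct) {
      data.frame(stage = stage, model = ct$model, t_min = ct$t_min,
                 t_min_method = unname(ct$methods["t_min"]),
                 t_opt = ct$t_opt,
                 t_opt_method = unname(ct$methods["t_opt"]),
                 t_max = ct$t_max,
                 t_max_method = unname(ct$methods["t_max"]),
                 tmax_plausible = ct$tmax_plausible,
                 stringsAsFactors = FALSE)
    }))
  }))
  p6 <- file.path(out_dir, "table6.csv")
  utils::write.csv(t6, p6, row.names = FALSE)
  files <- c(files, p6)

  if (plots) {
    for (stage in names(bundle$fits)) {
      pf <- file.path(out_dir, paste0(stage, ".png"))
      grDevices::png(pf, width = 900, height = 700)
      tryCatch(plot_stage_fits(bundle, stage), finally = grDevices::dev.off())
      files <- c(files, pf)
    }
  }
  invisible(files)
}

#' Overlay observed rates and fitted curves for one stage
#'
#' @param bundle a `dev_pipeline`.
#' @param stage stage name present in the bundle.
#' @param models subset of models to draw (default: all fitted).
#' @export
plot_stage_fits <- function(bundle, stage, models = NULL) {
  fits <- bundle$fits[[stage]]
  if (is.null(fits) || length(fits) == 0L) stop("no fits for stage ", stage)
  if (is.null(models)) models <- names(fits)
  f1 <- fits[[1L]]
  Tg <- seq(min(f1$temperature) - 2, max(f1$temperature) + 4, by = 0.1)
  graphics::plot(f1$temperature, f1$observed, pch = 16,
                 xlab = "Temperature (°C)",
                 ylab = "Development rate (1/day)",
                 main = paste("Stage:", stage),
                 ylim = c(0, max(f1$observed) * 1.3))
  cols <- grDevices::rainbow(length(models))
  for (i in seq_along(models)) {
    f <- fits[[models[i]]]
    if (is.null(f) || !f$converged) next
    graphics::lines(Tg, evaluate_model(f$model, f$theta, Tg, clip = TRUE),
                    col = cols[i])
  }
  graphics::legend("topleft", legend = models, col = cols, lty = 1,
                   cex = 0.6, ncol = 2, bty = "n")
  invisible(NULL)
}
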