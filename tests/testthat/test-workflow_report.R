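stub_fit <- function(model, p, aic, r2_adj = NA_real_, rss = 1e-4) {
  structure(list(model = model, p = p, rss = rss, r2 = NA_real_,
                 r2_adj = r2_adj, aic = aic, n_obs = 6L, converged = TRUE),
            class = "dev_fit")
}

test_that("models rank by ascending AIC with p-then-name tie-breaks", {
  # published total-development AIC values: Sigmoid above Stinner above
  # Logan-10
  fits <- list(stub_fit("Stinner", 4, -71.20, 0.9949),
               stub_fit("Sigmoid", 3, -73.20, 0.9948),
               stub_fit("Logan-10", 5, -69.08, 0.9780))
  rk <- rank_models(fits)
  expect_equal(rk$model, c("Sigmoid", "Stinner", "Logan-10"))
  expect_equal(rk$rank_aic, 1:3)

  expect_equal(rank_models(list(stub_fit("Lamb", 3, -50)))$rank_aic, 1L)

  tie <- rank_models(list(stub_fit("Briere-2", 4, -60),
                          stub_fit("Taylor", 3, -60)))
  expect_equal(tie$model[1], "Taylor")  # fewer parameters wins the tie

  noconv <- list(structure(list(model = "x", converged = FALSE,
                                rss = NA_real_), class = "dev_fit"))
  expect_warning(empty <- rank_models(noconv), "no converged")
  expect_equal(nrow(empty), 0L)
})

test_that("degree-day forecasting finds the first completion day", {
  f <- forecast_emergence(11.96, 187.87, rep(27, 30))
  expect_equal(f$completion_day, 13L)       # ceil(187.87 / 15.04)
  expect_true(all(diff(f$accumulated) >= 0))

  cold <- forecast_emergence(10, 100, rep(5, 10))
  expect_true(is.na(cold$completion_day))
  expect_equal(cold$total, 0)

  expect_equal(forecast_emergence(10, 5, c(20, 20))$completion_day, 1L)
  expect_error(forecast_emergence(10, -1, 20), "K must be")

  # constant-temperature identity: completion = ceil(K / (T - T0))
  set.seed(31)
  for (i in 1:25) {
    T0 <- runif(1, 5, 15); K <- runif(1, 20, 400); Tc <- T0 + runif(1, 2, 20)
    f <- forecast_emergence(T0, K, rep(Tc, 1000))
    expect_equal(f$completion_day, as.integer(ceiling(K / (Tc - T0))))
  }
})

test_that("the pipeline produces cross-linked, deterministic bundles", {
  cfg <- pipeline_config(stages = c("egg", "total"),
                         models = c("Briere-2", "Lactin-1", "Sigmoid"),
                         n_starts = 16, seed = 2)
  b1 <- run_pipeline(stethorus_table2(), cfg)
  expect_setequal(names(b1$fits), c("egg", "total"))
  for (s in names(b1$fits)) {
    expect_setequal(names(b1$fits[[s]]), cfg$models)
    expect_s3_class(b1$linear[[s]]$common, "thermal_constants")
    expect_s3_class(b1$linear[[s]]$ikemoto_takai, "thermal_constants")
    expect_equal(nrow(b1$rankings[[s]]),
                 sum(vapply(b1$fits[[s]], function(f) f$converged, TRUE)))
  }
  b2 <- run_pipeline(stethorus_table2(), cfg)
  expect_identical(b1$fits$total$`Briere-2`$theta,
                   b2$fits$total$`Briere-2`$theta)

  expect_warning(eb <- run_pipeline(stethorus_table2(),
                                    pipeline_config(models = character(0))),
                 "empty model list")
  expect_length(eb$fits, 0L)
})

test_that("report tables are written and rankings round-trip", {
  cfg <- pipeline_config(stages = "total",
                         models = c("Briere-2", "Sigmoid", "Taylor"),
                         n_starts = 16, seed = 2)
  b <- run_pipeline(stethorus_table2(), cfg)
  out <- tempfile("report")
  on.exit(unlink(out, recursive = TRUE))
  files <- render_tables(b, out)
  expect_true(all(file.exists(file.path(out, paste0("table", 3:6, ".csv")))))
  expect_false(any(grepl("[.]png$", list.files(out))))

  t5 <- read.csv(file.path(out, "table5.csv"))
  rk <- b$rankings$total
  expect_equal(t5$aic[match(rk$model, t5$model)], rk$aic, tolerance = 1e-12)

  t3 <- read.csv(file.path(out, "table3.csv"))
  expect_equal(t3$T0[t3$method == "ikemoto_takai"],
               b$linear$total$ikemoto_takai$T0, tolerance = 1e-12)
})

test_that("config files round-trip through key-value text", {
  cfg <- pipeline_config(stages = c("egg", "pupa"), sex = "female",
                         linear_range = c(15, 27), n_starts = 32, seed = 9,
                         models = c("Briere-2", "Lamb"))
  p <- tempfile(fileext = ".cfg")
  on.exit(unlink(p))
  write_pipeline_config(cfg, p)
  back <- read_pipeline_config(p)
  expect_equal(back$stages, cfg$stages)
  expect_equal(back$models, cfg$models)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$linear_range, cfg$linear_range)
  writeLines("bogus_key = 1", p)
  expect_error(read_pipeline_config(p), "unknown config key")
})

test_that("noise-free data from a known model rank that model first", {
  # scaled-down replicate count; ties allowed within the duplicate pairs
  # {Equation-16, Kontodimas-16} and {Lamb, Taylor}
  duplicates <- list(
    "Equation-16" = c("Equation-16", "Kontodimas-16"),
    "Kontodimas-16" = c("Equation-16", "Kontodimas-16"),
    "Lamb" = c("Lamb", "Taylor"), "Taylor" = c("Lamb", "Taylor"))
  gens <- c("Briere-2", "Lactin-2", "Kontodimas-16", "Taylor")
  temps <- c(15, 20, 25, 27, 30, 34)
  hits <- 0L; total <- 0L
  for (g in gens) {
    th <- recovery_truth[[g]]
    ds <- simulate_development(sim_config(g, th, temps, noise = "none",
                                          seed = 77))
    for (seed in c(101, 202)) {
      b <- run_pipeline(ds, pipeline_config(stages = "total",
                                            n_starts = 16, seed = seed))
      top <- b$rankings$total$model[1]
      ok_set <- if (g %in% names(duplicates)) duplicates[[g]] else g
      total <- total + 1L
      if (top %in% ok_set) hits <- hits + 1L
    }
  }
  expect_gte(hits, total - 1L)
})
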