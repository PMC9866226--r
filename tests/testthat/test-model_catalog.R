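test_that("the registry holds the twenty catalog models with their p", {
  reg <- model_registry()
  expect_length(reg, 20L)
  expected_p <- c("Sigmoid" = 3, "Logan-6" = 4, "Logan-10" = 5,
                  "Lactin-1" = 3, "Lactin-2" = 4, "Briere-1" = 3,
                  "Briere-2" = 4, "Polynomial-3rd" = 4, "Kontodimas-16" = 3,
                  "Janisch" = 4, "Taylor" = 3, "Stinner" = 4,
                  "Hilbert-Logan" = 5, "Lamb" = 3, "Analytis" = 5,
                  "Equation-16" = 3, "Enkegaard" = 4, "Bieri-1" = 4,
                  "Bieri-2" = 3, "Sharpe-DeMichele" = 6)
  expect_setequal(names(reg), names(expected_p))
  for (m in names(expected_p)) {
    expect_equal(reg[[m]]$p, unname(expected_p[m]), label = m)
    expect_length(reg[[m]]$params, reg[[m]]$p)
  }
  expect_error(model_spec("NoSuchModel"), "unknown model")
})

test_that("evaluation matches direct arithmetic for the Briere family", {
  th <- table4_theta$briere1_egg
  # factor (T - tmin) vanishes at the lower threshold
  expect_equal(evaluate_model("Briere-1", th, 13.48), 0)
  oracle <- 30.51e-5 * 25 * (25 - 13.48) * sqrt(35 - 25)
  expect_equal(evaluate_model("Briere-1", th, 25), oracle)
  expect_equal(round(oracle, 4), 0.2779)
  # vectorized evaluation and clipping beyond the upper threshold
  v <- evaluate_model("Briere-1", th, c(10, 25, 36), clip = TRUE)
  expect_equal(v[3], 0)
  expect_error(evaluate_model("Briere-1", th[1:2], 25), "parameters")
})

test_that("Logan-10 is negative at its asymptote parameter TL", {
  th <- table4_theta$logan10_total
  expect_lt(evaluate_model("Logan-10", th, th[["TL"]]), 0)
  # and equals the documented closed expression there
  direct <- th[["alpha"]] *
    (1 / (1 + th[["k"]] * exp(-th[["rho"]] * th[["TL"]])) - 1)
  expect_equal(evaluate_model("Logan-10", th, th[["TL"]]), direct)
})

test_that("Equation-16 and Kontodimas-16 are the same functional form", {
  th <- table4_theta$eq16_egg
  Tg <- seq(0, 45, by = 0.5)
  expect_equal(evaluate_model("Equation-16", th, Tg),
               evaluate_model("Kontodimas-16", th, Tg))
})

test_that("threshold-type models are unimodal between their thresholds", {
  cases <- list(
    list("Briere-1", table4_theta$briere1_egg, c(13.6, 34.9)),
    list("Briere-2", table4_theta$briere2_pupa, c(11.4, 38.7)),
    list("Kontodimas-16", table4_theta$eq16_egg, c(10.8, 39.5)),
    list("Equation-16", table4_theta$eq16_egg, c(10.8, 39.5)),
    list("Lactin-1", table4_theta$lactin1_total, c(0, 38.1)),
    list("Lactin-2", table4_theta$lactin2_total, c(13.1, 46.6)),
    list("Logan-10", table4_theta$logan10_total, c(0, 44)),
    list("Logan-6", recovery_truth[["Logan-6"]], c(0, 37.9)))
  for (cs in cases) {
    Tg <- seq(cs[[3]][1], cs[[3]][2], length.out = 400)
    v <- evaluate_model(cs[[1]], cs[[2]], Tg)
    d <- diff(v)
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_equal(sign_changes, 1L, label = cs[[1]])
  }
})

test_that("duration-form models satisfy D(T) * rate(T) = 1 where D > 0", {
  Tg <- seq(10, 40, by = 1)
  for (m in c("Janisch", "Taylor", "Lamb")) {
    th <- recovery_truth[[m]]
    D <- evaluate_duration(m, th, Tg)
    r <- evaluate_model(m, th, Tg)
    keep <- is.finite(D) & D > 0
    expect_true(any(keep))
    expect_equal(D[keep] * r[keep], rep(1, sum(keep)), label = m)
  }
})

test_that("parameter counts reproduce the published R2 -> adjusted-R2 pairs", {
  # printed (R2, R2_adj) pairs for total development; n = 6 temperature means
  pairs <- list(
    "Sigmoid"        = c(0.9969, 0.9948), "Logan-6"       = c(0.9493, 0.8732),
    "Logan-10"       = c(0.9956, 0.9780), "Lactin-2"      = c(0.9776, 0.9440),
    "Briere-1"       = c(0.7871, 0.6451), "Briere-2"      = c(0.9923, 0.9807),
    "Polynomial-3rd" = c(0.9924, 0.9810), "Kontodimas-16" = c(0.9880, 0.9801),
    "Equation-16"    = c(0.9880, 0.9801), "Janisch"       = c(0.9743, 0.9358),
    "Taylor"         = c(0.9825, 0.9708), "Hilbert-Logan" = c(0.9937, 0.9686),
    "Lamb"           = c(0.9825, 0.9708), "Analytis"      = c(0.9848, 0.9241),
    "Enkegaard"      = c(0.9492, 0.8732), "Bieri-1"       = c(0.9915, 0.9792),
    "Bieri-2"        = c(0.9492, 0.9154))
  reg <- model_registry()
  n_ok <- 0L
  for (m in names(pairs)) {
    got <- r2_adjusted(pairs[[m]][1], 6, reg[[m]]$p)
    if (abs(got - pairs[[m]][2]) <= 5e-4) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 16L)
})

test_that("the manifest lists every model parameter with finite bounds", {
  man <- model_manifest()
  expect_setequal(unique(man$model), names(model_registry()))
  expect_true(all(is.finite(man$lower) & is.finite(man$upper)))
  expect_true(all(man$lower < man$upper))
  expect_equal(sum(vapply(model_registry(), `[[`, 0, "p")), nrow(man))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  model_manifest(tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(man))
})
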