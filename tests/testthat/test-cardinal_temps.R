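test_that("grid-argmax optimum matches the published quarter-degree reads", {
  expect_equal(find_topt("Briere-1", table4_theta$briere1_egg)$topt, 29.75)
  expect_equal(find_topt("Equation-16", table4_theta$eq16_egg)$topt, 30.00)
  # refined value agrees with the Briere closed form to < 1e-3
  cf <- model_spec("Briere-1")$analytic$topt(table4_theta$briere1_egg)
  expect_equal(find_topt("Briere-1", table4_theta$briere1_egg)$topt_refined,
               cf, tolerance = 1e-3)
  # symmetric Gaussian curve peaks at its location parameter
  th <- c(Rm = 0.3, Tm = 29.6197, Tsig = 7.42)
  expect_equal(find_topt("Taylor", th)$topt_refined, 29.6197,
               tolerance = 1e-3)
})

test_that("upper thresholds come from roots or parameter identities", {
  tx <- find_tmax("Logan-10", table4_theta$logan10_total)
  expect_equal(tx$method, "root")
  expect_equal(tx$tmax, 44.03, tolerance = 0.01)
  expect_lte(abs(evaluate_model("Logan-10", table4_theta$logan10_total,
                                tx$tmax)), 1e-10)

  # Briere: the (tmax - T)^(1/m) factor vanishes at the fitted parameter
  tb <- find_tmax("Briere-1", table4_theta$briere1_egg)
  expect_equal(tb$tmax, 35.00)

  # monotone curves have no upper intersection
  ts <- find_tmax("Sigmoid", table4_theta$sigmoid_total)
  expect_true(is.na(ts$tmax))
  expect_equal(ts$method, "undefined")

  # rounding of printed Logan-10 egg parameters shifts the root slightly;
  # reported, not asserted equal to the printed 38.43
  te <- find_tmax("Logan-10", table4_theta$logan10_egg)
  expect_true(is.finite(te$tmax))
  expect_lt(abs(te$tmax - 38.43), 0.5)
})

test_that("lower thresholds: parameter identities, roots and absences", {
  expect_equal(find_tmin("Briere-2", table4_theta$briere2_total)$tmin, 11.96)
  expect_equal(find_tmin("Kontodimas-16", table4_theta$eq16_egg)$tmin,
               10.7196)
  tl <- find_tmin("Lactin-1", table4_theta$lactin1_total)
  expect_true(is.na(tl$tmin))
  expect_equal(tl$method, "undefined")
  t2 <- find_tmin("Lactin-2", table4_theta$lactin2_total)
  expect_equal(t2$method, "root")
  expect_lte(abs(evaluate_model("Lactin-2", table4_theta$lactin2_total,
                                t2$tmin)), 1e-10)
})

test_that("a symmetric cubic parabola yields (10, 20, 30)", {
  # R = 0.001 (T - 10)(30 - T) expressed as a cubic with zero leading term
  th <- c(a = -0.3, b = 0.04, c = -0.001, d = 0)
  ct <- cardinal_temps("Polynomial-3rd", th)
  expect_equal(ct$t_min, 10, tolerance = 1e-8)
  expect_equal(ct$t_opt, 20)
  expect_equal(ct$t_max, 30, tolerance = 1e-8)
})

test_that("cardinal bundle orders t_min < t_opt < t_max and flags outliers", {
  cases <- list(
    c("Briere-2", "briere2_total"), c("Briere-2", "briere2_pupa"),
    c("Briere-1", "briere1_egg"), c("Equation-16", "eq16_egg"),
    c("Lactin-2", "lactin2_total"), c("Bieri-1", "bieri1_egg"))
  for (cs in cases) {
    ct <- cardinal_temps(cs[1], table4_theta[[cs[2]]], window = c(0, 70))
    defined <- !is.na(c(ct$t_min, ct$t_opt, ct$t_max))
    if (all(defined)) {
      expect_lt(ct$t_min, ct$t_opt)
      expect_lt(ct$t_opt, ct$t_max)
    }
  }
  # a 67 C fitted upper threshold is reported but flagged implausible
  ct <- cardinal_temps("Briere-2", table4_theta$briere2_total, window = c(0, 70))
  expect_equal(ct$t_max, 67.48)
  expect_false(ct$tmax_plausible)
})

test_that("closed-form and grid optima agree over random in-bounds thetas", {
  set.seed(99)
  for (i in 1:100) {
    tmin <- runif(1, 2, 16)
    tmax <- tmin + runif(1, 10, 30)
    model <- sample(c("Briere-1", "Briere-2", "Kontodimas-16"), 1)
    th <- switch(model,
      "Briere-1" = c(a = 10^runif(1, -6, -4), tmin = tmin, tmax = tmax),
      "Briere-2" = c(a = 10^runif(1, -6, -4), m = runif(1, 0.3, 5),
                     tmin = tmin, tmax = tmax),
      "Kontodimas-16" = c(a = 10^runif(1, -6, -4), tmin = tmin,
                          tmax = tmax))
    cf <- model_spec(model)$analytic$topt(th)
    res <- find_topt(model, th, window = c(-10, 80))
    expect_false(is.na(res$topt))
    # lattice argmax brackets the true optimum; refinement nails it
    expect_lte(abs(cf - res$topt), 0.25 + 1e-9)
    expect_lte(abs(cf - res$topt_refined), 1e-3)
  }
})

test_that("every defined root has |rate| below 1e-10", {
  cases <- list(
    c("Logan-10", "logan10_total"), c("Logan-10", "logan10_egg"),
    c("Lactin-2", "lactin2_total"), c("Bieri-1", "bieri1_egg"),
    c("Briere-1", "briere1_egg"))
  for (cs in cases) {
    th <- table4_theta[[cs[2]]]
    tx <- find_tmax(cs[1], th)
    if (!is.na(tx$tmax)) {
      expect_lte(abs(evaluate_model(cs[1], th, tx$tmax)), 1e-10,
                 label = paste(cs[1], "tmax"))
    }
    tn <- find_tmin(cs[1], th)
    if (!is.na(tn$tmin)) {
      expect_lte(abs(evaluate_model(cs[1], th, tn$tmin)), 1e-10,
                 label = paste(cs[1], "tmin"))
    }
  }
})
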