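# Composite aggregation, the normality gate's operating characteristics,
# and leave-one-out / full-cohort z-scoring.

test_that("composites aggregate by mean for thickness and sum for volumes", {
  tab <- toy_table()
  map <- region_map(list(
    list(name = "frontal_motor_L", hemisphere = "L",
         members = c("lh.precentral", "lh.paracentral"),
         aggregation = "mean", measure_class = "cortical_thickness"),
    list(name = "single", hemisphere = "L", members = "lh.putamen",
         aggregation = "sum", measure_class = "subcortical_volume"),
    list(name = "pair", hemisphere = "L",
         members = c("lh.putamen", "lh.hippocampus"),
         aggregation = "sum", measure_class = "subcortical_volume")))
  comp <- aggregate_composites(tab, map)
  expect_equal(comp$values["C01", "frontal_motor_L"], 2.5)  # mean(2, 3)
  expect_identical(comp$values[, "single"], tab$values[, "lh.putamen"])
  expect_equal(unname(comp$values["C01", "pair"]), 7000 + 4000)

  # eTIV-fraction sums behave the same way
  frac <- tab; frac$metadata$etiv <- rep(1, 4)
  frac$values[, 3:4] <- cbind(rep(0.004, 4), rep(0.006, 4))
  expect_equal(unname(aggregate_composites(frac, map)$values[1, "pair"]), 0.010)

  # missing member => composite missing, no partial aggregation
  tab$values["C02", "lh.paracentral"] <- NA
  comp2 <- aggregate_composites(tab, map)
  expect_true(is.na(comp2$values["C02", "frontal_motor_L"]))
  expect_false(anyNA(comp2$values[, "pair"]))

  # mixed measure classes in one composite are a hard error
  bad <- region_map(list(list(name = "bad", hemisphere = "L",
                              members = c("lh.precentral", "lh.putamen"),
                              aggregation = "sum",
                              measure_class = "subcortical_volume")))
  expect_error(aggregate_composites(tab, bad), "mixed measure_class")
})

test_that("normality gate passes Gaussian and fails skewed samples at n = 41", {
  pass <- vapply(1:500, function(s) {
    set.seed(s); screen_normality(rnorm(41))$pass
  }, TRUE)
  expect_gte(mean(pass), 0.90)
  # exponential data: the moment estimator g1 (population skew 2) sits above
  # 1 in most samples at n = 41 (small-n downward bias caps this near ~0.9),
  # and the full gate (skew, kurtosis, Shapiro-Wilk) almost always fails
  exp_reports <- lapply(1:500, function(s) {
    set.seed(s); screen_normality(rexp(41))
  })
  expect_gte(mean(vapply(exp_reports, function(r) abs(r$skewness) >= 1, TRUE)),
             0.8)
  expect_gte(mean(vapply(exp_reports, function(r) !r$pass, TRUE)), 0.95)
  expect_error(screen_normality(rnorm(7)), ">= 8")
  expect_error(screen_normality(rep(1, 20)), "degenerate")
})

test_that("LOO z-scores match hand arithmetic and the delete-and-recompute oracle", {
  z <- loo_zscores(c(1, 2, 3))
  expect_equal(z[1], (1 - 2.5) / sd(c(2, 3)), tolerance = 1e-12)
  expect_equal(z[1], -2.1213203, tolerance = 1e-6)
  expect_equal(z[2], 0)  # equal to the mean of the others

  set.seed(11)
  x <- stats::setNames(rnorm(20, 5, 2), sprintf("C%02d", 1:20))
  oracle <- vapply(seq_along(x), function(i)
    (x[i] - mean(x[-i])) / sd(x[-i]), 0)
  expect_equal(unname(loo_zscores(x)), oracle, tolerance = 1e-10)

  expect_error(loo_zscores(c(5, 5, 5)), "zero holdout SD")
  expect_error(loo_zscores(c(1, NA, 2)), ">= 3")
  withna <- c(a = 1, b = NA, c = 2, d = 3, e = 4)
  zn <- loo_zscores(withna)
  expect_true(is.na(zn["b"]) && !anyNA(zn[c("a", "c", "d", "e")]))
})

test_that("patient z-scoring uses the full control distribution and propagates NA", {
  expect_equal(zscore_patients(4, c(1, 2, 3)), 2.0)
  expect_equal(zscore_patients(2, c(1, 2, 3)), 0)
  expect_true(is.na(zscore_patients(NA_real_, c(1, 2, 3))))
  expect_error(zscore_patients(1, c(2, 2, 2)), "zero control SD")
  expect_error(zscore_patients(1, c(2, 2)), ">= 3")
})

test_that("patient z is invariant to affine transforms of the composite", {
  set.seed(3)
  ctrl <- rnorm(41); pat <- rnorm(62, 0.5)
  z1 <- zscore_patients(pat, ctrl)
  z2 <- zscore_patients(3.7 * pat - 11, 3.7 * ctrl - 11)
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("build_zmap z-scores controls LOO and patients against all controls", {
  co <- generate_cohort(mini_config(n_controls = 20, n_patients = 10, seed = 5))
  comp <- aggregate_composites(co$table, co$map)
  zm <- build_zmap(comp)
  expect_identical(unname(zm$method[zm$group == "control"][1]), "loo")
  expect_identical(unname(zm$method[zm$group == "patient"][1]), "full")
  ctrl <- zm$group == "control"
  cn <- colnames(zm$z)[1]
  expect_equal(unname(zm$z[!ctrl, cn]),
               unname(zscore_patients(comp$values[!ctrl, cn],
                                      comp$values[ctrl, cn])))
  expect_equal(unname(zm$z[ctrl, cn]),
               unname(loo_zscores(comp$values[ctrl, cn])))
  expect_identical(zm$normative_n, 20L)
  expect_s3_class(zm$normality, "data.frame")
})
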