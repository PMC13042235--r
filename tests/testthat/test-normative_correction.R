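# Per-region GAM correction: recovery of known covariate effects, the
# residualization contract, and exact JSON round-tripping.

make_control_table <- function(n, y_fun, seed = 1, all_female = FALSE) {
  set.seed(seed)
  age <- runif(n, 12, 25)
  sexM <- if (all_female) rep(0, n) else rbinom(n, 1, 0.4)
  tiv <- rnorm(n, 1.17e6, 1.1e5)
  y <- y_fun(age, tiv, sexM)
  md <- data.frame(subject_id = sprintf("C%03d", 1:n), group = "control",
                   age = age, sex = ifelse(sexM == 1, "M", "F"),
                   etiv = tiv / 0.78, brainseg_vol = tiv,
                   stringsAsFactors = FALSE)
  morphometry_table(matrix(y, ncol = 1, dimnames = list(NULL, "lh.hippocampus")),
                    md, c(lh.hippocampus = "subcortical_volume"))
}

test_that("with no covariate effects the fitted age curve is flat", {
  # per-seed fitted curves carry the sampling error of the linear trend
  # (SE ~ sd/(sd_age sqrt(n)), ~0.1 SD at n = 200), so flatness is asserted
  # on the across-seed average curve (no systematic age effect) with a
  # noise-floor bound on the per-seed curves
  curves <- sapply(1:10, function(s) {
    tab <- make_control_table(200, function(a, t, x) rnorm(200, 4200, 400),
                              seed = s)
    m <- fit_correction_model(tab, "lh.hippocampus")
    grid <- data.frame(age = seq(12, 25, length.out = 50),
                       brainseg_vol = m$reference$brainseg_vol,
                       sexM = m$reference$sexM)
    as.numeric(predict(m$fit, newdata = grid))
  })
  avg <- rowMeans(curves)
  expect_lt((max(avg) - min(avg)) / 2, 0.1 * 400)
  half_range <- (apply(curves, 2, max) - apply(curves, 2, min)) / 2
  expect_lt(median(half_range), 0.2 * 400)
})

test_that("a pure linear TIV effect is recovered within the OLS oracle's CI", {
  b <- 0.002
  tab <- make_control_table(200, function(a, t, s)
    4200 + b * (t - 1.17e6) + rnorm(200, 0, 200), seed = 2)
  m <- fit_correction_model(tab, "lh.hippocampus")
  ols <- lm(y ~ age + brainseg_vol + sexM,
            data = data.frame(y = tab$values[, 1], age = tab$metadata$age,
                              brainseg_vol = tab$metadata$brainseg_vol,
                              sexM = as.numeric(tab$metadata$sex == "M")))
  ci <- confint(ols)["brainseg_vol", ]
  bt <- correction_coefficients(m)[["beta_tiv"]]
  expect_gte(bt, ci[1]); expect_lte(bt, ci[2])
  expect_gte(b, ci[1]); expect_lte(b, ci[2])   # oracle itself covers the truth
})

test_that("a constant response yields zero effects and identity correction", {
  tab <- make_control_table(50, function(a, t, s) rep(4000, 50), seed = 3)
  m <- fit_correction_model(tab, "lh.hippocampus")
  cf <- correction_coefficients(m)
  expect_equal(cf[["beta_tiv"]], 0, tolerance = 1e-8)
  expect_equal(cf[["intercept"]], 4000, tolerance = 1e-6)
  corrected <- apply_correction(m, tab)
  expect_equal(corrected$values[, 1], tab$values[, 1], tolerance = 1e-6)
})

test_that("a subject at the reference covariates is left unchanged", {
  tab <- make_control_table(21, function(a, t, s)
    3000 + 10 * a + rnorm(21, 0, 30), seed = 4, all_female = TRUE)
  # setting x1 to the mean of the others makes it the mean of all 21 exactly
  tab$metadata$age[1] <- mean(tab$metadata$age[-1])
  tab$metadata$brainseg_vol[1] <- mean(tab$metadata$brainseg_vol[-1])
  m <- fit_correction_model(tab, "lh.hippocampus")
  expect_equal(tab$metadata$age[1], m$reference$age)
  corrected <- apply_correction(m, tab)
  expect_equal(corrected$values[1, 1], tab$values[1, 1], tolerance = 1e-8)
})

test_that("correction is linear in TIV: equal-covariate subjects differ by beta_tiv * delta", {
  tab <- make_control_table(100, function(a, t, s)
    4200 + 0.003 * (t - 1.17e6) - 20 * (a - 18) + rnorm(100, 0, 150), seed = 5)
  m <- fit_correction_model(tab, "lh.hippocampus")
  delta <- 5e4
  md2 <- tab$metadata[c(1, 1), ]
  md2$subject_id <- c("A", "B")
  md2$brainseg_vol[2] <- md2$brainseg_vol[1] + delta
  two <- morphometry_table(matrix(c(4000, 4100), ncol = 1,
                                  dimnames = list(NULL, "lh.hippocampus")),
                           md2, tab$measure_class)
  corr <- apply_correction(m, two)
  bt <- correction_coefficients(m)[["beta_tiv"]]
  expect_equal(corr$values[2, 1] - corr$values[1, 1], 100 - bt * delta,
               tolerance = 1e-8)
})

test_that("corrected controls are decorrelated from age and TIV, and stay centered", {
  # linear age truth (no curvature, decline from the lower age bound): the
  # centering contract is exact up to fitted-smooth curvature noise
  cfg <- mini_config(n_controls = 200, n_patients = 1, seed = 9,
                     thickness_age_quad = 0, age_peak = 12)
  co <- generate_cohort(cfg)
  tab <- normalize_by_etiv(co$table)
  models <- fit_correction_models(tab)
  corrected <- apply_correction(models, tab)
  ctrl <- corrected$metadata$group == "control"
  for (r in regions(corrected)) {
    expect_lt(abs(cor(corrected$values[ctrl, r], corrected$metadata$age[ctrl])), 0.1)
    expect_lt(abs(cor(corrected$values[ctrl, r],
                      corrected$metadata$brainseg_vol[ctrl])), 0.1)
    # centering: residualizing to the reference point shifts the mean by the
    # Jensen gap of the *fitted* smooth — zero for a linear fit, and bounded
    # by ~0.15 SD when the 5-knot smooth picks up noise curvature; the
    # downstream z-scores are invariant to this per-region constant
    expect_lt(abs(mean(corrected$values[ctrl, r]) - mean(tab$values[ctrl, r])),
              0.2 * sd(tab$values[ctrl, r]))
  }
})

test_that("JSON round-trip reproduces predictions exactly", {
  cfg <- mini_config(n_controls = 60, n_patients = 20, seed = 10)
  co <- generate_cohort(cfg)
  tab <- normalize_by_etiv(co$table)
  models <- fit_correction_models(tab)
  d <- withr::local_tempdir()
  f <- file.path(d, "models.json")
  write_correction_models(models, f)
  back <- read_correction_models(f)
  a <- apply_correction(models, tab)
  b <- apply_correction_json(back, tab)
  expect_equal(b$values, a$values, tolerance = 1e-8)
})

test_that("small or degenerate fitting sets are rejected or reduced", {
  tab <- make_control_table(10, function(a, t, s) rnorm(10, 4200, 400))
  expect_error(fit_correction_model(tab, "lh.hippocampus"), ">= 15")
  tabf <- make_control_table(30, function(a, t, s) rnorm(30, 4200, 400),
                             all_female = TRUE)
  expect_warning(m <- fit_correction_model(tabf, "lh.hippocampus"), "sexM")
  expect_identical(m$dropped, "sexM")
})
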