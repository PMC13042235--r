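# Normative covariate correction: per-region additive models of age, sex and
# total brain volume fitted on the normative (control) cohort, whose
# predicted covariate effects are then subtracted from all subjects.

#' Fit a per-region normative correction model
#'
#' Fits `value ~ s(age, k = n_knots, bs = "cr") + brainseg_vol + sexM` with
#' mgcv: a penalized cubic-regression age smooth (5 knots at age quantiles by
#' default, smoothing parameter selected by REML, which is less prone to
#' spurious wiggliness than GCV on normative-sized cohorts) plus linear
#' terms for total brain segmentation volume and sex. Sex is coded F = 0 / M = 1 (equivalent to a
#' treatment-coded factor with female reference). The model is fitted on the
#' normative cohort only by default; `fit_cohort = "pooled"` reproduces the
#' alternative reading in which patients co-determine the covariate effects.
#'
#' @param table a `morph_table` (normally eTIV-normalized first).
#' @param region region (column) to model.
#' @param n_knots knots of the age smooth.
#' @param fit_cohort `"controls"` (normative convention) or `"pooled"`.
#' @param min_n minimum number of non-missing fitting subjects.
#' @return a `correction_model`: the mgcv fit plus the reference covariates
#'   (fitting-cohort means of age, brainseg_vol and the male indicator),
#'   the fitted age range and bookkeeping fields.
#' @export
fit_correction_model <- function(table, region, n_knots = 5,
                                 fit_cohort = c("controls", "pooled"),
                                 min_n = 15) {
  fit_cohort <- match.arg(fit_cohort)
  abort_if(!region %in% regions(table), "region not in table: ", region)
  md <- table$metadata
  keep <- if (fit_cohort == "controls") md$group == "control" else rep(TRUE, nrow(md))
  dat <- data.frame(y = table$values[keep, region],
                    age = md$age[keep],
                    brainseg_vol = md$brainseg_vol[keep],
                    sexM = as.numeric(md$sex[keep] == "M"))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  abort_if(nrow(dat) < min_n,
           "need >= ", min_n, " fitting subjects for ", region,
           " (have ", nrow(dat), ")")
  abort_if(sample_sd(dat$age) == 0, "age variance is zero")

  dropped <- character()
  rhs <- sprintf("s(age, k = %d, bs = 'cr')", n_knots)
  if (sample_sd(dat$brainseg_vol) > 0) rhs <- c(rhs, "brainseg_vol")
  else dropped <- c(dropped, "brainseg_vol")
  if (sample_sd(dat$sexM) > 0) rhs <- c(rhs, "sexM")
  else dropped <- c(dropped, "sexM")
  if (length(dropped) > 0)
    warning("dropping degenerate term(s) for ", region, ": ",
            paste(dropped, collapse = ", "), call. = FALSE)
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  # REML smoothing selection; degenerate responses (e.g. constant y) break
  # the REML reparameterization, so fall back to GCV for those
  fit <- tryCatch(mgcv::gam(form, data = dat, method = "REML"),
                  error = function(e) mgcv::gam(form, data = dat,
                                                method = "GCV.Cp"))
  structure(list(region = region, fit = fit,
                 reference = list(age = mean(dat$age),
                                  brainseg_vol = mean(dat$brainseg_vol),
                                  sexM = mean(dat$sexM)),
                 age_range = range(dat$age),
                 fit_cohort = fit_cohort, n = nrow(dat),
                 n_knots = n_knots, dropped = dropped),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model>", x$region, "| fit on", x$n, x$fit_cohort,
      "subjects |", x$n_knots, "knot age smooth\n")
  invisible(x)
}

# Predicted covariate surface at given covariates; newdata may hold a
# fractional male indicator (used for the reference point).
predict_mu <- function(model, age, brainseg_vol, sexM) {
  nd <- data.frame(age = age, brainseg_vol = brainseg_vol, sexM = sexM)
  as.numeric(predict(model$fit, newdata = nd))
}

#' Linear coefficients of a correction model
#' @param model a `correction_model`.
#' @return named numeric with `intercept`, `beta_tiv`, `beta_sex` (dropped
#'   terms are reported as 0).
#' @export
correction_coefficients <- function(model) {
  cf <- coef(model$fit)
  c(intercept = unname(cf["(Intercept)"]),
    beta_tiv = if ("brainseg_vol" %in% names(cf)) unname(cf["brainseg_vol"]) else 0,
    beta_sex = if ("sexM" %in% names(cf)) unname(cf["sexM"]) else 0)
}

#' Fit correction models for many regions
#'
#' @inheritParams fit_correction_model
#' @param regions regions to model; defaults to all columns.
#' @return a `correction_models` list (one `correction_model` per region).
#' @export
fit_correction_models <- function(table, regions = NULL, n_knots = 5,
                                  fit_cohort = c("controls", "pooled"),
                                  min_n = 15) {
  fit_cohort <- match.arg(fit_cohort)
  regions <- regions %||% colnames(table$values)
  models <- lapply(regions, fit_correction_model, table = table,
                   n_knots = n_knots, fit_cohort = fit_cohort, min_n = min_n)
  names(models) <- regions
  structure(models, class = "correction_models", fit_cohort = fit_cohort)
}

#' Subtract predicted covariate effects from all subjects
#'
#' Each cell becomes `observed - (mu_hat(covariates) - mu_hat(reference))`,
#' i.e. the region is residualized to the fitting cohort's reference
#' covariates (its mean age, mean brain volume and sex composition),
#' preserving the region's natural scale. Ages outside the fitted support
#' are extrapolated linearly from the boundary (the natural-spline basis is
#' linear beyond its boundary knots) with a warning.
#'
#' @param models a `correction_models` list (or single `correction_model`).
#' @param table the `morph_table` to correct (all subjects).
#' @return the corrected `morph_table`; attribute `"correction"` records the
#'   fit cohort and corrected regions.
#' @export
apply_correction <- function(models, table) {
  if (inherits(models, "correction_model")) models <- list(models)
  regs <- vapply(models, `[[`, "", "region")
  abort_if(!all(regs %in% regions(table)), "model region(s) absent from table")
  md <- table$metadata
  covs_ok <- !(is.na(md$age) | is.na(md$brainseg_vol) | is.na(md$sex))
  abort_if(!all(covs_ok), "missing covariates for subject(s): ",
           paste(md$subject_id[!covs_ok], collapse = ", "))
  sexM <- as.numeric(md$sex == "M")
  out <- table
  outside <- character()
  for (m in models) {
    if (any(md$age < m$age_range[1] | md$age > m$age_range[2]))
      outside <- c(outside, m$region)
    mu <- predict_mu(m, md$age, md$brainseg_vol, sexM)
    mu_ref <- predict_mu(m, m$reference$age, m$reference$brainseg_vol,
                         m$reference$sexM)
    out$values[, m$region] <- table$values[, m$region] - (mu - mu_ref)
  }
  if (length(outside) > 0)
    warning("age outside the fitted support; linear extrapolation used for ",
            length(outside), " region(s)", call. = FALSE)
  attr(out, "correction") <- list(
    fit_cohort = models[[1]]$fit_cohort %||% attr(models, "fit_cohort"),
    regions = unname(regs))
  out
}

# --- JSON serialization -----------------------------------------------------

# The cr age smooth is a natural cubic spline, fully determined by its knot
# locations and its values at the knots, so (knots, values-at-knots) plus the
# linear coefficients and reference covariates serialize the model exactly;
# stats::splinefun(method = "natural") rebuilds the curve, including the
# linear extrapolation beyond the boundary knots.
model_to_record <- function(m) {
  sm <- m$fit$smooth[[1]]
  knots <- as.numeric(sm$xp)
  ref <- m$reference
  age_term <- as.numeric(predict(
    m$fit, newdata = data.frame(age = knots, brainseg_vol = ref$brainseg_vol,
                                sexM = ref$sexM),
    type = "terms", terms = "s(age)"))
  cf <- correction_coefficients(m)
  list(region = m$region, n = m$n, fit_cohort = m$fit_cohort,
       n_knots = m$n_knots, knots = knots, age_term_at_knots = age_term,
       beta_tiv = unname(cf["beta_tiv"]), beta_sex = unname(cf["beta_sex"]),
       mu_reference = predict_mu(m, ref$age, ref$brainseg_vol, ref$sexM),
       reference = ref, age_range = as.numeric(m$age_range),
       dropped = as.list(m$dropped))
}

#' Serialize / reload correction models as JSON
#'
#' The JSON records, per region, the age-smooth knots and fitted values at
#' the knots, the linear brain-volume and sex coefficients, the reference
#' covariates and the fitted value at the reference point — enough to audit
#' the models and to reproduce their predictions exactly.
#'
#' @param models a `correction_models` list.
#' @param path output/input JSON path.
#' @return `path` invisibly (writer); a `correction_models_json` object whose
#'   elements predict via [apply_correction_json()] (reader).
#' @export
write_correction_models <- function(models, path) {
  jsonlite::write_json(
    list(schema = "zmapendo/correction_models/1",
         fit_cohort = attr(models, "fit_cohort"),
         models = lapply(unclass(models), model_to_record)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_models
#' @export
read_correction_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  models <- lapply(raw$models, function(r) {
    r$age_fun <- stats::splinefun(unlist(r$knots), unlist(r$age_term_at_knots),
                                  method = "natural")
    r
  })
  names(models) <- vapply(models, `[[`, "", "region")
  structure(models, class = "correction_models_json",
            fit_cohort = raw$fit_cohort)
}

#' Apply serialized correction models to a table
#'
#' Reproduces [apply_correction()] from the JSON representation.
#'
#' @param models a `correction_models_json` from [read_correction_models()].
#' @param table the `morph_table` to correct.
#' @return the corrected `morph_table`.
#' @export
apply_correction_json <- function(models, table) {
  md <- table$metadata
  sexM <- as.numeric(md$sex == "M")
  out <- table
  for (r in models) {
    eff <- (r$age_fun(md$age) - r$age_fun(r$reference$age)) +
      r$beta_tiv * (md$brainseg_vol - r$reference$brainseg_vol) +
      r$beta_sex * (sexM - r$reference$sexM)
    out$values[, r$region] <- table$values[, r$region] - eff
  }
  attr(out, "correction") <- list(fit_cohort = attr(models, "fit_cohort"),
                                  regions = names(models))
  out
}
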