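# Synthetic cohort generator: controls and patients with the covariate
# structure the correction model assumes and planted endophenotype effects,
# plus ground-truth labels, so every downstream stage is testable without
# access to the original (non-deposited) cohort.

#' Default per-region baselines for the synthetic generator
#'
#' Means and SDs on the control scale for every region of
#' [default_region_map()]: Desikan-Killiany cortical thickness in mm,
#' subcortical / thalamic-nucleus / white-matter volumes in mm^3. Values are
#' realistic magnitudes for an adolescent/young-adult cohort; the SD column
#' is the residual (measurement plus idiosyncratic) spread after covariate
#' effects, the scale on which planted endophenotype shifts are expressed.
#'
#' @return data.frame with columns `region`, `measure_class`, `mean`, `sd`.
#' @export
default_region_baselines <- function() {
  lobe_mean <- c(frontal_motor = 2.55, frontal_nonmotor = 2.60, parietal = 2.30,
                 temporal = 2.80, occipital = 2.00, limbic = 2.70)
  ctx <- do.call(rbind, lapply(names(dk_lobe_assignment()), function(lobe) {
    labs <- dk_lobe_assignment()[[lobe]]
    expand.grid(hemi = c("lh", "rh"), label = labs,
                stringsAsFactors = FALSE)[, c("hemi", "label")] |>
      transform(region = paste0(hemi, ".", label),
                measure_class = "cortical_thickness",
                mean = lobe_mean[[lobe]], sd = 0.12)
  }))[, c("region", "measure_class", "mean", "sd")]

  sub_mean <- c(hippocampus = 4200, amygdala = 1700, caudate = 3800,
                putamen = 5500, pallidum = 1800, accumbens = 600,
                ventraldc = 4100, cerebellum.cortex = 52000)
  nuc_mean <- c(VA = 400, VAmc = 30, VLa = 620, VLp = 950, VM = 21,
                AV = 130, LD = 25, LP = 120, VPL = 850, CM = 240, CeM = 70,
                MDm = 700, MDl = 250, LGN = 250, MGN = 110,
                PuA = 210, PuM = 980, PuL = 180, PuI = 220)
  vol_rows <- function(labels, means, infix = "") {
    do.call(rbind, lapply(c("lh", "rh"), function(h)
      data.frame(region = paste0(h, ".", infix, labels),
                 measure_class = "subcortical_volume",
                 mean = unname(means[labels]), sd = 0.10 * unname(means[labels]),
                 stringsAsFactors = FALSE)))
  }
  sub <- vol_rows(names(sub_mean), sub_mean)
  nuc <- vol_rows(names(nuc_mean), nuc_mean, infix = "thal.")
  wm <- data.frame(region = c("lh.cerebral.wm", "rh.cerebral.wm"),
                   measure_class = "white_matter_volume",
                   mean = 230000, sd = 18000, stringsAsFactors = FALSE)
  cc_mean <- c(900, 450, 450, 420, 980)
  cc <- data.frame(region = cc_segments(), measure_class = "white_matter_volume",
                   mean = cc_mean, sd = 0.12 * cc_mean, stringsAsFactors = FALSE)
  out <- rbind(ctx, sub, nuc, wm, cc)
  rownames(out) <- NULL
  out
}

#' Default planted endophenotypes
#'
#' Three endophenotypes with composite-level effect maps (shifts in control
#' residual-SD units, applied to both hemispheres) that qualitatively
#' reproduce the patterns the clustering is expected to recover: a
#' subcortical-reduction group (SR) with marked motor-thalamic and diffuse
#' subcortical volume loss, an increased-cortical-thickness group (ICT) with
#' frontal-motor/parietal thickening and milder motor-thalamic reduction, and
#' a decreased-cortical-thickness group (DCT) with frontal-motor/parietal
#' thinning and little subcortical change. Prevalences 0.44/0.34/0.22; with
#' 62 patients the largest-remainder allocation yields groups of 27, 21
#' and 14.
#'
#' @return list of endophenotypes, each with `name`, `prevalence` and
#'   `effect_map` (named numeric, composite -> shift in residual-SD units).
#' @export
default_endophenotypes <- function() {
  both <- function(base, shift) {
    v <- rep(shift, 2L * length(base))
    names(v) <- paste0(rep(base, each = 2), c("_L", "_R"))
    v
  }
  list(
    list(name = "subcortical_reduction", prevalence = 0.44,
         effect_map = c(both("motor_thalamus", -1.5),
                        both("nonmotor_thalamus", -1.0),
                        both("subcortical_grey", -1.0))),
    list(name = "increased_cortical_thickness", prevalence = 0.34,
         effect_map = c(both("frontal_motor", 1.2),
                        both("parietal", 1.2),
                        both("temporal", 0.6),
                        both("motor_thalamus", -0.6))),
    list(name = "decreased_cortical_thickness", prevalence = 0.22,
         effect_map = c(both("frontal_motor", -1.2),
                        both("parietal", -1.2),
                        both("subcortical_grey", -0.2))))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the modelled study: 41 healthy controls and 62 patients
#' aged 12-25 (age mean 20.4, SD 3.6, truncated), ~60% female, cortical
#' thickness declining ~0.01 mm/year with curvature (peak in early
#' adolescence), shallow monotone volume decline, volumes scaling with total
#' brain segmentation volume so that head size explains about half of the
#' between-subject volume variance, and the three planted endophenotypes of
#' [default_endophenotypes()].
#'
#' @param n_controls,n_patients cohort sizes.
#' @param seed integer RNG seed; a fixed seed makes the cohort bit-identical.
#' @param age_range years, subjects drawn from a truncated normal inside it.
#' @param age_mean,age_sd parameters of the (untruncated) age distribution.
#' @param sex_ratio_female fraction of female subjects.
#' @param region_map composite definitions (drives which regions exist).
#' @param region_baselines data.frame as [default_region_baselines()].
#' @param endophenotypes list as [default_endophenotypes()]; prevalences must
#'   sum to 1.
#' @param measurement_noise_sd multiplier on the per-region baseline SD for
#'   the residual noise draw.
#' @param thickness_age_slope mm/year linear decline past `age_peak`.
#' @param thickness_age_quad mm/year^2 curvature of the thickness decline.
#' @param age_peak years; age at which cortical thickness peaks.
#' @param volume_age_rate fractional volume change per year (of the region
#'   mean), centred at age 18.5.
#' @param sex_effect_thickness additive thickness offset (mm) for males.
#' @param sex_effect_volume_frac fractional volume offset for males.
#' @param tiv_r2 fraction of between-subject volume variance explained by
#'   brain segmentation volume (sets the linear scaling slope).
#' @param etiv_mean,etiv_sd eTIV distribution (mm^3).
#' @param plant_cognitive_effects if `TRUE`, plants lower general ability in
#'   the increased-cortical-thickness group (-0.6) and higher
#'   speed/response-inhibition in the decreased-cortical-thickness group
#'   (+0.6); by default clinical/cognitive variables are independent of the
#'   endophenotype.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_controls = 41, n_patients = 62, seed = 1,
                          age_range = c(12, 25), age_mean = 20.4, age_sd = 3.6,
                          sex_ratio_female = 0.6,
                          region_map = default_region_map(),
                          region_baselines = default_region_baselines(),
                          endophenotypes = default_endophenotypes(),
                          measurement_noise_sd = 1.0,
                          thickness_age_slope = -0.010,
                          thickness_age_quad = -0.0008,
                          age_peak = 14,
                          volume_age_rate = -0.003,
                          sex_effect_thickness = -0.03,
                          sex_effect_volume_frac = 0.02,
                          tiv_r2 = 0.5,
                          etiv_mean = 1.5e6, etiv_sd = 1.4e5,
                          plant_cognitive_effects = FALSE) {
  cfg <- as.list(environment())
  abort_if(any(region_baselines$sd <= 0), "all baseline SDs must be > 0")
  abort_if(measurement_noise_sd <= 0, "measurement_noise_sd must be > 0")
  prev <- vapply(endophenotypes, `[[`, 0, "prevalence")
  abort_if(abs(sum(prev) - 1) > 1e-8, "endophenotype prevalences must sum to 1")
  structure(cfg, class = "cohort_config")
}

# Largest-remainder allocation of n subjects over prevalences: deterministic
# group sizes whose proportions are as close as possible to the target.
allocate_counts <- function(n, prevalence) {
  raw <- n * prevalence
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

# Residual SD of a composite given per-region residual SDs: mean-aggregated
# composites average noise, sum-aggregated composites accumulate it.
composite_residual_sd <- function(sds, aggregation) {
  if (aggregation == "mean") sqrt(sum(sds^2)) / length(sds)
  else sqrt(sum(sds^2))
}

#' Generate a synthetic cohort with planted endophenotypes
#'
#' Control region values are baseline + age effect + sex effect + brain-size
#' scaling + Gaussian residual noise; patient values are additionally shifted
#' according to their endophenotype's composite-level effect map, expressed
#' in control-scale SD units at the composite level and spread equally over
#' the member regions. Because the shifts are anchored to the control-scale
#' SD while the z-scores downstream normalize by the residual spread,
#' raising `measurement_noise_sd` above 1 attenuates the recovered z-signal
#' (and lowering it sharpens it) — at the default of 1 the planted shift is
#' recovered one-to-one in z units. Clinical, cognitive and psychiatric variables are drawn
#' from distributions parameterized to the modelled cohort's summary
#' characteristics and are, by default, independent of the planted
#' endophenotype.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `table` (raw [morphometry_table()],
#'   volumes in mm^3, not yet eTIV-normalized), `map` (the region map),
#'   `true_labels` (named character vector, patient id -> endophenotype) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  abort_if(!inherits(config, "cohort_config"), "need a cohort_config")
  nep <- length(config$endophenotypes)
  abort_if(config$n_patients < nep,
           "n_patients must be at least the number of endophenotypes")
  set.seed(config$seed)
  nc <- config$n_controls; np <- config$n_patients; n <- nc + np
  ids <- c(sprintf("C%03d", seq_len(nc)), sprintf("P%03d", seq_len(np)))
  group <- rep(c("control", "patient"), c(nc, np))

  age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_ratio_female, "F", "M")
  etiv <- stats::rnorm(n, config$etiv_mean, config$etiv_sd)
  brainseg <- 0.78 * etiv + stats::rnorm(n, 0, 35000)
  brainseg_ref <- 0.78 * config$etiv_mean
  brainseg_sd <- sqrt((0.78 * config$etiv_sd)^2 + 35000^2)

  bl <- config$region_baselines
  noise_sd <- bl$sd * config$measurement_noise_sd
  is_thick <- bl$measure_class == "cortical_thickness"

  # covariate effects, n x regions
  da <- age - config$age_peak
  age_eff <- outer(config$thickness_age_slope * pmax(da, 0) +
                     config$thickness_age_quad * pmax(da, 0)^2,
                   as.numeric(is_thick)) +
    outer(age - 18.5, ifelse(is_thick, 0, config$volume_age_rate * bl$mean))
  sex_eff <- outer(as.numeric(sex == "M"),
                   ifelse(is_thick, config$sex_effect_thickness,
                          config$sex_effect_volume_frac * bl$mean))
  tiv_slope <- ifelse(is_thick, 0,
                      sqrt(config$tiv_r2 / (1 - config$tiv_r2)) *
                        noise_sd / brainseg_sd)
  tiv_eff <- outer(brainseg - brainseg_ref, tiv_slope)

  noise <- matrix(stats::rnorm(n * nrow(bl), 0, 1), n, nrow(bl),
                  byrow = FALSE) * rep(noise_sd, each = n)
  values <- rep(bl$mean, each = n) + age_eff + sex_eff + tiv_eff + noise

  # planted endophenotype shifts for patients
  ep_names <- vapply(config$endophenotypes, `[[`, "", "name")
  counts <- allocate_counts(np, vapply(config$endophenotypes, `[[`, 0, "prevalence"))
  labels <- sample(rep(ep_names, counts))
  names(labels) <- ids[group == "patient"]
  region_index <- stats::setNames(seq_len(nrow(bl)), bl$region)
  for (ep in config$endophenotypes) {
    rows <- which(group == "patient")[labels == ep$name]
    for (cname in names(ep$effect_map)) {
      cmp <- config$region_map[[cname]]
      abort_if(is.null(cmp), "effect map names unknown composite: ", cname)
      j <- region_index[cmp$members]
      abort_if(anyNA(j), "composite ", cname, " has members without baselines")
      # shifts are in control-scale SD units (baseline SD), independent of the
      # measurement-noise fraction, so noisier cohorts have weaker z-signal
      sd_c <- composite_residual_sd(bl$sd[j], cmp$aggregation)
      per_member <- ep$effect_map[[cname]] * sd_c /
        (if (cmp$aggregation == "mean") 1 else length(j))
      values[rows, j] <- values[rows, j] + per_member
    }
  }
  values <- pmax(values, 0)
  colnames(values) <- bl$region

  metadata <- simulate_clinical(ids, group, age, sex, etiv, brainseg,
                                labels, config)
  table <- morphometry_table(values, metadata,
                             stats::setNames(bl$measure_class, bl$region))
  structure(list(table = table, map = config$region_map,
                 true_labels = labels, config = config),
            class = "synthetic_cohort")
}

# Clinical/cognitive/psychiatric variables parameterized to the modelled
# cohort's summary statistics; epilepsy-specific variables are missing for
# controls.
simulate_clinical <- function(ids, group, age, sex, etiv, brainseg,
                              labels, config) {
  n <- length(ids); pat <- group == "patient"
  md <- data.frame(subject_id = ids, group = group, age = age, sex = sex,
                   etiv = etiv, brainseg_vol = brainseg,
                   stringsAsFactors = FALSE)
  md$iq <- stats::rnorm(n, 98, 13)
  md$general_ability <- stats::rnorm(n, 0, 0.9)
  md$speed_inhibition <- stats::rnorm(n, 0, 0.9)
  md$learning_memory <- stats::rnorm(n, 0, 0.9)
  md$adi <- pmin(pmax(stats::rnorm(n, 48, 20), 1), 100)
  md$adhd <- stats::rbinom(n, 1, ifelse(pat, 0.18, 0.07)) == 1
  md$anxiety <- stats::rbinom(n, 1, ifelse(pat, 0.36, 0.34)) == 1
  md$depression <- stats::rbinom(n, 1, ifelse(pat, 0.48, 0.27)) == 1

  dur <- pmin(pmax(abs(stats::rnorm(n, 6.3, 5.6)), 0.25), age - 2)
  md$duration <- ifelse(pat, dur, NA_real_)
  md$age_of_onset <- ifelse(pat, age - dur, NA_real_)
  md$n_asm <- ifelse(pat, pmax(0, round(stats::rnorm(n, 1.48, 0.62))), NA_real_)
  md$months_since_gtc <- ifelse(pat, pmin(pmax(stats::rlnorm(n, log(15), 0.95), 1), 126),
                                NA_real_)
  gtc <- stats::rbinom(n, 1, 0.8) == 1
  gtc[stats::runif(n) < 0.11] <- NA  # tolerated missingness, as in real interviews
  md$gtc_controlled <- ifelse(pat, gtc, NA)
  md$abnormal_eeg <- ifelse(pat, stats::rbinom(n, 1, 0.35) == 1, NA)
  md$vpa_use <- ifelse(pat, stats::rbinom(n, 1, 0.16) == 1, NA)

  if (isTRUE(config$plant_cognitive_effects)) {
    lab_full <- rep(NA_character_, n); lab_full[pat] <- labels
    md$general_ability <- md$general_ability -
      0.6 * (lab_full %in% "increased_cortical_thickness")
    md$speed_inhibition <- md$speed_inhibition +
      0.6 * (lab_full %in% "decreased_cortical_thickness")
  }
  md
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> seed", x$config$seed, "\n")
  print(x$table)
  cat("  planted endophenotypes:",
      paste(names(table(x$true_labels)), table(x$true_labels),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `morphometry.csv`, `metadata.csv`, `truth.csv` and `regionmap.yaml`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_morphometry(cohort$table, file.path(dir, "morphometry.csv"),
                    file.path(dir, "metadata.csv"))
  write.csv(data.frame(subject_id = names(cohort$true_labels),
                       endophenotype = unname(cohort$true_labels)),
            file.path(dir, "truth.csv"), row.names = FALSE)
  write_region_map(cohort$map, file.path(dir, "regionmap.yaml"))
  invisible(dir)
}
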