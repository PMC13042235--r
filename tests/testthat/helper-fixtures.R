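# Shared fixtures: a reduced region map (5 composites over 11 regions) and
# cohort configs built on it, so simulation-heavy tests stay fast while
# exercising every measure class and aggregation rule.

mini_map <- function() {
  region_map(list(
    list(name = "motor_thalamus_L", hemisphere = "L",
         members = c("lh.thal.VA", "lh.thal.VLp"),
         aggregation = "sum", measure_class = "subcortical_volume"),
    list(name = "nonmotor_thalamus_L", hemisphere = "L",
         members = c("lh.thal.AV", "lh.thal.MDm"),
         aggregation = "sum", measure_class = "subcortical_volume"),
    list(name = "subcortical_grey_L", hemisphere = "L",
         members = c("lh.hippocampus", "lh.putamen", "lh.caudate"),
         aggregation = "sum", measure_class = "subcortical_volume"),
    list(name = "frontal_motor_L", hemisphere = "L",
         members = c("lh.precentral", "lh.paracentral"),
         aggregation = "mean", measure_class = "cortical_thickness"),
    list(name = "parietal_L", hemisphere = "L",
         members = c("lh.postcentral", "lh.superiorparietal"),
         aggregation = "mean", measure_class = "cortical_thickness")))
}

mini_baselines <- function() {
  data.frame(
    region = c("lh.thal.VA", "lh.thal.VLp", "lh.thal.AV", "lh.thal.MDm",
               "lh.hippocampus", "lh.putamen", "lh.caudate",
               "lh.precentral", "lh.paracentral",
               "lh.postcentral", "lh.superiorparietal"),
    measure_class = c(rep("subcortical_volume", 7),
                      rep("cortical_thickness", 4)),
    mean = c(400, 950, 130, 700, 4200, 5500, 3800, 2.55, 2.55, 2.30, 2.30),
    sd = c(40, 95, 15, 70, 400, 500, 400, 0.12, 0.12, 0.12, 0.12),
    stringsAsFactors = FALSE)
}

null_endophenotype <- function() {
  list(list(name = "null", prevalence = 1,
            effect_map = stats::setNames(numeric(0), character(0))))
}

mini_endophenotypes <- function() {
  list(
    list(name = "subcortical_reduction", prevalence = 0.44,
         effect_map = c(motor_thalamus_L = -1.5, nonmotor_thalamus_L = -1.0,
                        subcortical_grey_L = -1.0)),
    list(name = "increased_cortical_thickness", prevalence = 0.34,
         effect_map = c(frontal_motor_L = 1.2, parietal_L = 1.2,
                        motor_thalamus_L = -0.6)),
    list(name = "decreased_cortical_thickness", prevalence = 0.22,
         effect_map = c(frontal_motor_L = -1.2, parietal_L = -1.2,
                        subcortical_grey_L = -0.2)))
}

mini_config <- function(n_controls = 41, n_patients = 62, seed = 1,
                        endophenotypes = null_endophenotype(), ...) {
  cohort_config(n_controls = n_controls, n_patients = n_patients, seed = seed,
                region_map = mini_map(), region_baselines = mini_baselines(),
                endophenotypes = endophenotypes, ...)
}

# tiny hand-built table for IO/arithmetic tests
toy_table <- function() {
  md <- data.frame(
    subject_id = c("C01", "C02", "C03", "P01"),
    group = c("control", "control", "control", "patient"),
    age = c(15, 20, 25, 18), sex = c("F", "M", "F", "F"),
    etiv = c(1.4e6, 1.5e6, 1.6e6, 1.45e6),
    brainseg_vol = c(1.1e6, 1.17e6, 1.25e6, 1.13e6),
    stringsAsFactors = FALSE)
  vals <- rbind(c(2.0, 3.0, 7000, 4000),
                c(2.5, 2.5, 7100, 4100),
                c(3.0, 2.0, 6900, 3900),
                c(2.2, 2.8, 7050, 4050))
  colnames(vals) <- c("lh.precentral", "lh.paracentral",
                      "lh.putamen", "lh.hippocampus")
  morphometry_table(vals, md,
                    c(lh.precentral = "cortical_thickness",
                      lh.paracentral = "cortical_thickness",
                      lh.putamen = "subcortical_volume",
                      lh.hippocampus = "subcortical_volume"))
}

# Gaussian clouds around given centers (rows), sizes per center
make_clouds <- function(centers, sizes, sd = 1, seed = 1) {
  set.seed(seed)
  z <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(sizes[i] * ncol(centers), 0, sd), sizes[i]) +
      rep(centers[i, ], each = sizes[i])))
  rownames(z) <- sprintf("S%03d", seq_len(nrow(z)))
  attr(z, "truth") <- rep(seq_len(nrow(centers)), sizes)
  z
}
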