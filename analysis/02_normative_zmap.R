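#!/usr/bin/env Rscript
# Normative modelling stage: eTIV normalization, the 3-SD total-thalamic-
# volume outlier screen, per-region GAM correction for age, sex and brain
# volume (fitted on controls), lobar composite aggregation, the normality
# gate, and z-scoring (leave-one-out for controls, full-control distribution
# for patients).

suppressPackageStartupMessages(library(zmapendo))

baselines <- default_region_baselines()
table <- read_morphometry("results/cohort/morphometry.csv",
                          "results/cohort/metadata.csv",
                          stats::setNames(baselines$measure_class,
                                          baselines$region))
map <- read_region_map("results/cohort/regionmap.yaml")
dir.create("results/zmap", recursive = TRUE, showWarnings = FALSE)

table_n <- normalize_by_etiv(table)
qc <- screen_outliers(table_n)
print(qc)
write_qc_report(qc, "results/zmap/qc.json")
if (nrow(qc$excluded_subjects) > 0)
  table_n <- drop_subjects(table_n, qc$excluded_subjects$subject_id)

models <- fit_correction_models(table_n, fit_cohort = "controls")
write_correction_models(models, "results/zmap/models.json")
corrected <- apply_correction(models, table_n)
write_morphometry(corrected, "results/zmap/corrected.csv",
                  "results/zmap/metadata.csv")

composites <- aggregate_composites(corrected, map)
write.csv(data.frame(subject_id = rownames(composites$values),
                     group = composites$metadata$group,
                     composites$values, check.names = FALSE),
          "results/zmap/composites.csv", row.names = FALSE)

zmap <- build_zmap(composites)
write_zmap(zmap, "results/zmap/zmap.csv")
print(zmap)
flagged <- zmap$normality$composite[!zmap$normality$pass]
cat("normality gate:", ncol(zmap$z) - length(flagged), "of", ncol(zmap$z),
    "composites pass",
    if (length(flagged)) paste0("(flagged: ", paste(flagged, collapse = ", "), ")"),
    "\n")
cat("wrote results/zmap/{qc,models}.json, corrected.csv, composites.csv, zmap.csv\n")
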