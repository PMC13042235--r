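#!/usr/bin/env Rscript
# Distribution stage: per-composite Kolmogorov-Smirnov comparison of patient
# vs control z-scores with BH-FDR within the composite family, and
# per-region Welch T statistics (map-style table) with FDR within the region
# family.

suppressPackageStartupMessages(library(zmapendo))

zdf <- read.csv("results/zmap/zmap.csv", check.names = FALSE)
zmat <- as.matrix(zdf[, setdiff(names(zdf), c("subject_id", "group"))])
rownames(zmat) <- zdf$subject_id
zmap <- structure(list(z = zmat, subject_id = zdf$subject_id,
                       group = zdf$group, normality = NULL),
                  class = "zmap")

dist_stats <- compare_distributions(zmap)
write.table(dist_stats, "results/zmap/dist_stats.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("composites with FDR-significant distribution differences (q < 0.05):\n")
sig <- dist_stats[dist_stats$q_fdr < 0.05, ]
print(sig[order(sig$q_fdr), c("composite", "ks_d", "p_uncorrected", "q_fdr",
                              "patient_mean_z", "patient_var_z")],
      row.names = FALSE, digits = 3)

# per-region z-scores from the corrected table for the T-statistic map
baselines <- default_region_baselines()
corrected <- read_morphometry("results/zmap/corrected.csv",
                              "results/zmap/metadata.csv",
                              stats::setNames(baselines$measure_class,
                                              baselines$region),
                              etiv_normalized = TRUE, allow_negative = TRUE)
rz <- build_zmap(corrected, screen = FALSE)
region_stats <- region_tstats(patient_z(rz), control_z(rz))
write.table(region_stats, "results/zmap/region_stats.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nregions with FDR-significant Welch T (q < 0.05):",
    sum(region_stats$q_fdr < 0.05, na.rm = TRUE), "of",
    nrow(region_stats), "\n")
cat("wrote results/zmap/dist_stats.tsv and region_stats.tsv\n")
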