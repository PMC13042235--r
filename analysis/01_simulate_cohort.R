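#!/usr/bin/env Rscript
# Simulate the study cohort: 41 healthy controls and 62 patients (aged
# 12-25) with three planted imaging endophenotypes — subcortical reduction,
# increased cortical thickness, decreased cortical thickness — over 129
# FreeSurfer-style regions. Writes the cohort tables that the later stages
# consume.

suppressPackageStartupMessages(library(zmapendo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

print(cohort)
cat("\nAge, controls:",
    describe_group(cohort$table$metadata$age[
      cohort$table$metadata$group == "control"], "continuous")$text, "\n")
cat("Age, patients:",
    describe_group(cohort$table$metadata$age[
      cohort$table$metadata$group == "patient"], "continuous")$text, "\n")
cat("\nwrote results/cohort/{morphometry,metadata,truth}.csv and regionmap.yaml\n")
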