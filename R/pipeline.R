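# Orchestration: QC -> eTIV normalization -> normative correction ->
# composite aggregation -> z-mapping -> distribution comparison ->
# endophenotyping -> group comparison, from one config, with a manifest of
# every artifact produced.

#' Pipeline configuration
#'
#' Either a synthetic-cohort specification (`synth`) or input paths
#' (`morphometry`, `metadata`, `region_map_path` plus a `measure_class`
#' map). All stage seeds derive from the master `seed` so individual stages
#' are reproducible in isolation.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param synth a [cohort_config()] to simulate the cohort, or `NULL`.
#' @param morphometry,metadata,region_map_path input CSV/CSV/YAML paths
#'   (used when `synth` is `NULL`).
#' @param measure_class named vector region -> class for file input.
#' @param fit_cohort `"controls"` or `"pooled"` for the correction fit.
#' @param aggregate_then_correct sensitivity option: aggregate composites
#'   first and correct at the composite level (default corrects regions,
#'   then aggregates, matching the method order).
#' @param screen_threshold_sd outlier-screen threshold (SD).
#' @param screen_on_normalized screen on eTIV-normalized values (default) or
#'   raw volumes.
#' @param drop_failing_normality drop composites failing the normality gate
#'   instead of flagging them.
#' @param k_range candidate cluster numbers.
#' @param boot_B bootstrap resamples for Jaccard stability.
#' @param gap_B gap-statistic reference draws.
#' @param n_init K-means restarts.
#' @param method clustering method for the endophenotyping.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synth = cohort_config(),
                            morphometry = NULL, metadata = NULL,
                            region_map_path = NULL, measure_class = NULL,
                            fit_cohort = "controls",
                            aggregate_then_correct = FALSE,
                            screen_threshold_sd = 3.0,
                            screen_on_normalized = TRUE,
                            drop_failing_normality = FALSE,
                            k_range = 2:5, boot_B = 500, gap_B = 100,
                            n_init = 50, method = "kmeans", seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  problems <- character()
  if (is.null(config$synth)) {
    for (f in c("morphometry", "metadata", "region_map_path")) {
      if (is.null(config[[f]]))
        problems <- c(problems, paste0("missing input: ", f))
      else if (!file.exists(config[[f]]))
        problems <- c(problems, paste0("no such file: ", config[[f]]))
    }
    if (is.null(config$measure_class))
      problems <- c(problems, "measure_class map required for file input")
  } else if (!inherits(config$synth, "cohort_config")) {
    problems <- c(problems, "synth must be a cohort_config")
  }
  if (!config$fit_cohort %in% c("controls", "pooled"))
    problems <- c(problems, "fit_cohort must be 'controls' or 'pooled'")
  if (min(config$k_range) < 2)
    problems <- c(problems, "k_range must start at 2 or above")
  abort_if(length(problems) > 0,
           "invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  invisible(config)
}

#' Run the full endophenotyping pipeline
#'
#' Executes the stages in method order — outlier QC, eTIV normalization,
#' normative correction, composite aggregation, z-mapping with the normality
#' gate, Kolmogorov-Smirnov distribution comparison, per-region T
#' statistics, endophenotyping with k selection and stability, and
#' endophenotype-wise clinical comparison — writing every table/report under
#' `out_dir` and returning a manifest with per-artifact checksums, stage
#' timings and collected warnings. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest` list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(schema = "zmapendo/manifest/1",
                   package_version = as.character(utils::packageVersion("zmapendo")),
                   seed = config$seed, stages = list(), warnings = character())
  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(withCallingHandlers(expr, warning = note),
                    error = function(e)
                      stop("stage '", name, "' failed: ", conditionMessage(e),
                           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # config hash (on the JSON serialization of the config, cohort inputs aside)
  cfg_json <- out("config.json")
  cfg_ser <- config
  cfg_ser$out_dir <- NULL  # analysis parameters only: the hash must not
                           # depend on where the artifacts land
  cfg_ser$synth <- if (!is.null(config$synth)) {
    s <- config$synth
    s$region_map <- NULL; s$region_baselines <- NULL; s$endophenotypes <- NULL
    s
  }
  jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  # ingest ------------------------------------------------------------------
  ing <- stage("ingest", {
    if (!is.null(config$synth)) {
      cohort <- generate_cohort(config$synth)
      list(table = cohort$table, map = cohort$map,
           truth = cohort$true_labels)
    } else {
      list(table = read_morphometry(config$morphometry, config$metadata,
                                    config$measure_class),
           map = read_region_map(config$region_map_path), truth = NULL)
    }
  })
  table <- ing$table; map <- ing$map

  # eTIV normalization + outlier screen -------------------------------------
  table_n <- stage("normalize", normalize_by_etiv(table))
  qc <- stage("qc", {
    basis <- if (config$screen_on_normalized) table_n else table
    rep <- screen_outliers(basis, threshold_sd = config$screen_threshold_sd)
    write_qc_report(rep, out("qc.json"))
    rep
  })
  if (nrow(qc$excluded_subjects) > 0)
    table_n <- drop_subjects(table_n, qc$excluded_subjects$subject_id)
  write_morphometry(table_n, out("normalized.csv"))

  # normative correction + aggregation --------------------------------------
  if (!config$aggregate_then_correct) {
    models <- stage("correction", fit_correction_models(
      table_n, fit_cohort = config$fit_cohort))
    corrected <- apply_correction(models, table_n)
    write_correction_models(models, out("models.json"))
    write_morphometry(corrected, out("corrected.csv"))
    composites <- stage("aggregate", aggregate_composites(corrected, map))
  } else {
    composites0 <- stage("aggregate", aggregate_composites(table_n, map))
    comp_tab <- structure(list(values = composites0$values,
                               metadata = composites0$metadata,
                               measure_class = composites0$measure_class,
                               etiv_normalized = TRUE),
                          class = "morph_table")
    models <- stage("correction", fit_correction_models(
      comp_tab, fit_cohort = config$fit_cohort))
    corrected_c <- apply_correction(models, comp_tab)
    write_correction_models(models, out("models.json"))
    composites <- structure(list(values = corrected_c$values,
                                 metadata = corrected_c$metadata,
                                 measure_class = composites0$measure_class,
                                 aggregation = composites0$aggregation),
                            class = "composite_table")
    corrected <- NULL
  }
  write.csv(data.frame(subject_id = rownames(composites$values),
                       composites$values, check.names = FALSE),
            out("composites.csv"), row.names = FALSE)

  # z-mapping ----------------------------------------------------------------
  zmap <- stage("zmap", build_zmap(composites,
                                   drop_failing = config$drop_failing_normality))
  write_zmap(zmap, out("zmap.csv"))

  # distribution comparison ---------------------------------------------------
  dist_stats <- stage("distributions", compare_distributions(zmap))
  utils::write.table(dist_stats, out("dist_stats.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  region_stats <- stage("region_stats", {
    if (is.null(corrected)) NULL else {
      rz <- build_zmap(corrected, screen = FALSE)
      rs <- region_tstats(patient_z(rz), control_z(rz))
      utils::write.table(rs, out("region_stats.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      rs
    }
  })

  # endophenotyping ------------------------------------------------------------
  endo <- stage("endophenotyping", endophenotype(
    zmap, map, k_range = config$k_range, method = config$method,
    B_boot = config$boot_B, B_ref = config$gap_B,
    seed = stage_seed(config$seed, 10), n_init = config$n_init))
  nm <- endo$assignment$names
  if (all(nm == "unlabeled"))  # naming rule is defined for k = 3 only
    nm <- stats::setNames(paste0("cluster_", names(nm)), names(nm))
  labels_named <- stats::setNames(unname(nm[as.character(endo$result$labels)]),
                                  names(endo$result$labels))
  write.csv(data.frame(subject_id = names(endo$result$labels),
                       cluster = unname(endo$result$labels),
                       endophenotype = unname(labels_named)),
            out("labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schema = "zmapendo/clustering/1", method = config$method,
         selected_k = endo$selected_k, wss = endo$wss,
         elbow_k = endo$elbow$k_star, gap = endo$gap$gap, gap_se = endo$gap$se,
         gap_k = endo$gap$k_star,
         jaccard_per_cluster = as.list(endo$stability$per_cluster),
         jaccard_overall = endo$stability$overall,
         sizes = endo$summary$size, percent = endo$summary$percent,
         pca_var_frac = endo$pca$var_frac[1:2]),
    out("diagnostics.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.table(
    data.frame(cluster = rownames(endo$result$centroids) %||%
                 seq_len(nrow(endo$result$centroids)),
               endophenotype = unname(endo$assignment$names),
               endo$result$centroids, check.names = FALSE),
    out("clustermeans.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)

  # group comparison -----------------------------------------------------------
  comparison <- stage("group_comparison", {
    cmp <- compare_groups(table_n$metadata, labels_named)
    write_comparison(cmp, out("group_comparison.tsv"))
    cmp
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(structure(c(manifest,
                        list(zmap = zmap, dist_stats = dist_stats,
                             region_stats = region_stats, endo = endo,
                             comparison = comparison, qc = qc,
                             truth = ing$truth)),
                      class = "run_manifest"))
}

#' In-memory cohort-to-Z-map path
#'
#' Runs the analysis stages up to the Z-map without touching the file
#' system: eTIV normalization, optional outlier screen, normative
#' correction, composite aggregation, z-scoring. Convenience wrapper used by
#' simulation studies; [run_pipeline()] is the artifact-producing variant.
#'
#' @param cohort a `synthetic_cohort` (or list with `table` and `map`).
#' @param fit_cohort `"controls"` or `"pooled"`.
#' @param screen run the outlier screen and drop flagged subjects.
#' @param drop_failing_normality forwarded to [build_zmap()].
#' @return list with `zmap`, `corrected`, `composites`, `map`, `truth`,
#'   `qc`.
#' @export
zmap_from_cohort <- function(cohort, fit_cohort = "controls", screen = TRUE,
                             drop_failing_normality = FALSE) {
  table_n <- normalize_by_etiv(cohort$table)
  qc <- NULL
  if (screen) {
    qc <- screen_outliers(table_n)
    if (nrow(qc$excluded_subjects) > 0)
      table_n <- drop_subjects(table_n, qc$excluded_subjects$subject_id)
  }
  models <- fit_correction_models(table_n, fit_cohort = fit_cohort)
  corrected <- apply_correction(models, table_n)
  composites <- aggregate_composites(corrected, cohort$map)
  zmap <- build_zmap(composites, drop_failing = drop_failing_normality)
  truth <- cohort$true_labels
  if (!is.null(truth))
    truth <- truth[names(truth) %in% table_n$metadata$subject_id]
  list(zmap = zmap, corrected = corrected, composites = composites,
       map = cohort$map, truth = truth, qc = qc)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "|",
      length(x$checksums), "artifacts |",
      round(x$total_seconds, 1), "s\n")
  cat("  selected k =", x$endo$selected_k, "| sizes:",
      paste(x$endo$summary$size, collapse = "/"), "\n")
  invisible(x)
}
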