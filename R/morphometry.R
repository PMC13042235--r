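# Morphometry container, delimited-text IO, eTIV normalization and cohort QC.

MEASURE_CLASSES <- c("cortical_thickness", "subcortical_volume",
                     "white_matter_volume", "unclassified")
VOLUME_CLASSES <- c("subcortical_volume", "white_matter_volume")

#' Construct a morphometry table
#'
#' Couples a subjects-by-regions measurement matrix (FreeSurfer-style
#' regional cortical thickness in mm and segmentation volumes in mm^3) with
#' per-subject covariates and a per-region measure class.
#'
#' @param values numeric matrix, one row per subject, one column per region;
#'   row names are subject ids, column names region names. `NA` encodes an
#'   explicitly missing cell; negative values are rejected.
#' @param metadata data.frame with one row per subject in the same order as
#'   `values`. Must contain `subject_id`, `group` ("control"/"patient"),
#'   `age` (years), `sex` ("F"/"M"), `etiv` and `brainseg_vol` (mm^3);
#'   further clinical/cognitive columns are carried along.
#' @param measure_class named character vector mapping every region to one of
#'   `"cortical_thickness"`, `"subcortical_volume"`, `"white_matter_volume"`
#'   or `"unclassified"`.
#' @param etiv_normalized logical provenance flag; set by
#'   [normalize_by_etiv()] so the division cannot be applied twice.
#' @param allow_negative permit negative cells (covariate-corrected tables
#'   may legitimately dip below zero; raw morphometry never should).
#' @return an object of class `morph_table`.
#' @export
morphometry_table <- function(values, metadata, measure_class,
                              etiv_normalized = FALSE,
                              allow_negative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  abort_if(is.null(colnames(values)), "`values` must have region column names")
  abort_if(anyDuplicated(colnames(values)) > 0, "duplicate region names")
  dup <- metadata$subject_id[duplicated(metadata$subject_id)]
  abort_if(length(dup) > 0,
           "duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  abort_if(nrow(values) != nrow(metadata),
           "values and metadata disagree on the number of subjects")
  rownames(values) <- metadata$subject_id
  abort_if(!allow_negative && any(values < 0, na.rm = TRUE),
           "negative morphometry values")

  need <- c("subject_id", "group", "age", "sex", "etiv", "brainseg_vol")
  miss <- setdiff(need, names(metadata))
  abort_if(length(miss) > 0, "metadata lacks columns: ", paste(miss, collapse = ", "))
  abort_if(!all(metadata$group %in% c("control", "patient")),
           "group must be 'control' or 'patient'")
  abort_if(!all(metadata$sex %in% c("F", "M")), "sex must be 'F' or 'M'")
  abort_if(any(metadata$age <= 0, na.rm = TRUE), "age must be positive")

  measure_class <- measure_class[colnames(values)]
  names(measure_class) <- colnames(values)
  measure_class[is.na(measure_class)] <- "unclassified"
  abort_if(!all(measure_class %in% MEASURE_CLASSES),
           "invalid measure_class value(s)")

  structure(list(values = values, metadata = metadata,
                 measure_class = measure_class,
                 etiv_normalized = isTRUE(etiv_normalized)),
            class = "morph_table")
}

#' @export
print.morph_table <- function(x, ...) {
  n <- table(factor(x$metadata$group, c("control", "patient")))
  cat("<morph_table> ", nrow(x$values), " subjects (",
      n[["control"]], " controls, ", n[["patient"]], " patients), ",
      ncol(x$values), " regions",
      if (x$etiv_normalized) ", eTIV-normalized" else "", "\n", sep = "")
  cat("  classes:", paste(names(table(x$measure_class)),
                          table(x$measure_class), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of subjects / regions of a morphometry table
#' @param table a `morph_table`.
#' @return integer count.
#' @export
n_subjects <- function(table) nrow(table$values)

#' @rdname n_subjects
#' @export
regions <- function(table) colnames(table$values)

#' Read a morphometry table from delimited text
#'
#' Expects a wide comma-separated file (UTF-8, "." decimal, header row) with a
#' `subject_id` column and one column per region, plus a metadata file with
#' one row per subject, joinable on `subject_id`. Missing cells are encoded
#' as empty strings and come back as `NA`.
#'
#' @param path morphometry CSV.
#' @param metadata either the path of a metadata CSV or a data.frame.
#' @param measure_class named character vector region -> class; regions absent
#'   from it are retained with a warning as `"unclassified"`.
#' @param etiv_normalized provenance flag for tables already divided by eTIV.
#' @param allow_negative forwarded to [morphometry_table()] (use for
#'   covariate-corrected tables).
#' @return a [morphometry_table()].
#' @export
read_morphometry <- function(path, metadata, measure_class,
                             etiv_normalized = FALSE,
                             allow_negative = FALSE) {
  abort_if(!file.exists(path), "no such file: ", path)
  wide <- read.csv(path, check.names = FALSE, na.strings = "",
                   stringsAsFactors = FALSE)
  abort_if(!"subject_id" %in% names(wide), "header must name a subject_id column")
  dup <- wide$subject_id[duplicated(wide$subject_id)]
  abort_if(length(dup) > 0,
           "duplicate subject row(s): ", paste(unique(dup), collapse = ", "))
  if (is.character(metadata)) {
    abort_if(!file.exists(metadata), "no such file: ", metadata)
    metadata <- read.csv(metadata, check.names = FALSE, na.strings = "",
                         stringsAsFactors = FALSE)
  }
  abort_if(!all(wide$subject_id %in% metadata$subject_id),
           "subjects missing from metadata")
  metadata <- metadata[match(wide$subject_id, metadata$subject_id), , drop = FALSE]
  rownames(metadata) <- NULL
  vals <- as.matrix(wide[, setdiff(names(wide), "subject_id"), drop = FALSE])
  unknown <- setdiff(colnames(vals), names(measure_class))
  if (length(unknown) > 0)
    warning("unclassified region column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  morphometry_table(vals, metadata, measure_class,
                    etiv_normalized = etiv_normalized,
                    allow_negative = allow_negative)
}

#' Write a morphometry table (and its metadata) as CSV
#'
#' Inverse of [read_morphometry()]: `read_morphometry(write_morphometry(x))`
#' is the identity on valid tables, cell-exact.
#'
#' @param table a `morph_table`.
#' @param path output CSV for the measurement matrix.
#' @param metadata_path optional output CSV for the metadata.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(table, path, metadata_path = NULL) {
  df <- data.frame(subject_id = rownames(table$values),
                   table$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(metadata_path))
    write.csv(table$metadata, metadata_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalize volumes by estimated total intracranial volume
#'
#' Divides every subcortical and white-matter volume cell by that subject's
#' eTIV, turning mm^3 into a dimensionless fraction of intracranial volume.
#' Cortical thickness is a length, not a volume, and is left unchanged. The
#' division must be applied exactly once per table; a provenance flag
#' enforces this.
#'
#' @param table a `morph_table`.
#' @param classes measure classes to normalize; defaults to both volume
#'   classes.
#' @return the normalized `morph_table` with `etiv_normalized = TRUE`.
#' @export
normalize_by_etiv <- function(table, classes = VOLUME_CLASSES) {
  abort_if(table$etiv_normalized,
           "table is already eTIV-normalized; the division must be applied exactly once")
  etiv <- table$metadata$etiv
  bad <- which(is.na(etiv) | etiv <= 0)
  abort_if(length(bad) > 0, "non-positive or missing eTIV for subject(s): ",
           paste(table$metadata$subject_id[bad], collapse = ", "))
  idx <- which(table$measure_class %in% classes)
  table$values[, idx] <- table$values[, idx, drop = FALSE] / etiv
  table$etiv_normalized <- TRUE
  table
}

#' Screen for cohort-level outliers on a composite volume
#'
#' Flags subjects whose screen value lies more than `threshold_sd` sample
#' standard deviations (two-sided) from the pooled patients-plus-controls
#' mean. The default screen variable is total thalamic volume, the bilateral
#' sum over all thalamic-nucleus regions.
#'
#' @param table a `morph_table` (by default screened after eTIV
#'   normalization; pass a raw table to screen raw volumes).
#' @param members regions summed into the screen variable; `NULL` selects all
#'   regions whose name contains "thal" (case-insensitive).
#' @param variable label of the screen variable for the report.
#' @param threshold_sd exclusion threshold in pooled-SD units (> 0).
#' @return a `qc_report`: list with `excluded_subjects` (data.frame of
#'   subject_id, reason, deviation_sd to 1 decimal), `screen_variable`,
#'   `threshold_sd`, `n_screened`.
#' @export
screen_outliers <- function(table, members = NULL,
                            variable = "total_thalamic_volume",
                            threshold_sd = 3.0) {
  abort_if(!is.numeric(threshold_sd) || threshold_sd <= 0,
           "threshold_sd must be > 0")
  abort_if(n_subjects(table) < 3, "need at least 3 subjects to screen")
  if (is.null(members))
    members <- grep("thal", regions(table), ignore.case = TRUE, value = TRUE)
  abort_if(length(members) == 0, "no screen regions found")
  abort_if(!all(members %in% regions(table)),
           "screen member(s) absent from table")
  value <- rowSums(table$values[, members, drop = FALSE])
  mu <- mean(value, na.rm = TRUE)
  sdev <- sample_sd(value[!is.na(value)])
  abort_if(!is.finite(sdev) || sdev == 0, "degenerate screen variable")
  z <- (value - mu) / sdev
  flagged <- which(!is.na(z) & abs(z) > threshold_sd)
  excluded <- data.frame(
    subject_id = table$metadata$subject_id[flagged],
    reason = rep(sprintf("|%s - pooled mean| > %.1f SD", variable, threshold_sd),
                 length(flagged)),
    deviation_sd = round(abs(z[flagged]), 1),
    stringsAsFactors = FALSE)
  structure(list(excluded_subjects = excluded, screen_variable = variable,
                 threshold_sd = threshold_sd, n_screened = sum(!is.na(z))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> screen on", x$screen_variable, "at", x$threshold_sd, "SD:",
      nrow(x$excluded_subjects), "of", x$n_screened, "subjects excluded\n")
  if (nrow(x$excluded_subjects) > 0) print(x$excluded_subjects)
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(schema = "zmapendo/qc_report/1",
         screen_variable = report$screen_variable,
         threshold_sd = report$threshold_sd,
         n_screened = report$n_screened,
         excluded_subjects = report$excluded_subjects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Drop subjects from a morphometry table
#' @param table a `morph_table`.
#' @param subject_ids ids to remove.
#' @return the reduced `morph_table`.
#' @export
drop_subjects <- function(table, subject_ids) {
  keep <- !(table$metadata$subject_id %in% subject_ids)
  morphometry_table(table$values[keep, , drop = FALSE],
                    table$metadata[keep, , drop = FALSE],
                    table$measure_class,
                    etiv_normalized = table$etiv_normalized)
}
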