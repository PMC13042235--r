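# Composite aggregation, normality screening of the normative distributions,
# and z-scoring: leave-one-out for controls, full-control-distribution for
# patients.

#' Aggregate corrected regions into lobar composites
#'
#' Thickness composites are the arithmetic mean of their member regions,
#' volume composites the sum. A missing member makes the composite missing
#' for that subject — no partial aggregation.
#'
#' @param table a (typically corrected) `morph_table`.
#' @param map a [region_map()].
#' @return a `composite_table`: list with `values` (subjects x composites),
#'   `metadata`, `measure_class` and `aggregation` per composite.
#' @export
aggregate_composites <- function(table, map) {
  vals <- sapply(map, function(cmp) {
    abort_if(!all(cmp$members %in% regions(table)),
             "composite ", cmp$name, ": member(s) absent from table")
    cls <- unique(table$measure_class[cmp$members])
    abort_if(length(cls) > 1,
             "composite ", cmp$name, ": mixed measure_class ",
             paste(cls, collapse = "/"))
    sub <- table$values[, cmp$members, drop = FALSE]
    if (cmp$aggregation == "mean") rowMeans(sub) else rowSums(sub)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(table$metadata$subject_id,
                                                         composite_names(map)))
  colnames(vals) <- composite_names(map)
  rownames(vals) <- table$metadata$subject_id
  structure(list(values = vals, metadata = table$metadata,
                 measure_class = stats::setNames(
                   vapply(map, `[[`, "", "measure_class"), composite_names(map)),
                 aggregation = stats::setNames(
                   vapply(map, `[[`, "", "aggregation"), composite_names(map))),
            class = "composite_table")
}

#' @export
print.composite_table <- function(x, ...) {
  cat("<composite_table>", nrow(x$values), "subjects x", ncol(x$values),
      "composites\n")
  invisible(x)
}

#' Screen a normative distribution for approximate normality
#'
#' Gates used before z-scoring: moment skewness |g1| < 1, moment excess
#' kurtosis |g2| < 3 and Shapiro-Wilk P > 0.05, applied to the control
#' values of a composite. Failing composites are retained downstream but
#' flagged in all outputs (dropping them is a pipeline option).
#'
#' @param x numeric vector of control values (n >= `min_n` non-missing).
#' @param min_n minimum sample size.
#' @return list with `skewness`, `excess_kurtosis`, `shapiro_w`, `shapiro_p`
#'   and `pass`.
#' @export
screen_normality <- function(x, min_n = 8) {
  x <- x[!is.na(x)]
  abort_if(length(x) < min_n, "need >= ", min_n, " non-missing values (have ",
           length(x), ")")
  abort_if(sample_sd(x) == 0, "degenerate composite")
  g1 <- e1071::skewness(x, type = 1)
  g2 <- e1071::kurtosis(x, type = 1)
  sw <- shapiro.test(x)
  list(skewness = g1, excess_kurtosis = g2,
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       pass = abs(g1) < 1 && abs(g2) < 3 && sw$p.value > 0.05)
}

#' Normality report for every composite of a table
#'
#' @param composites a `composite_table`.
#' @param min_n forwarded to [screen_normality()].
#' @return data.frame with one row per composite.
#' @export
screen_normality_table <- function(composites, min_n = 8) {
  ctrl <- composites$metadata$group == "control"
  rows <- lapply(colnames(composites$values), function(cn) {
    rep <- screen_normality(composites$values[ctrl, cn], min_n = min_n)
    data.frame(composite = cn, skewness = rep$skewness,
               excess_kurtosis = rep$excess_kurtosis,
               shapiro_w = rep$shapiro_w, shapiro_p = rep$shapiro_p,
               pass = rep$pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-out z-scores for the normative cohort
#'
#' Each control is standardized against the mean and sample SD (n-1
#' denominator over the n-1 retained values) of all other controls, avoiding
#' self-inclusion bias: `z_i = (x_i - mean_{-i}) / sd_{-i}`.
#'
#' @param x numeric vector of control values; names (subject ids) are
#'   preserved. `NA` values yield `NA` z-scores and are excluded from every
#'   holdout statistic.
#' @return numeric vector of z-scores aligned to `x`.
#' @export
loo_zscores <- function(x) {
  obs <- which(!is.na(x))
  n <- length(obs)
  abort_if(n < 3, "need >= 3 non-missing controls")
  v <- x[obs]
  s1 <- sum(v); s2 <- sum(v^2)
  m_i <- (s1 - v) / (n - 1)
  # sample variance of the n-1 retained values (n-2 denominator)
  var_i <- (s2 - v^2 - (n - 1) * m_i^2) / (n - 2)
  var_i <- pmax(var_i, 0)
  sd_i <- sqrt(var_i)
  bad <- which(sd_i == 0)
  abort_if(length(bad) > 0, "zero holdout SD for: ",
           paste(names(v)[bad] %||% obs[bad], collapse = ", "))
  z <- rep(NA_real_, length(x))
  z[obs] <- (v - m_i) / sd_i
  names(z) <- names(x)
  z
}

#' Z-score patients against the full control distribution
#'
#' `z = (x - mean(controls)) / sd(controls)` with the sample SD. Missing
#' patient values stay missing (no imputation).
#'
#' @param patients numeric vector of patient values.
#' @param controls numeric vector of control values (n >= 3 non-missing).
#' @return numeric vector of patient z-scores aligned to `patients`.
#' @export
zscore_patients <- function(patients, controls) {
  controls <- controls[!is.na(controls)]
  abort_if(length(controls) < 3, "need >= 3 non-missing controls")
  sdev <- sample_sd(controls)
  abort_if(sdev == 0, "zero control SD")
  (patients - mean(controls)) / sdev
}

#' Build a Z-map from a (composite or regional) table
#'
#' Controls are z-scored leave-one-out, patients against the full control
#' distribution, column by column. Columns failing the normality gate are
#' flagged (and optionally dropped).
#'
#' @param table a `composite_table` or corrected `morph_table`.
#' @param drop_failing drop columns failing the normality gate instead of
#'   flagging them (default `FALSE`: flag only).
#' @param screen run the normality gate at all (disable for per-region maps
#'   of small regions where the gate is not meaningful).
#' @return a `zmap`: list with `z` (subjects x columns), `subject_id`,
#'   `group`, `method` per subject ("loo"/"full"), `normative_n`, and the
#'   `normality` report (or `NULL`).
#' @export
build_zmap <- function(table, drop_failing = FALSE, screen = TRUE) {
  md <- table$metadata
  ctrl <- md$group == "control"
  vals <- table$values
  normality <- NULL
  if (screen) {
    normality <- do.call(rbind, lapply(colnames(vals), function(cn) {
      rep <- screen_normality(vals[ctrl, cn])
      data.frame(composite = cn, skewness = rep$skewness,
                 excess_kurtosis = rep$excess_kurtosis,
                 shapiro_w = rep$shapiro_w, shapiro_p = rep$shapiro_p,
                 pass = rep$pass, stringsAsFactors = FALSE)
    }))
    if (drop_failing && any(!normality$pass))
      vals <- vals[, normality$composite[normality$pass], drop = FALSE]
  }
  z <- vals
  for (cn in colnames(vals)) {
    cv <- stats::setNames(vals[ctrl, cn], md$subject_id[ctrl])
    z[ctrl, cn] <- loo_zscores(cv)
    z[!ctrl, cn] <- zscore_patients(vals[!ctrl, cn], cv)
  }
  abort_if(any(is.infinite(z)), "infinite z-scores produced")
  structure(list(z = z, subject_id = md$subject_id,
                 group = md$group,
                 method = ifelse(ctrl, "loo", "full"),
                 normative_n = sum(ctrl & rowSums(is.na(vals)) == 0),
                 normality = normality),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat("<zmap>", nrow(x$z), "subjects x", ncol(x$z), "columns; normative n =",
      x$normative_n, "\n")
  if (!is.null(x$normality) && any(!x$normality$pass))
    cat("  normality gate flagged:",
        paste(x$normality$composite[!x$normality$pass], collapse = ", "), "\n")
  invisible(x)
}

#' Patient / control sub-matrices of a Z-map
#' @param zmap a `zmap`.
#' @return numeric matrix of z-scores.
#' @export
patient_z <- function(zmap) zmap$z[zmap$group == "patient", , drop = FALSE]

#' @rdname patient_z
#' @export
control_z <- function(zmap) zmap$z[zmap$group == "control", , drop = FALSE]

#' Write a Z-map as CSV plus a JSON sidecar
#'
#' @param zmap a `zmap`.
#' @param path CSV path for the z matrix; the sidecar (normative n, per-
#'   subject method, normality gate) goes to the same path with extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_zmap <- function(zmap, path) {
  write.csv(data.frame(subject_id = zmap$subject_id, group = zmap$group,
                       zmap$z, check.names = FALSE),
            path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(schema = "zmapendo/zmap/1", normative_n = zmap$normative_n,
         method = stats::setNames(as.list(zmap$method), zmap$subject_id),
         normality = zmap$normality),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
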