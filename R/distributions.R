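# Patient-vs-control distribution comparison: two-sample Kolmogorov-Smirnov
# per composite with Benjamini-Hochberg FDR across the composite family, and
# per-region Welch T statistics for map-style reporting.

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided `D = sup_x |F_pat(x) - F_ctrl(x)|`. By default the exact
#' two-sample null distribution is used when `n_pat * n_ctrl < 10000` and the
#' asymptotic formula otherwise (the standard rule; at the modelled sample
#' sizes the exact test keeps the type-I rate at its nominal level, where the
#' asymptotic formula is conservative). Pass `exact = FALSE`/`TRUE` to force
#' either.
#'
#' @param z_patients,z_controls numeric vectors (each n >= 5 non-missing).
#' @param exact `NULL` (auto), `TRUE` or `FALSE`.
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(z_patients, z_controls, exact = NULL) {
  z_patients <- z_patients[!is.na(z_patients)]
  z_controls <- z_controls[!is.na(z_controls)]
  abort_if(length(z_patients) < 5 || length(z_controls) < 5,
           "need >= 5 non-missing values per group")
  kt <- suppressWarnings(ks.test(z_patients, z_controls, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values aligned to the input.
#' @export
fdr_adjust <- function(p_values) {
  abort_if(any(is.na(p_values)) || any(p_values < 0 | p_values > 1),
           "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Compare patient and control z distributions per composite
#'
#' One Kolmogorov-Smirnov test per composite, FDR-corrected within the
#' composite family, with group means and variances reported alongside
#' (the variance columns carry the heavy-tail signal that motivates testing
#' distribution shape rather than location only).
#'
#' @param zmap a `zmap`.
#' @param exact forwarded to [ks_compare()] (`NULL` = auto).
#' @return data.frame with one row per composite: `composite`, `ks_d`,
#'   `p_uncorrected`, `q_fdr`, `n_patient`, `n_control`, `patient_mean_z`,
#'   `control_mean_z`, `patient_var_z`, `control_var_z`.
#' @export
compare_distributions <- function(zmap, exact = NULL) {
  zp <- patient_z(zmap); zc <- control_z(zmap)
  rows <- lapply(colnames(zmap$z), function(cn) {
    ks <- ks_compare(zp[, cn], zc[, cn], exact = exact)
    data.frame(composite = cn, ks_d = ks$D, p_uncorrected = ks$p,
               n_patient = sum(!is.na(zp[, cn])),
               n_control = sum(!is.na(zc[, cn])),
               patient_mean_z = mean(zp[, cn], na.rm = TRUE),
               control_mean_z = mean(zc[, cn], na.rm = TRUE),
               patient_var_z = var(zp[, cn], na.rm = TRUE),
               control_var_z = var(zc[, cn], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- fdr_adjust(out$p_uncorrected)
  out[, c("composite", "ks_d", "p_uncorrected", "q_fdr", "n_patient",
          "n_control", "patient_mean_z", "control_mean_z", "patient_var_z",
          "control_var_z")]
}

#' Per-region mean Z and T statistics
#'
#' Welch two-sample t per region on the z-scores (positive t means the
#' patient mean exceeds the control mean), FDR-corrected across the region
#' family; the patient mean z is reported alongside for map-style outputs.
#'
#' @param z_patients,z_controls numeric matrices (subjects x regions) with
#'   matching columns.
#' @param pooled_var use the pooled-variance t instead of Welch.
#' @return data.frame with `region`, `mean_z_patient`, `t_stat`, `p`,
#'   `q_fdr`; regions with zero variance in both groups come back `NA` with
#'   a warning.
#' @export
region_tstats <- function(z_patients, z_controls, pooled_var = FALSE) {
  abort_if(!identical(colnames(z_patients), colnames(z_controls)),
           "patient and control matrices must share regions")
  rows <- lapply(colnames(z_patients), function(cn) {
    x <- z_patients[, cn]; y <- z_controls[, cn]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    abort_if(length(x) < 2 || length(y) < 2, "need n >= 2 per group for ", cn)
    if (var(x) == 0 && var(y) == 0) {
      warning("zero variance in both groups for ", cn, "; t undefined",
              call. = FALSE)
      return(data.frame(region = cn, mean_z_patient = mean(x),
                        t_stat = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, y, var.equal = pooled_var)
    data.frame(region = cn, mean_z_patient = mean(x),
               t_stat = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q_fdr <- NA_real_
  out$q_fdr[ok] <- fdr_adjust(out$p[ok])
  out
}
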