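# Endophenotype-wise comparison of demographic, clinical, cognitive and
# psychiatric variables: per-group summaries and pairwise tests (Wilcoxon
# rank-sum for continuous, Fisher exact for categorical), uncorrected
# p-values by default.

#' Default clinical variable declarations for the synthetic cohort
#'
#' @return named character vector, variable -> "continuous"/"categorical".
#' @export
default_clinical_variables <- function() {
  c(age = "continuous", sex = "categorical", adi = "continuous",
    n_asm = "continuous", gtc_controlled = "categorical",
    months_since_gtc = "continuous", abnormal_eeg = "categorical",
    duration = "continuous", age_of_onset = "continuous",
    vpa_use = "categorical", adhd = "categorical", anxiety = "categorical",
    depression = "categorical", iq = "continuous",
    general_ability = "continuous", speed_inhibition = "continuous",
    learning_memory = "continuous")
}

#' Summarize one variable within one group
#'
#' Continuous variables are formatted as
#' `"Mean: x.xx (SD: y.yy), Range: a.aa-b.bb"`; categorical/boolean
#' variables as level proportions. Computed on non-missing values, with n
#' reported.
#'
#' @param values the variable's values for the group's members.
#' @param type `"continuous"` or `"categorical"`.
#' @return list with `n`, `text`, and (continuous) `mean`, `sd`, `range` or
#'   (categorical) `proportions`.
#' @export
describe_group <- function(values, type = c("continuous", "categorical")) {
  type <- match.arg(type)
  v <- values[!is.na(values)]
  if (length(v) == 0)
    return(list(n = 0L, text = "all missing"))
  if (type == "continuous") {
    m <- mean(v)
    s <- if (length(v) > 1) sample_sd(v) else 0
    out <- list(n = length(v), mean = m, sd = s, range = range(v),
                degenerate = length(v) == 1,
                text = sprintf("Mean: %s (SD: %s), Range: %s\u2013%s",
                               fmt_num(m), fmt_num(s),
                               fmt_num(min(v)), fmt_num(max(v))))
  } else {
    p <- prop.table(table(as.character(v)))
    out <- list(n = length(v), proportions = p,
                text = paste(sprintf("%s: %s", names(p), fmt_num(p)),
                             collapse = "; "))
  }
  out
}

pairwise_p <- function(x, y, type, min_n = 3) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < min_n || length(y) < min_n)
    return(list(p = NA_real_, reason = "fewer than 3 non-missing per group"))
  if (type == "continuous") {
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  } else {
    lev <- unique(c(as.character(x), as.character(y)))
    if (length(lev) < 2)
      return(list(p = 1, reason = "single level in both groups"))
    tab <- rbind(table(factor(as.character(x), lev)),
                 table(factor(as.character(y), lev)))
    p <- fisher.test(tab)$p.value
  }
  list(p = p, reason = NA_character_)
}

#' Compare endophenotype groups on clinical and cognitive variables
#'
#' For every declared variable: per-group summaries plus two-sided pairwise
#' tests over all group pairs — Wilcoxon rank-sum for continuous variables,
#' Fisher's exact test for categorical ones (cell counts at these group
#' sizes are small). P-values are uncorrected by default, matching the
#' presentation convention for endophenotype tables; `fdr = TRUE` adds a
#' global Benjamini-Hochberg column.
#'
#' @param metadata data.frame with `subject_id` and the variables.
#' @param labels named vector, subject_id -> group (e.g. endophenotype name
#'   from the clustering); subjects absent from it are ignored.
#' @param variables named character vector, variable -> type, as
#'   [default_clinical_variables()].
#' @param alpha significance flag threshold.
#' @param fdr add a BH-adjusted column over all pairwise tests.
#' @return list with `summaries` (variable x group long data.frame) and
#'   `pairwise` (variable x group-pair data.frame with `p`, `test_used`,
#'   `significant`).
#' @export
compare_groups <- function(metadata, labels, variables = default_clinical_variables(),
                           alpha = 0.05, fdr = FALSE) {
  variables <- variables[names(variables) %in% names(metadata)]
  abort_if(length(variables) == 0, "no declared variables present in metadata")
  idx <- match(names(labels), metadata$subject_id)
  abort_if(anyNA(idx), "labels name subjects absent from metadata")
  md <- metadata[idx, , drop = FALSE]
  groups <- sort(unique(unname(labels)))
  abort_if(length(groups) < 2, "need >= 2 groups")
  pairs <- utils::combn(groups, 2)

  summaries <- do.call(rbind, lapply(names(variables), function(vn) {
    do.call(rbind, lapply(groups, function(g) {
      d <- describe_group(md[[vn]][labels == g], variables[[vn]])
      data.frame(variable = vn, group = g, n = d$n, summary = d$text,
                 stringsAsFactors = FALSE)
    }))
  }))
  pairwise <- do.call(rbind, lapply(names(variables), function(vn) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      pr <- pairwise_p(md[[vn]][labels == g1], md[[vn]][labels == g2],
                       variables[[vn]])
      data.frame(variable = vn, group1 = g1, group2 = g2, p = pr$p,
                 test_used = if (variables[[vn]] == "continuous")
                   "wilcoxon_rank_sum" else "fisher_exact",
                 skipped_reason = pr$reason, stringsAsFactors = FALSE)
    }))
  }))
  pairwise$significant <- !is.na(pairwise$p) & pairwise$p < alpha
  if (fdr) {
    ok <- !is.na(pairwise$p)
    pairwise$q_fdr <- NA_real_
    pairwise$q_fdr[ok] <- fdr_adjust(pairwise$p[ok])
  }
  list(summaries = summaries, pairwise = pairwise)
}

#' Write a group-comparison table as TSV
#'
#' One row per variable: per-group summary columns followed by one p-value
#' column per group pair and a boolean significance column per pair.
#'
#' @param comparison output of [compare_groups()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  sm <- comparison$summaries; pw <- comparison$pairwise
  groups <- unique(sm$group)
  wide <- data.frame(variable = unique(sm$variable), stringsAsFactors = FALSE)
  for (g in groups)
    wide[[g]] <- sm$summary[match(paste(wide$variable, g),
                                  paste(sm$variable, sm$group))]
  for (pair in unique(paste(pw$group1, pw$group2, sep = " vs "))) {
    sel <- paste(pw$group1, pw$group2, sep = " vs ") == pair
    wide[[paste0("p: ", pair)]] <- pw$p[sel][match(wide$variable, pw$variable[sel])]
    wide[[paste0("sig: ", pair)]] <-
      pw$significant[sel][match(wide$variable, pw$variable[sel])]
  }
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
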