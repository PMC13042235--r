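# Unsupervised endophenotyping of patient Z-maps: K-means and Ward
# hierarchical clustering, cluster-number selection by elbow and gap
# statistic, bootstrapped Jaccard stability, endophenotype naming and
# cluster summaries.

drop_missing_rows <- function(z) {
  keep <- rowSums(is.na(z)) == 0
  if (!all(keep))
    warning(sum(!keep), " subject(s) with missing composites excluded from clustering",
            call. = FALSE)
  z[keep, , drop = FALSE]
}

#' K-means clustering of a patient Z-map
#'
#' Euclidean K-means (Hartigan-Wong) with `n_init` random restarts, keeping
#' the solution with the lowest within-cluster sum of squares; deterministic
#' given `seed`. `k = 1` is allowed and returns the trivial single cluster
#' (its WSS is the total sum of squares about the grand centroid).
#'
#' @param z numeric matrix, patients x composites (row names = subject ids);
#'   rows with missing values are excluded with a warning.
#' @param k number of clusters (1 <= k <= n-1).
#' @param seed RNG seed for the restarts.
#' @param n_init number of restarts.
#' @return a `clustering_result`: list with `method`, `k`, `labels` (named
#'   integer vector), `centroids`, `wss`, `seed`, `n_init`.
#' @export
kmeans_cluster <- function(z, k, seed = 1, n_init = 50) {
  z <- drop_missing_rows(as.matrix(z))
  abort_if(k < 1 || k > nrow(z), "k must satisfy 1 <= k <= n")
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = n_init, iter.max = 300)
  structure(list(method = "kmeans", k = k,
                 labels = stats::setNames(km$cluster, rownames(z)),
                 centroids = km$centers, wss = km$tot.withinss,
                 sizes = km$size, seed = seed, n_init = n_init),
            class = "clustering_result")
}

#' Ward hierarchical clustering of a patient Z-map
#'
#' Agglomerative clustering with Ward linkage (`ward.D2`, so that the merge
#' criterion operates on squared Euclidean distances) cut at `k` clusters.
#'
#' @inheritParams kmeans_cluster
#' @return a `clustering_result` (method `"hierarchical_ward"`).
#' @export
hierarchical_cluster <- function(z, k, seed = 1) {
  z <- drop_missing_rows(as.matrix(z))
  abort_if(k < 1 || k > nrow(z), "k must satisfy 1 <= k <= n")
  lab <- cutree(hclust(dist(z), method = "ward.D2"), k = k)
  centroids <- do.call(rbind, lapply(sort(unique(lab)), function(cl)
    colMeans(z[lab == cl, , drop = FALSE])))
  wss <- sum(vapply(sort(unique(lab)), function(cl) {
    sub <- z[lab == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
  structure(list(method = "hierarchical_ward", k = k,
                 labels = stats::setNames(lab, rownames(z)),
                 centroids = centroids, wss = wss,
                 sizes = as.integer(table(lab)), seed = seed, n_init = NA),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result>", x$method, "k =", x$k, "| sizes:",
      paste(x$sizes, collapse = "/"), "| WSS =", signif(x$wss, 5), "\n")
  invisible(x)
}

cluster_fun <- function(method) {
  switch(method,
         kmeans = kmeans_cluster,
         hierarchical_ward = function(z, k, seed = 1, n_init = NULL)
           hierarchical_cluster(z, k, seed = seed),
         stop("unknown clustering method: ", method, call. = FALSE))
}

#' Within-cluster sum-of-squares curve over k
#'
#' @inheritParams kmeans_cluster
#' @param k_max largest k (curve runs k = 1..k_max).
#' @param method `"kmeans"` or `"hierarchical_ward"`.
#' @return numeric vector `wss[k]`, k = 1..k_max.
#' @export
wss_curve <- function(z, k_max = 5, seed = 1, n_init = 50, method = "kmeans") {
  fun <- cluster_fun(method)
  vapply(seq_len(k_max), function(k)
    fun(z, k, seed = stage_seed(seed, k), n_init = n_init)$wss, 0)
}

#' Elbow selection of the number of clusters
#'
#' `k*` maximizes the discrete second difference
#' `wss[k-1] - 2 wss[k] + wss[k+1]` over interior k. A linear WSS decline has
#' no interior curvature exceeding tolerance, in which case `k_star` is `NA`
#' ("none") — the elbow is advisory, the curve is always reported alongside.
#'
#' @param wss non-increasing WSS values for k = 1..k_max (k_max >= 3).
#' @param tol curvature below `tol * wss[1]` counts as no elbow.
#' @return list with `k_star` (integer or `NA`) and `second_diff` (named by
#'   interior k).
#' @export
elbow_select <- function(wss, tol = 1e-3) {
  abort_if(length(wss) < 3, "need WSS for k_max >= 3")
  abort_if(any(diff(wss) > 1e-8 * max(wss[1], 1)),
           "wss must be non-increasing in k")
  interior <- 2:(length(wss) - 1)
  d2 <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
  names(d2) <- interior
  k_star <- if (max(d2) > tol * wss[1]) interior[which.max(d2)] else NA_integer_
  list(k_star = k_star, second_diff = d2)
}

#' Gap statistic for the number of clusters
#'
#' `Gap(k) = mean_b log W_k^(b) - log W_k`, with `B_ref` reference datasets
#' drawn uniformly over the PCA-aligned bounding box of the data (the
#' rotated-uniform reference), `s_k = sd_b(log W_k^(b)) * sqrt(1 + 1/B)`, and
#' `k* = ` smallest k with `Gap(k) >= Gap(k+1) - s_(k+1)`; if the inequality
#' never triggers, `k* = k_max`.
#'
#' @inheritParams kmeans_cluster
#' @param k_max largest k examined (>= 2).
#' @param B_ref number of reference datasets (>= 10).
#' @param n_init_ref restarts used on the reference draws (clustering the
#'   featureless reference needs fewer restarts than the data).
#' @param method `"kmeans"` or `"hierarchical_ward"`.
#' @return list with `gap`, `se`, `log_w`, `k_star`, `k_max`, `B_ref`.
#' @export
gap_statistic <- function(z, k_max = 5, B_ref = 100, seed = 1,
                          n_init = 50, n_init_ref = 10, method = "kmeans") {
  abort_if(k_max < 2, "k_max must be >= 2")
  abort_if(B_ref < 10, "B_ref must be >= 10")
  z <- drop_missing_rows(as.matrix(z))
  fun <- cluster_fun(method)
  log_w <- log(vapply(seq_len(k_max), function(k)
    fun(z, k, seed = stage_seed(seed, k), n_init = n_init)$wss, 0))

  ctr <- colMeans(z)
  zc <- sweep(z, 2, ctr)
  V <- svd(zc, nu = 0)$v
  zr <- zc %*% V
  lo <- apply(zr, 2, min); hi <- apply(zr, 2, max)
  # all reference datasets are drawn up front so the clustering calls (which
  # seed their own restarts) cannot perturb the reference stream
  set.seed(stage_seed(seed, 777))
  refs <- lapply(seq_len(B_ref), function(b) {
    ref_r <- sapply(seq_along(lo), function(j) runif(nrow(z), lo[j], hi[j]))
    ref_r %*% t(V) + rep(ctr, each = nrow(z))
  })
  log_w_ref <- matrix(NA_real_, B_ref, k_max)
  for (b in seq_len(B_ref)) {
    ref_seed <- stage_seed(seed, 1000 + b)
    log_w_ref[b, ] <- log(vapply(seq_len(k_max), function(k)
      fun(refs[[b]], k, seed = stage_seed(ref_seed, k),
          n_init = n_init_ref)$wss, 0))
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2, sample_sd) * sqrt(1 + 1 / B_ref)
  k_star <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { k_star <- k; break }
  }
  list(gap = gap, se = se, log_w = log_w, k_star = k_star,
       k_max = k_max, B_ref = B_ref)
}

#' Jaccard index of two membership sets
#' @param a,b vectors interpreted as sets.
#' @return `|intersect| / |union|` (1 for two identical sets).
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Bootstrapped Jaccard cluster stability
#'
#' For each of `B` bootstrap resamples of the patients, the data are
#' re-clustered with the same method and k, and each original cluster is
#' matched to the best-overlapping new cluster by the Jaccard index computed
#' on the unique subjects present in the resample (the clusterboot
#' convention). Per-cluster stability is the mean over resamples; the
#' overall value is the unweighted mean over clusters. Values around 0.75
#' and above indicate stable clusters.
#'
#' @inheritParams kmeans_cluster
#' @param method `"kmeans"` or `"hierarchical_ward"`.
#' @param B number of bootstrap resamples.
#' @param result optional pre-computed full-data `clustering_result` (must
#'   match `method` and `k`).
#' @return list with `per_cluster` (mean Jaccard per original cluster),
#'   `overall`, `min_cluster`, `B`, `n_redraws`.
#' @export
bootstrap_jaccard <- function(z, k, method = "kmeans", B = 500, seed = 1,
                              n_init = 50, result = NULL) {
  z <- drop_missing_rows(as.matrix(z))
  n <- nrow(z)
  fun <- cluster_fun(method)
  if (is.null(result))
    result <- fun(z, k, seed = stage_seed(seed, 0), n_init = n_init)
  orig <- result$labels
  clusters <- sort(unique(orig))
  jac <- matrix(NA_real_, B, length(clusters))
  set.seed(stage_seed(seed, 555))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (nrow(unique(z[idx, , drop = FALSE])) >= k) break
      n_redraws <- n_redraws + 1L
    }
    res_b <- fun(z[idx, , drop = FALSE], k,
                 seed = stage_seed(seed, 2000 + b), n_init = n_init)
    u <- unique(idx)
    lab_u <- res_b$labels[match(u, idx)]
    for (ci in seq_along(clusters)) {
      A <- intersect(which(orig == clusters[ci]), u)
      if (length(A) == 0) next
      jac[b, ci] <- max(vapply(unique(lab_u), function(cl)
        jaccard_index(A, u[lab_u == cl]), 0))
    }
  }
  per_cluster <- colMeans(jac, na.rm = TRUE)
  names(per_cluster) <- paste0("cluster_", clusters)
  list(per_cluster = per_cluster, overall = mean(per_cluster),
       min_cluster = min(per_cluster), B = B, n_redraws = n_redraws)
}

#' Name the endophenotypes of a 3-cluster solution
#'
#' Computes each cluster's mean z over cortical-thickness composites (C) and
#' over subcortical-volume composites (S): the cluster with the highest C is
#' named `increased_cortical_thickness`, the lowest C
#' `decreased_cortical_thickness`, and the remaining cluster
#' `subcortical_reduction`. Ties in C are broken by the lower S (the more
#' subcortically reduced cluster), then by cluster id; exact ties are
#' flagged degenerate. The rule is defined for k = 3; any other k returns
#' all clusters `unlabeled`.
#'
#' @param result a `clustering_result`.
#' @param z the patient z matrix the clustering was run on.
#' @param map the [region_map()] supplying composite measure classes.
#' @return an `endophenotype_assignment`: list with `names` (cluster id ->
#'   name), `evidence` (per-cluster mean cortical / subcortical z) and
#'   `degenerate`.
#' @export
name_endophenotypes <- function(result, z, map) {
  z <- as.matrix(z)[names(result$labels), , drop = FALSE]
  cls <- vapply(map, `[[`, "", "measure_class")[colnames(z)]
  ct <- which(cls == "cortical_thickness")
  sc <- which(cls == "subcortical_volume")
  clusters <- sort(unique(result$labels))
  evid <- data.frame(
    cluster = clusters,
    mean_cortical_z = vapply(clusters, function(cl)
      mean(z[result$labels == cl, ct, drop = FALSE]), 0),
    mean_subcortical_z = vapply(clusters, function(cl)
      mean(z[result$labels == cl, sc, drop = FALSE]), 0))
  nm <- stats::setNames(rep("unlabeled", length(clusters)), clusters)
  degenerate <- FALSE
  if (result$k == 3) {
    C <- evid$mean_cortical_z; S <- evid$mean_subcortical_z
    degenerate <- anyDuplicated(C) > 0
    ord_ict <- order(-C, S, clusters)   # highest C, tie -> lower S
    ord_dct <- order(C, S, clusters)    # lowest C, tie -> lower S
    ict <- clusters[ord_ict[1]]
    dct <- setdiff(clusters[ord_dct], ict)[1]
    sr <- setdiff(clusters, c(ict, dct))
    nm[as.character(ict)] <- "increased_cortical_thickness"
    nm[as.character(dct)] <- "decreased_cortical_thickness"
    nm[as.character(sr)] <- "subcortical_reduction"
    if (degenerate)
      warning("degenerate tie in cluster naming; broken by subcortical mean, then cluster id",
              call. = FALSE)
  }
  structure(list(names = nm, evidence = evid, degenerate = degenerate),
            class = "endophenotype_assignment")
}

#' @export
print.endophenotype_assignment <- function(x, ...) {
  cat("<endophenotype_assignment>\n")
  print(cbind(x$evidence, name = unname(x$names)))
  invisible(x)
}

#' Cluster sizes and percentages
#'
#' @param result a `clustering_result` (or a named label vector).
#' @param n_total denominator for the percentages (>= 1). Cluster sizes may
#'   sum to less than `n_total` (subjects excluded from clustering keep their
#'   place in the denominator) but never to more.
#' @return data.frame with `cluster`, `size`, `percent` (1 decimal).
#' @export
summarize_clusters <- function(result, n_total) {
  labels <- if (inherits(result, "clustering_result")) result$labels else result
  abort_if(n_total < 1, "n_total must be >= 1")
  tab <- table(labels)
  abort_if(sum(tab) > n_total,
           "cluster sizes (", sum(tab), ") exceed n_total (", n_total, ")")
  data.frame(cluster = names(tab), size = as.integer(tab),
             percent = round(100 * as.integer(tab) / n_total, 1),
             stringsAsFactors = FALSE)
}

#' 2-D PCA projection of a Z-map
#'
#' Centered (not re-scaled: the inputs are already z-scores) principal
#' components, for low-dimensional displays of cluster separation.
#'
#' @param z numeric matrix (>= 3 subjects, >= 2 composites).
#' @return list with `coords` (n x 2), `var_frac` (all components,
#'   non-increasing, summing to <= 1) and `rank`.
#' @export
pca_project <- function(z) {
  z <- as.matrix(z)
  abort_if(nrow(z) < 3 || ncol(z) < 2, "need >= 3 subjects and >= 2 composites")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-8)
  if (rank < 2) {
    warning("rank < 2: second component fraction is 0", call. = FALSE)
    var_frac[2] <- 0
  }
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("DIM1", "DIM2")
  list(coords = coords, var_frac = var_frac, rank = rank)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, used to score recovery of planted labels.
#'
#' @param a,b label vectors over the same subjects (matched by names when
#'   both are named).
#' @return the ARI.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}

#' Full endophenotyping of a patient Z-map
#'
#' Runs the WSS curve, elbow, gap statistic and bootstrapped Jaccard
#' stability over a k range, clusters at the gap-selected k (clamped into
#' the range), and names the endophenotypes when k = 3.
#'
#' @param zmap a `zmap` (patients are extracted) or a patient z matrix.
#' @param map the [region_map()] (needed for naming).
#' @param k_range candidate cluster numbers.
#' @param method `"kmeans"` or `"hierarchical_ward"`.
#' @param B_boot bootstrap resamples for the stability of the selected k.
#' @param B_ref gap-statistic reference draws.
#' @param seed master seed.
#' @param n_init K-means restarts.
#' @return list with `wss`, `elbow`, `gap`, `selected_k`, `result`,
#'   `stability`, `assignment`, `summary`, `pca`.
#' @export
endophenotype <- function(zmap, map, k_range = 2:5, method = "kmeans",
                          B_boot = 500, B_ref = 100, seed = 1, n_init = 50) {
  z <- if (inherits(zmap, "zmap")) patient_z(zmap) else as.matrix(zmap)
  z <- drop_missing_rows(z)
  k_max <- max(k_range)
  wss <- wss_curve(z, k_max = k_max, seed = stage_seed(seed, 1),
                   n_init = n_init, method = method)
  elbow <- elbow_select(cummin(wss))
  gap <- gap_statistic(z, k_max = k_max, B_ref = B_ref,
                       seed = stage_seed(seed, 2), n_init = n_init,
                       method = method)
  selected_k <- min(max(gap$k_star, min(k_range)), max(k_range))
  result <- cluster_fun(method)(z, selected_k, seed = stage_seed(seed, 3),
                                n_init = n_init)
  stability <- bootstrap_jaccard(z, selected_k, method = method, B = B_boot,
                                 seed = stage_seed(seed, 4), n_init = n_init,
                                 result = result)
  assignment <- name_endophenotypes(result, z, map)
  list(wss = wss, elbow = elbow, gap = gap, selected_k = selected_k,
       result = result, stability = stability, assignment = assignment,
       summary = summarize_clusters(result, nrow(z)),
       pca = pca_project(z))
}
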