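# Clustering, cluster-number selection, bootstrap stability, naming and the
# PCA projection.

test_that("k-means recovers well-separated clouds exactly", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0))
  z <- make_clouds(centers, c(20, 20), seed = 1)
  km <- kmeans_cluster(z, 2, seed = 2)
  # oracle: nearest true center
  oracle <- apply(z, 1, function(p)
    which.min(colSums((t(centers) - p)^2)))
  expect_equal(adjusted_rand(km$labels, oracle), 1)
  # Ward agrees on the same data
  hw <- hierarchical_cluster(z, 2)
  expect_equal(adjusted_rand(hw$labels, oracle), 1)
})

test_that("k = 1 WSS is the total sum of squares; duplication doubles WSS", {
  z <- make_clouds(rbind(c(0, 0), c(4, 4)), c(15, 15), seed = 3)
  km1 <- kmeans_cluster(z, 1, seed = 1)
  tss <- sum(sweep(z, 2, colMeans(z))^2)
  expect_equal(km1$wss, tss, tolerance = 1e-10)

  km <- kmeans_cluster(z, 2, seed = 4)
  z2 <- rbind(z, z); rownames(z2) <- sprintf("D%03d", seq_len(nrow(z2)))
  km2 <- kmeans_cluster(z2, 2, seed = 4)
  ord <- function(m) m[order(m[, 1]), , drop = FALSE]
  expect_equal(ord(unname(km2$centroids)), ord(unname(km$centroids)),
               tolerance = 1e-8)
  expect_equal(km2$wss, 2 * km$wss, tolerance = 1e-8)
})

test_that("hierarchical clustering cuts to singletons and differs from single linkage on a chain", {
  z3 <- matrix(c(0, 0, 5, 5, 10, 10), ncol = 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  hc3 <- hierarchical_cluster(z3, 3)
  expect_identical(as.integer(sort(table(hc3$labels))), c(1L, 1L, 1L))

  # chaining fixture: Ward splits by variance, single linkage by the largest gap
  x <- matrix(c(1, 2, 3, 4, 5, 6.5), ncol = 1,
              dimnames = list(letters[1:6], NULL))
  ward <- cutree(hclust(dist(x), "ward.D2"), 2)
  single <- cutree(hclust(dist(x), "single"), 2)
  expect_identical(unname(ward), c(1L, 1L, 1L, 1L, 2L, 2L))
  expect_identical(unname(single), c(1L, 1L, 1L, 1L, 1L, 2L))
  expect_false(identical(unname(ward), unname(single)))
  expect_identical(unname(hierarchical_cluster(x, 2)$labels), unname(ward))
})

test_that("elbow selection maximizes the discrete second difference", {
  sel <- elbow_select(c(100, 30, 28, 27, 26))
  expect_identical(sel$k_star, 2L)
  expect_equal(unname(sel$second_diff["2"]), 100 - 60 + 28)
  # linear decline: no elbow
  expect_true(is.na(elbow_select(c(100, 80, 60, 40, 20))$k_star))
  expect_error(elbow_select(c(100, 30)), "k_max >= 3")
  expect_error(elbow_select(c(100, 30, 35, 20)), "non-increasing")
})

test_that("gap statistic separates one cloud from three well-separated clouds", {
  one <- vapply(1:20, function(s) {
    z <- make_clouds(matrix(0, 1, 5), 60, seed = s)
    gap_statistic(z, k_max = 4, B_ref = 50, seed = s, n_init = 20)$k_star
  }, 0L)
  expect_gte(mean(one == 1), 0.8)

  centers <- rbind(c(0, 0, 0, 0, 0), c(8, 0, 0, 0, 0), c(0, 8, 0, 0, 0))
  three <- vapply(1:20, function(s) {
    z <- make_clouds(centers, c(20, 20, 20), seed = 100 + s)
    gap_statistic(z, k_max = 5, B_ref = 50, seed = s, n_init = 20)$k_star
  }, 0L)
  expect_gte(mean(three == 3), 0.9)

  # boundary contract: k_star never exceeds k_max
  expect_lte(gap_statistic(make_clouds(matrix(0, 1, 3), 30, seed = 2),
                           k_max = 3, B_ref = 10, seed = 1)$k_star, 3)
  expect_error(gap_statistic(make_clouds(matrix(0, 1, 3), 30), B_ref = 5),
               ">= 10")
})

test_that("gap curve agrees with the clusGap reference implementation", {
  z <- make_clouds(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)),
                   c(20, 20, 20), seed = 7)
  mine <- gap_statistic(z, k_max = 4, B_ref = 200, seed = 1, n_init = 20)
  set.seed(99)
  # seed-free FUNcluster (a FUNcluster that reseeds the RNG would freeze
  # clusGap's reference stream); d.power = 2 matches the squared-distance W
  ref <- cluster::clusGap(z, function(x, k) list(cluster =
    stats::kmeans(x, k, nstart = 20, iter.max = 100)$cluster),
    K.max = 4, B = 200, d.power = 2, spaceH0 = "scaledPCA", verbose = FALSE)
  # two independent Monte-Carlo references: compare within sampling error
  expect_lt(max(abs(mine$gap - unname(ref$Tab[, "gap"]))), 0.1)
})

test_that("bootstrap Jaccard stability orders separated vs unstructured data", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(jaccard_index(1:3, 2:4), 0.5)

  centers <- 10 * diag(3)
  zsep <- make_clouds(centers, c(20, 20, 20), seed = 5)
  bs <- bootstrap_jaccard(zsep, 3, B = 100, seed = 1, n_init = 20)
  expect_true(all(bs$per_cluster >= 0.95))

  zone <- make_clouds(matrix(0, 1, 3), 60, seed = 6)
  b1 <- bootstrap_jaccard(zone, 3, B = 100, seed = 1, n_init = 20)
  expect_lt(b1$overall, 0.8)
  expect_lt(b1$overall, bs$overall)
})

test_that("endophenotype naming follows the cortical/subcortical evidence", {
  map <- mini_map()
  comps <- composite_names(map)
  mk_z <- function(cent, sizes) {
    z <- do.call(rbind, lapply(seq_along(sizes), function(i)
      matrix(rep(cent[[i]], each = sizes[i]), sizes[i])))
    colnames(z) <- comps
    rownames(z) <- sprintf("P%02d", seq_len(nrow(z)))
    z
  }
  z <- mk_z(list(c(-2, -1.5, -1.5, 0, 0),    # subcortical reduction
                 c(-0.5, 0, 0, 2, 2),        # thickening
                 c(0, 0, 0, -2, -2)),        # thinning
            c(4, 3, 3))
  res <- list(method = "kmeans", k = 3,
              labels = stats::setNames(rep(1:3, c(4, 3, 3)), rownames(z)))
  class(res) <- "clustering_result"
  asg <- name_endophenotypes(res, z, map)
  expect_identical(unname(asg$names[c("1", "2", "3")]),
                   c("subcortical_reduction", "increased_cortical_thickness",
                     "decreased_cortical_thickness"))

  # permuting cluster ids leaves the subject -> name assignment unchanged
  perm <- c(2L, 3L, 1L)
  res2 <- res; res2$labels <- stats::setNames(perm[res$labels], names(res$labels))
  asg2 <- name_endophenotypes(res2, z, map)
  expect_identical(unname(asg2$names[as.character(res2$labels)]),
                   unname(asg$names[as.character(res$labels)]))

  # all-zero map: deterministic degenerate tie-break
  z0 <- mk_z(list(rep(0, 5), rep(0, 5), rep(0, 5)), c(4, 3, 3))
  expect_warning(asg0 <- name_endophenotypes(res, z0, map), "degenerate")
  expect_setequal(unname(asg0$names),
                  c("subcortical_reduction", "increased_cortical_thickness",
                    "decreased_cortical_thickness"))

  # rule scope: k != 3 stays unlabeled
  res2 <- res; res2$k <- 2
  res2$labels <- stats::setNames(rep(1:2, c(5, 5)), rownames(z))
  expect_true(all(name_endophenotypes(res2, z, map)$names == "unlabeled"))
})

test_that("cluster summaries compute exact percentages and enforce conservation", {
  lab <- rep(c("SR", "ICT", "DCT"), c(27, 21, 14))
  sm <- summarize_clusters(stats::setNames(lab, sprintf("P%02d", 1:62)), 62)
  expect_setequal(sm$percent, c(43.5, 33.9, 22.6))
  expect_identical(summarize_clusters(rep(1:2, c(10, 10)), 20)$percent,
                   c(50.0, 50.0))
  expect_error(summarize_clusters(rep(1, 10), 8), "exceed n_total")
})

test_that("PCA projection is rotation-invariant with valid variance fractions", {
  z <- make_clouds(rbind(c(0, 0, 0, 0), c(4, 4, 0, 0)), c(20, 20), seed = 9)
  p <- pca_project(z)
  expect_true(all(diff(p$var_frac) <= 1e-12))
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)

  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  p2 <- pca_project(z %*% Q)
  expect_equal(p2$var_frac, p$var_frac, tolerance = 1e-8)

  line <- matrix(seq_len(10), 10, 1) %*% t(c(1, 2))
  expect_warning(pl <- pca_project(line), "rank")
  expect_equal(pl$var_frac[1], 1, tolerance = 1e-10)
})
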