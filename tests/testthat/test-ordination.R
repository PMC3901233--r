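test_that("classical MDS recovers exact planar configurations", {
  # unit-square corners: Euclidean distances embed exactly in 2D
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  rownames(square) <- paste0("p", 1:4)
  d <- as.matrix(dist(square))
  fit <- classical_mds(d, dims = 2)
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(procrustes_rmse(square, fit$points), 1e-6)

  # cross-check the alignment with an independent implementation
  skip_if_not_installed("vegan")
  pr <- vegan::procrustes(square, fit$points, symmetric = FALSE)
  expect_lt(sqrt(mean(stats::residuals(pr)^2)), 1e-6)
})

test_that("MDS of all-equal distances yields an equilateral triangle", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  fit <- classical_mds(d, dims = 2)
  emb <- dist(fit$points)
  expect_equal(unname(as.vector(emb)), rep(emb[1], 3), tolerance = 1e-9)
})

test_that("MDS stress beats random configurations and rejects NA input", {
  x <- random_dataset(40, 10, seed = 55)
  d <- fingerprint_dist(x)
  fit <- classical_mds(d, dims = 2)
  s0 <- config_stress(unclass(d), fit$points)
  set.seed(77)
  random_stress <- replicate(100, {
    config_stress(unclass(d), matrix(rnorm(20), 10, 2))
  })
  expect_true(all(s0 <= random_stress))

  dna <- unclass(d)
  dna[1, 2] <- dna[2, 1] <- NA
  expect_error(classical_mds(dna), class = "mfp_missing_distance")
  expect_error(classical_mds(d, dims = 0), class = "mfp_bad_input")
})

test_that("max-standardization maps features onto [0,1] and is idempotent", {
  x <- tiny_dataset()
  x$abund["f1", ] <- c(2, 4, 8, 8)
  std <- standardize_max(x)
  expect_equal(unname(std["f1", ]), c(0.25, 0.5, 1, 1))
  expect_equal(unname(apply(std, 1, max, na.rm = TRUE)), rep(1, nrow(std)))

  std2 <- standardize_max(std)
  expect_equal(std2, std, ignore_attr = TRUE)

  # all-zero features are dropped with a warning
  y <- x
  y$abund["f3", ] <- 0
  expect_warning(stdy <- standardize_max(y), "dropped")
  expect_identical(attr(stdy, "dropped"), "f3")
  expect_identical(nrow(stdy), 2L)
})

test_that("K-means recovers planted partitions and is seed-deterministic", {
  sim <- simulate_dataset(prunella_preset(organs = "shoots"), seed = 23)
  std <- standardize_max(sim$dataset)
  km <- kmeans_cluster(std, k = 3, seed = 7)
  truth <- sim$truth$group_of_accession[sim$dataset$samples$accession]
  expect_equal(adjusted_rand_index(km$assignments, truth), 1)

  km2 <- kmeans_cluster(std, k = 3, seed = 7)
  expect_identical(km$assignments, km2$assignments)

  # k = 1: single cluster, WCSS equals total SS
  km1 <- kmeans_cluster(std, k = 1, seed = 1)
  expect_equal(km1$wcss, km1$total_ss)
  expect_identical(unname(unique(km1$assignments)), 1L)

  expect_error(kmeans_cluster(std, k = 26), class = "mfp_bad_input")
})

test_that("hierarchical clustering recovers the three accession groups", {
  # the published qualitative structure: one distinct accession group, one
  # three-accession group, one outlier accession
  sim <- simulate_dataset(prunella_preset(organs = "shoots"), seed = 29)
  std <- standardize_max(sim$dataset)
  truth <- sim$truth$group_of_accession[sim$dataset$samples$accession]
  for (link in c("average", "complete", "single")) {
    hc <- hierarchical_cluster(std, linkage = link, k = 3)
    expect_equal(adjusted_rand_index(hc$assignments, truth), 1,
                 label = link)
  }

  # identical samples merge first at height 0
  m <- matrix(rlnorm(40), 10, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 1]
  hc <- hierarchical_cluster(m, k = 2)
  expect_equal(hc$tree$height[1], 0)
  expect_setequal(abs(hc$tree$merge[1, ]), c(1, 2))

  expect_error(hierarchical_cluster(m, linkage = "ward", k = 2),
               class = "mfp_bad_input")
})

test_that("single linkage agrees with a brute-force nearest-cluster oracle", {
  set.seed(13)
  pts <- matrix(rnorm(12), 6, 2)
  m <- t(pts)  # features x samples
  colnames(m) <- paste0("s", 1:6)
  hc <- hierarchical_cluster(m, linkage = "single", k = 2)

  # oracle: iteratively merge the two clusters with the smallest minimum
  # inter-point distance; compare the final 2-cluster partition
  d <- as.matrix(dist(pts))
  clusters <- as.list(1:6)
  while (length(clusters) > 2) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dm <- min(d[clusters[[i]], clusters[[j]]])
      if (dm < best[1]) best <- c(dm, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-best[3]]
  }
  oracle <- integer(6)
  for (i in seq_along(clusters)) oracle[clusters[[i]]] <- i
  expect_equal(adjusted_rand_index(hc$assignments, oracle), 1)
})

test_that("ARI matches its closed form and is label-permutation invariant", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)

  # hand computation for the contingency table (2,1 ; 1,2), n = 6:
  # sum choose(n_ij,2) = 2, row/col pair sums = 6 each,
  # expected = 36/15 = 2.4, max = 6 -> ARI = (2-2.4)/(6-2.4) = -1/9
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), -1 / 9)

  # label permutation invariance on random partitions
  set.seed(5)
  for (i in 1:10) {
    p <- sample(1:3, 12, replace = TRUE)
    q <- sample(1:4, 12, replace = TRUE)
    ari <- adjusted_rand_index(p, q)
    relabel <- c(3, 1, 2)[p]
    expect_equal(adjusted_rand_index(relabel, q), ari)
  }

  # independent implementation cross-check
  skip_if_not_installed("igraph")
  set.seed(6)
  for (i in 1:5) {
    p <- sample(1:3, 20, replace = TRUE)
    q <- sample(1:3, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(p, q),
                 igraph::compare(p, q, method = "adjusted.rand"))
  }

  expect_error(adjusted_rand_index(1:3, 1:4), class = "mfp_length_mismatch")
})

test_that("replicates embed closer within accession than between (MDS claim)", {
  sim <- simulate_dataset(prunella_preset(organs = "vegetative organs of shoots"),
                          seed = 37)
  d <- fingerprint_dist(select_features(sim$dataset, platform = "surface_lipid"))
  fit <- classical_mds(d, dims = 2)
  emb <- as.matrix(dist(fit$points))
  acc <- sim$dataset$samples$accession
  same <- outer(acc, acc, "==") & upper.tri(emb)
  diff <- outer(acc, acc, "!=") & upper.tri(emb)
  expect_lt(mean(emb[same]), mean(emb[diff]))
})
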