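make_tm <- function(n = 4, seed = 31, missing = NULL) {
  set.seed(seed)
  g <- expand.grid(variety = sprintf("V%02d", 1:n), concentration = c(0, 50, 100, 150),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (tr in c("plant_height", "root_length", "germination_rate", "sti"))
    g[[tr]] <- rnorm(nrow(g), 50, 10)
  if (!is.null(missing)) g[missing$row, missing$col] <- NA
  g <- g[order(g$variety, g$concentration), ]
  class(g) <- c("trait_matrix", "data.frame")
  g
}

test_that("wide matrix has the deterministic 16-column layout and flags imputation", {
  tm <- make_tm(3)
  W <- build_wide_matrix(tm)
  expect_equal(dim(W), c(3, 16))
  expect_equal(colnames(W)[1:4],
               c("plant_height_0", "plant_height_50", "plant_height_100",
                 "plant_height_150"))
  expect_false(any(attr(W, "imputed")))

  # one missing cell among 3 varieties -> imputed with the mean of the others
  tm2 <- make_tm(3, missing = list(row = 1, col = "plant_height"))
  # row 1 is (V01, 0 mM) before reordering; recompute which cell is NA
  na_cell <- which(is.na(tm2$plant_height))
  v <- tm2$variety[na_cell]; cc <- tm2$concentration[na_cell]
  W2 <- build_wide_matrix(tm2)
  others <- tm2$plant_height[tm2$concentration == cc & tm2$variety != v]
  expect_equal(W2[v, paste0("plant_height_", cc)], mean(others))
  expect_true(attr(W2, "imputed")[v, paste0("plant_height_", cc)])

  # column order is independent of input row order
  tm3 <- make_tm(4)
  shuffled <- tm3[sample(nrow(tm3)), ]
  class(shuffled) <- class(tm3)
  expect_identical(attr(build_wide_matrix(tm3), "manifest"),
                   attr(build_wide_matrix(shuffled), "manifest"))
  expect_identical(build_wide_matrix(tm3), build_wide_matrix(shuffled))
})

test_that("varieties over the missingness cap are dropped; empty feature columns error", {
  tm <- make_tm(4)
  idx <- tm$variety == "V01" & tm$concentration %in% c(50, 100, 150)
  tm[idx, c("plant_height", "root_length")] <- NA  # 6/16 = 37.5% missing
  expect_warning(W <- build_wide_matrix(tm), "V01")
  expect_false("V01" %in% rownames(W))

  tm2 <- make_tm(3)
  tm2$sti[tm2$concentration == 150] <- NA
  expect_error(build_wide_matrix(tm2), "sti_150")
})

test_that("z-scoring hits exact closed forms and is idempotent", {
  W <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  Z <- zscore_standardize(W)
  expect_equal(Z[, "a"], c(-1.224744871391589, 0, 1.224744871391589),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-9)
  # population SD convention: divisor n
  expect_equal(apply(Z, 2, function(x) sqrt(mean(x^2))), c(a = 1, b = 1),
               tolerance = 1e-9)
  Z2 <- zscore_standardize(Z)
  expect_equal(unclass(Z2), unclass(Z), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(zscore_standardize(cbind(a = c(1, 1, 1))), "zero-variance")
  Z3 <- zscore_standardize(cbind(a = c(1, 1, 1), b = 1:3), constant = "zero")
  expect_equal(unname(Z3[, "a"]), c(0, 0, 0))

  # sample-SD convention differs by sqrt(n/(n-1))
  Zs <- zscore_standardize(W, sd_type = "sample")
  expect_equal(unname(Zs[, "a"]), c(-1, 0, 1))
})

test_that("euclidean distances: 3-4-5 triangle, symmetry, permutation invariance", {
  W <- rbind(p = c(0, 0), q = c(3, 4))
  d <- euclidean_distance_matrix(W)
  expect_equal(as.numeric(d), 5)
  expect_equal(as.matrix(d)["p", "p"], 0)

  set.seed(32)
  X <- matrix(rnorm(50), 10)
  expect_equal(as.matrix(euclidean_distance_matrix(X)),
               as.matrix(euclidean_distance_matrix(X[, 5:1])))
})

test_that("UPGMA reproduces the worked 3-leaf example", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(as.dist(D))
  expect_equal(tr$node_height, c(1, 3))
  # leaf branch lengths: A and B hang at height 1, C joins the root at 3
  nwk <- write_newick(tr)
  expect_equal(nwk, "((A:1,B:1):2,C:3);")
  # cophenetic distances reproduce the ultrametric input exactly
  expect_equal(as.matrix(cophenetic_distances(tr)), D[rownames(D), colnames(D)])

  # two leaves: heights are half the distance
  d2 <- as.dist(matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  t2 <- upgma(d2)
  expect_equal(t2$node_height, 2)
  expect_equal(write_newick(t2), "(A:2,B:2);")
})

test_that("UPGMA matches the brute-force agglomeration oracle on random matrices", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 5)
    d <- random_metric_dist(n, seed)
    tr <- upgma(d)
    orc <- oracle_upgma(d)
    expect_equal(tr$height, orc$heights, tolerance = 1e-12, info = paste("seed", seed))
    expect_identical(tree_clades(tr), orc$members)
  }
})

test_that("UPGMA agrees with hclust average linkage and has no inversions", {
  for (seed in c(101, 102, 103)) {
    d <- random_metric_dist(12, seed)
    tr <- upgma(d)
    hc <- stats::hclust(d, method = "average")
    expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-10)
    expect_equal(as.matrix(cophenetic_distances(tr)),
                 as.matrix(stats::cophenetic(hc)), tolerance = 1e-10)
    # monotone merge heights (no inversions for UPGMA on metric input)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("Newick output round-trips byte-identically and quotes reserved labels", {
  d <- random_metric_dist(7, 55)
  tr <- upgma(d)
  s1 <- write_newick(tr)
  s2 <- write_newick(read_newick(s1))
  expect_identical(s1, s2)
  expect_identical(write_newick(read_newick(s2)), s2)

  # file round-trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_identical(write_newick(read_newick(path)), s1)

  # reserved characters in labels survive quoting
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3)
  dimnames(D) <- list(c("var 1;x", "b(2)", "o'k"), c("var 1;x", "b(2)", "o'k"))
  trq <- upgma(as.dist(D))
  sq <- write_newick(trq)
  back <- read_newick(sq)
  labs <- sort(c(back$children[[1]]$children[[1]]$label,
                 back$children[[1]]$children[[2]]$label,
                 back$children[[2]]$label))
  expect_equal(labs, sort(rownames(D)))
  expect_identical(write_newick(back), sq)

  # cross-check the dialect with an independent reader on plain labels
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = write_newick(tr))
  expect_setequal(ph$tip.label, tr$labels)
  expect_equal(max(ape::node.depth.edgelength(ph)), max(tr$node_height),
               tolerance = 1e-9)
})

test_that("PCA limits: rank-1 data, completeness, orthonormal loadings, sign rule", {
  set.seed(33)
  t_param <- rnorm(20)
  X <- outer(t_param, c(1, -2, 0.5, 3, 1)) +
    matrix(rep(c(5, 1, 0, 2, 4), each = 20), 20)
  p <- suppressWarnings(pheno_pca(X))
  expect_equal(p$variance_explained[1], 1.0, tolerance = 1e-9)
  expect_equal(sum(p$variance_explained), 1.0, tolerance = 1e-9)

  Y <- matrix(rnorm(200), 20)
  p2 <- pheno_pca(Y)
  expect_equal(sum(p2$variance_explained), 1)
  expect_equal(crossprod(p2$loadings), diag(ncol(Y)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # reconstruction from all components reproduces the centered matrix
  Yc <- scale(Y, scale = FALSE)
  expect_equal(p2$scores %*% t(p2$loadings), Yc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores are uncorrelated across components
  cc <- cor(p2$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # sign rule: the largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(p2$loadings)))
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
})

test_that("PCA on an isotropic cloud splits variance evenly and truncation warns", {
  set.seed(34)
  X <- matrix(rnorm(4000), 2000, 2)
  p <- pheno_pca(X)
  expect_equal(p$variance_explained[1], 0.5, tolerance = 0.05)
  expect_equal(p$variance_explained[2], 0.5, tolerance = 0.05)
  expect_warning(pheno_pca(matrix(rnorm(20), 10, 2) %*% matrix(1, 2, 2),
                           n_components = 2), "rank")
})

test_that("k-means recovers separated blobs and is deterministic for a fixed seed", {
  set.seed(35)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60, sd = 1), 30), 2, centers[i, ], "+")))
  rownames(X) <- sprintf("V%03d", 1:90)
  truth <- rep(1:3, each = 30)
  cl <- kmeans_cluster(X, k = 3, seed = 99)
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
  cl2 <- kmeans_cluster(X, k = 3, seed = 99)
  expect_identical(cl$cluster, cl2$cluster)

  one <- kmeans_cluster(X, k = 1, seed = 1)
  expect_equal(one$inertia, sum(scale(X, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(kmeans_cluster(X[1:2, ], k = 3), "exceeds")
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(36)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})
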