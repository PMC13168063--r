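#' Build the variety x (trait x concentration) wide matrix
#'
#' Pivots the aggregated trait matrix into one row per variety and one
#' column per (trait, concentration) pair — 4 traits x 4 levels = 16
#' features in the default design. Column order is deterministic: traits in
#' canonical order, concentrations ascending within trait. Missing cells
#' are imputed with the column mean and flagged in the `imputed` attribute;
#' varieties missing more than `max_missing` of their features are dropped
#' with a warning. A feature column with no observed value at all is an
#' error.
#'
#' @param tm a `trait_matrix`.
#' @param max_missing maximum tolerated fraction of missing features per
#'   variety before it is dropped (default 0.25).
#' @return a numeric matrix (class `wide_matrix`) with variety rownames,
#'   attributes `imputed` (logical matrix) and `manifest` (column order).
#' @export
build_wide_matrix <- function(tm, max_missing = 0.25) {
  stopifnot(inherits(tm, "trait_matrix"))
  levels_ <- sort(unique(tm$concentration))
  varieties <- sort(unique(tm$variety))
  cols <- as.vector(t(outer(TRAITS, levels_, function(tr, l) paste0(tr, "_", l))))
  W <- matrix(NA_real_, length(varieties), length(cols),
              dimnames = list(varieties, cols))
  for (tr in TRAITS) for (l in levels_) {
    v <- tm[tm$concentration == l, c("variety", tr)]
    W[match(v$variety, varieties), paste0(tr, "_", l)] <- v[[tr]]
  }
  frac_missing <- rowMeans(is.na(W))
  drop <- frac_missing > max_missing
  if (any(drop)) {
    warning("dropping ", sum(drop), " variety(ies) with > ",
            round(100 * max_missing), "% missing features: ",
            paste(head(varieties[drop], 5), collapse = ", "))
    W <- W[!drop, , drop = FALSE]
  }
  empty <- colSums(!is.na(W)) == 0L
  if (any(empty))
    stop("feature column(s) entirely missing: ",
         paste(cols[empty], collapse = ", "), call. = FALSE)
  imputed <- is.na(W)
  if (any(imputed)) {
    mu <- colMeans(W, na.rm = TRUE)
    for (j in which(colSums(imputed) > 0)) W[imputed[, j], j] <- mu[j]
  }
  structure(W, imputed = imputed, manifest = cols, class = c("wide_matrix", "matrix"))
}

#' Z-score standardize a wide matrix column-wise
#'
#' Centers each feature to mean 0 and scales it to unit SD. The SD
#' convention defaults to the population form (divisor n); the sample form
#' (n - 1) is available and is recorded in the `sd_type` attribute since it
#' changes downstream distances slightly. Constant columns are an error by
#' default; `constant = "zero"` instead centers them to all-zero (so they
#' contribute nothing to distances or PCA), the convention the pipeline
#' uses because the control-level STI feature is identically 1 by
#' definition.
#'
#' @param W a `wide_matrix` (or plain numeric matrix).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param constant what to do with zero-variance columns: `"error"`
#'   (default) or `"zero"`.
#' @return the standardized matrix, same class and attributes.
#' @export
zscore_standardize <- function(W, sd_type = c("population", "sample"),
                               constant = c("error", "zero")) {
  sd_type <- match.arg(sd_type)
  constant <- match.arg(constant)
  X <- unclass(W)
  n <- nrow(X)
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero)) {
    if (constant == "error")
      stop("zero-variance column(s): ", paste(colnames(X)[zero], collapse = ", "),
           call. = FALSE)
    s[zero] <- 1  # centered column is all zeros
  }
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  attributes(Z)[c("imputed", "manifest")] <- attributes(W)[c("imputed", "manifest")]
  attr(Z, "sd_type") <- sd_type
  class(Z) <- class(W)
  Z
}

#' Euclidean distance matrix between varieties
#'
#' Pairwise Euclidean distances between the rows of the (usually
#' standardized) wide matrix, as a symmetric `stats::dist` object.
#'
#' @param W a `wide_matrix`.
#' @return a `dist` object with the metric tag in its `method` attribute.
#' @export
euclidean_distance_matrix <- function(W) {
  dist(unclass(W), method = "euclidean")
}

#' Principal component analysis of the standardized wide matrix
#'
#' PCA by singular value decomposition of the column-centered matrix
#' (`stats::prcomp`; no further scaling — the input is expected to be
#' Z-scored already). Variance-explained proportions are reported over all
#' components, so they sum to 1. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making score plots reproducible.
#'
#' @param W standardized `wide_matrix`.
#' @param n_components number of components to retain in scores/loadings
#'   (default: all). Requests beyond the matrix rank are truncated with a
#'   warning.
#' @return a `pheno_pca`: list with `scores` (varieties x components),
#'   `loadings` (features x components, orthonormal columns),
#'   `variance_explained` (proportions over all components), `sdev`,
#'   `center`.
#' @export
pheno_pca <- function(W, n_components = NULL) {
  X <- unclass(W)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ve <- ev / sum(ev)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  n_components <- n_components %||% rank
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, sdev = pc$sdev, center = pc$center),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  k <- min(5L, ncol(x$scores))
  cat("PCA of the variety x (trait x concentration) matrix\n")
  cat(sprintf("  %d varieties, %d features\n", nrow(x$scores), nrow(x$loadings)))
  ve <- round(100 * x$variance_explained[seq_len(k)], 1)
  cat("  variance explained (%):", paste0("PC", seq_len(k), "=", ve, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pheno_pca <- function(x, clusters = NULL, ...) {
  ve <- round(100 * x$variance_explained[1:2], 1)
  col <- if (is.null(clusters)) 1 else as.integer(factor(clusters[rownames(x$scores)])) + 1
  plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", ve[1]),
       ylab = sprintf("PC2 (%.1f%%)", ve[2]), ...)
  invisible(x)
}

#' K-means grouping of varieties
#'
#' Partitions varieties (typically on their PC1-PC2 scores) into K groups
#' with `stats::kmeans`, using `n_start` random restarts under the given
#' seed and keeping the lowest-inertia solution. K = 3 is the pipeline
#' default — retained as the biologically interpretable tolerant /
#' intermediate / sensitive split, not as a statistical optimum; silhouette
#' or elbow diagnostics may inform but never override it. Deterministic for
#' a fixed seed.
#'
#' @param x numeric matrix with variety rownames (e.g. `scores[, 1:2]` of a
#'   [pheno_pca()]), or a `pheno_pca` (its first two components are used).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_start random restarts (default 25).
#' @return a `cluster_assignment`: list with named integer `cluster`, `k`,
#'   `seed`, `inertia` (total within-cluster SS), `centers`, `sizes`.
#' @export
kmeans_cluster <- function(x, k = 3, seed = 1L, n_start = 25) {
  if (inherits(x, "pheno_pca")) x <- x$scores[, 1:2, drop = FALSE]
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of varieties", call. = FALSE)
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = n_start, iter.max = 100)
  structure(list(cluster = setNames(km$cluster, rownames(x)), k = k,
                 seed = seed, inertia = km$tot.withinss,
                 centers = km$centers, sizes = km$size),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("K-means grouping: K = %d, inertia = %.4g (seed %d)\n",
              x$k, x$inertia, x$seed))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
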