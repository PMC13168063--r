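# Independent oracles and fixture builders used across the suite.
# These are written step-by-step from the textbook definitions and stay
# independent of the package internals they check.

# Brute-force TOPSIS: explicit loops, no shared code with topsis().
oracle_topsis <- function(X, w = rep(1 / ncol(X), ncol(X)),
                          directions = rep("benefit", ncol(X))) {
  n <- nrow(X); m <- ncol(X)
  R <- matrix(0, n, m)
  for (j in 1:m) {
    nrm <- sqrt(sum(X[, j]^2))
    for (i in 1:n) R[i, j] <- X[i, j] / nrm
  }
  V <- matrix(0, n, m)
  for (j in 1:m) for (i in 1:n) V[i, j] <- w[j] * R[i, j]
  apos <- aneg <- numeric(m)
  for (j in 1:m) {
    if (directions[j] == "benefit") {
      apos[j] <- max(V[, j]); aneg[j] <- min(V[, j])
    } else {
      apos[j] <- min(V[, j]); aneg[j] <- max(V[, j])
    }
  }
  dpos <- dneg <- numeric(n)
  for (i in 1:n) {
    dpos[i] <- sqrt(sum((V[i, ] - apos)^2))
    dneg[i] <- sqrt(sum((V[i, ] - aneg)^2))
  }
  cc <- numeric(n)
  for (i in 1:n) cc[i] <- if (dpos[i] + dneg[i] > 0) dneg[i] / (dpos[i] + dneg[i]) else 0.5
  cc
}

# Naive UPGMA oracle: cluster distance recomputed each step as the plain
# mean of ALL original leaf-pair distances between the two clusters (the
# defining property), rather than the incremental update the package uses.
oracle_upgma <- function(D) {
  D0 <- as.matrix(D)
  labs <- rownames(D0)
  clusters <- lapply(seq_along(labs), function(i) i)
  names(clusters) <- labs  # representative label = smallest member
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    nms <- names(clusters)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      dd <- mean(D0[clusters[[a]], clusters[[b]]])
      lab <- sort(c(nms[a], nms[b]))
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2]))))
        best <- list(a = a, b = b, d = dd, lab = lab)
    }
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    heights <- c(heights, best$d)
    members[[length(members) + 1L]] <- sort(labs[merged])
    rep_lab <- min(names(clusters)[c(best$a, best$b)])
    clusters[[best$a]] <- NULL
    # removing element a shifts b's index when b > a
    bb <- if (best$b > best$a) best$b - 1L else best$b
    clusters[[bb]] <- merged
    names(clusters)[bb] <- rep_lab
  }
  list(heights = heights, members = members)
}

# clade membership sets of a package tree, in merge order
tree_clades <- function(tree) {
  leafset <- vector("list", nrow(tree$merge))
  out <- list()
  for (s in seq_len(nrow(tree$merge))) {
    kids <- lapply(tree$merge[s, ], function(k)
      if (k < 0) -k else leafset[[k]])
    leafset[[s]] <- c(kids[[1]], kids[[2]])
    out[[s]] <- sort(tree$labels[leafset[[s]]])
  }
  out
}

# random metric (Euclidean-embeddable) distance matrix on n leaves
random_metric_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  rownames(pts) <- sprintf("L%02d", seq_len(n))
  dist(pts)
}

# tiny hand-built phenotype table
toy_pheno <- function() {
  as_pheno_table(expand.grid(
    variety = c("A", "B"), replicate = 1:2,
    concentration = c(0, 100), KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE) |> transform(
      plant_height = 100, root_length = 50,
      germination_rate = 0.9, sti = 1))
}

# small fast simulation config for tests
small_sim <- function(seed = 11, n = 24, ...) {
  sim_config(n_varieties = n, seed = seed, ...)
}
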