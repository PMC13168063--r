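#' Build a TOPSIS decision matrix
#'
#' Assembles alternatives (varieties) x criteria values with per-criterion
#' weights and directions. All four phenotypes — plant height, root length,
#' germination rate, STI — are benefit criteria (higher is better) in the
#' salt-tolerance evaluation. Weights default to equal; weights that do not
#' sum to 1 are re-normalized with a warning, negative weights are an
#' error. Missing values are an error: imputation belongs upstream.
#'
#' @param x numeric matrix or data.frame, rows = alternatives (rownames =
#'   variety ids), columns = criteria.
#' @param weights numeric weights, one per criterion (default equal).
#' @param directions `"benefit"` or `"cost"` per criterion (default all
#'   benefit).
#' @return a `decision_matrix`: list with `values`, `weights`, `directions`.
#' @export
build_decision_matrix <- function(x, weights = NULL, directions = NULL) {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("decision matrix must be numeric", call. = FALSE)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty decision matrix", call. = FALSE)
  if (any(is.na(X)))
    stop("decision matrix contains missing values (impute upstream): criteria ",
         paste(colnames(X)[colSums(is.na(X)) > 0], collapse = ", "), call. = FALSE)
  m <- ncol(X)
  weights <- weights %||% rep(1 / m, m)
  if (length(weights) != m) stop("need one weight per criterion", call. = FALSE)
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  if (sum(weights) == 0) stop("weights sum to zero", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    warning("weights re-normalized to sum to 1")
    weights <- weights / sum(weights)
  }
  directions <- directions %||% rep("benefit", m)
  if (length(directions) == 1L) directions <- rep(directions, m)
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- sprintf("A%d", seq_len(nrow(X)))
  structure(list(values = X, weights = weights, directions = directions),
            class = "decision_matrix")
}

#' TOPSIS composite scoring
#'
#' Technique for Order Preference by Similarity to Ideal Solution. The
#' decision matrix is column-normalized (vector normalization by default:
#' each column divided by its Euclidean norm), weighted, and every
#' alternative is scored by its relative closeness
#' `C_i = D_i^- / (D_i^+ + D_i^-)` to the ideal point `A+` (best value per
#' criterion: column max for benefit criteria, min for cost) versus the
#' anti-ideal `A-`. `C_i` lies in \[0, 1\]; higher means closer to the
#' ideal salt-tolerant phenotype. When all alternatives are identical
#' (`D+ + D- = 0`) `C_i = 0.5` by convention.
#'
#' @param x a `decision_matrix` from [build_decision_matrix()], or a plain
#'   numeric matrix (equal weights, all-benefit assumed).
#' @param weights,directions passed to [build_decision_matrix()] when `x`
#'   is a plain matrix.
#' @param normalization `"vector"` (default) or `"minmax"`.
#' @return a `topsis` object: list with `score` (named closeness
#'   coefficients), `rank` (1 = best; ties broken by id), `d_pos`, `d_neg`,
#'   `ideal`, `anti_ideal`, `weighted` (normalized weighted matrix),
#'   `weights`, `normalization`.
#' @examples
#' x <- matrix(c(1, 2, 2, 2, 1, 2), 3, dimnames = list(c("a", "b", "c"), NULL))
#' topsis(x)
#' @export
topsis <- function(x, weights = NULL, directions = NULL,
                   normalization = c("vector", "minmax")) {
  normalization <- match.arg(normalization)
  dm <- if (inherits(x, "decision_matrix")) x
        else build_decision_matrix(x, weights, directions)
  X <- dm$values
  R <- switch(normalization,
    vector = {
      norms <- sqrt(colSums(X^2))
      if (any(norms == 0)) stop("all-zero criterion column", call. = FALSE)
      sweep(X, 2, norms, "/")
    },
    minmax = {
      rng <- apply(X, 2, range)
      span <- rng[2, ] - rng[1, ]
      if (any(span == 0)) span[span == 0] <- 1  # constant column -> all 0
      sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
    })
  V <- sweep(R, 2, dm$weights, "*")
  benefit <- dm$directions == "benefit"
  ideal <- ifelse(benefit, apply(V, 2, max), apply(V, 2, min))
  anti <- ifelse(benefit, apply(V, 2, min), apply(V, 2, max))
  d_pos <- sqrt(rowSums(sweep(V, 2, ideal)^2))
  d_neg <- sqrt(rowSums(sweep(V, 2, anti)^2))
  denom <- d_pos + d_neg
  score <- ifelse(denom > 0, d_neg / denom, 0.5)
  names(score) <- names(d_pos) <- names(d_neg) <- rownames(X)
  ord <- order(-score, names(score))
  rank <- integer(length(score)); rank[ord] <- seq_along(score)
  names(rank) <- names(score)
  structure(list(score = score, rank = rank, d_pos = d_pos, d_neg = d_neg,
                 ideal = ideal, anti_ideal = anti, weighted = V,
                 weights = dm$weights, normalization = normalization),
            class = "topsis")
}

#' @export
print.topsis <- function(x, n = 10, ...) {
  cat(sprintf("TOPSIS ranking of %d alternatives (%s normalization)\n",
              length(x$score), x$normalization))
  ord <- order(x$rank)
  show <- head(ord, n)
  print(data.frame(rank = x$rank[show], score = round(x$score[show], 4)))
  if (length(ord) > n) cat("... and", length(ord) - n, "more\n")
  invisible(x)
}

#' @export
summary.topsis <- function(object, ...) {
  cat(sprintf("TOPSIS: %d alternatives, %d criteria\n",
              length(object$score), length(object$weights)))
  cat("weights:", paste(round(object$weights, 4), collapse = ", "), "\n")
  cat("closeness score: min", round(min(object$score), 4),
      "median", round(median(object$score), 4),
      "max", round(max(object$score), 4), "\n")
  invisible(object)
}

#' @export
plot.topsis <- function(x, n = 30, ...) {
  ord <- order(-x$score)
  top <- head(ord, n)
  barplot(rev(x$score[top]), names.arg = rev(names(x$score)[top]),
          horiz = TRUE, las = 1, cex.names = 0.6,
          xlab = "TOPSIS closeness score", ...)
  invisible(x)
}

#' Select extreme alternatives from a TOPSIS ranking
#'
#' Returns the top (most salt-tolerant) and bottom (most sensitive)
#' alternatives in descending closeness order. Ties are broken by id; the
#' two lists must not overlap.
#'
#' @param result a `topsis` object.
#' @param n_top,n_bottom how many extremes to take from each end.
#' @return list with character vectors `top` and `bottom`.
#' @export
rank_and_select <- function(result, n_top, n_bottom) {
  stopifnot(inherits(result, "topsis"))
  n <- length(result$score)
  if (n_top + n_bottom > n)
    stop("n_top + n_bottom exceeds the number of alternatives", call. = FALSE)
  ids <- names(sort(result$rank))
  list(top = ids[seq_len(n_top)],
       bottom = tail(ids, n_bottom))
}

#' Entropy weights for a decision matrix
#'
#' Information-entropy weighting: criteria whose (share-normalized) values
#' vary more across alternatives receive more weight. Offered as an
#' alternative to the default equal weights; values must be positive.
#'
#' @param x numeric matrix, rows = alternatives.
#' @return weight vector summing to 1.
#' @export
entropy_weights <- function(x) {
  X <- as.matrix(x)
  if (any(X < 0)) stop("entropy weighting needs non-negative values", call. = FALSE)
  P <- sweep(X, 2, colSums(X), "/")
  n <- nrow(X)
  e <- apply(P, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  d <- 1 - e
  if (sum(d) == 0) return(rep(1 / ncol(X), ncol(X)))
  d / sum(d)
}
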