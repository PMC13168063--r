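#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group agglomeration with arithmetic mean: at each step
#' the two closest clusters merge, and the distance from the new cluster to
#' every other is the size-weighted average of its members' distances
#' (equivalently, the mean of all original pairwise leaf distances between
#' the two clusters). The node created by a merge at distance d sits at
#' height d / 2, so the resulting dendrogram is ultrametric: every
#' root-to-leaf path has the same length. Ties are broken deterministically
#' by merging the pair whose (sorted) representative labels — the
#' lexicographically smallest leaf of each cluster — are smallest.
#'
#' @param d a `dist` object or symmetric numeric matrix with labels;
#'   at least two leaves, no NaN/NA.
#' @return an `upgma_tree`: list with `merge` (hclust-style n-1 x 2 matrix,
#'   negative entries = leaves), `height` (merge distances), `node_height`
#'   (`height / 2`), `labels`.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- upgma(as.dist(d))
#' tr$node_height   # 1, 3
#' @export
upgma <- function(d) {
  D <- as.matrix(d)
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("distance matrix contains NA/NaN/Inf", call. = FALSE)
  n <- nrow(D)
  if (n < 2L) stop("need at least two leaves", call. = FALSE)
  labels <- rownames(D) %||% as.character(seq_len(n))
  D <- (D + t(D)) / 2  # enforce exact symmetry

  # active clusters: id (negative leaf index or merge-step index),
  # size, representative label (lexicographically smallest member)
  id <- -seq_len(n)
  size <- rep(1L, n)
  rep_lab <- labels
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # tie: lexicographically smallest (sorted) pair of representative labels
      key <- apply(cand, 1, function(rc) {
        lab <- sort(c(rep_lab[active[rc[1]]], rep_lab[active[rc[2]]]))
        paste(lab, collapse = "\r")
      })
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    a <- active[cand[1, 1]]; b <- active[cand[1, 2]]
    # children ordered by representative label for reproducible output
    merge[step, ] <- if (rep_lab[a] <= rep_lab[b]) c(id[a], id[b]) else c(id[b], id[a])
    height[step] <- D[a, b]
    # size-weighted average distance to every remaining cluster
    for (o in setdiff(active, c(a, b)))
      D[a, o] <- D[o, a] <- (size[a] * D[a, o] + size[b] * D[b, o]) /
        (size[a] + size[b])
    size[a] <- size[a] + size[b]
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    id[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height, node_height = height / 2,
                 labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$node_height)))
  invisible(x)
}

#' Convert a UPGMA tree to hclust
#'
#' Allows plotting and use of `stats::cophenetic` etc. Heights are the
#' merge distances (twice the node heights).
#'
#' @param x an `upgma_tree`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  ord <- function(node) {
    if (node < 0) return(-node)
    c(ord(x$merge[node, 1]), ord(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord(nrow(x$merge)), labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

#' @export
plot.upgma_tree <- function(x, ...) {
  plot(as.hclust.upgma_tree(x), ...)
  invisible(x)
}

#' Cophenetic distances of a UPGMA tree
#'
#' The cophenetic distance between two leaves is the merge distance (twice
#' the node height) of their lowest common ancestor. On ultrametric input
#' UPGMA reproduces the input distances exactly.
#'
#' @param tree an `upgma_tree`.
#' @return a `dist` object over the leaves.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  M <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leafset <- vector("list", n - 1L)
  for (s in seq_len(nrow(tree$merge))) {
    kids <- lapply(tree$merge[s, ], function(k)
      if (k < 0) -k else leafset[[k]])
    M[kids[[1]], kids[[2]]] <- tree$height[s]
    M[kids[[2]], kids[[1]]] <- tree$height[s]
    leafset[[s]] <- c(kids[[1]], kids[[2]])
  }
  stats::as.dist(M)
}

# ---- Newick serialization ----------------------------------------------

# a newick node is list(label=, length=, children=list(...) or NULL)

needs_quote <- function(lab) grepl("[][ ():;,'\t\n]", lab)

quote_label <- function(lab) {
  if (needs_quote(lab)) paste0("'", gsub("'", "''", lab), "'") else lab
}

fmt_len <- function(x) sprintf("%.10g", x)

node_to_newick <- function(node) {
  s <- if (!is.null(node$children))
    paste0("(", paste(vapply(node$children, node_to_newick, character(1)),
                      collapse = ","), ")")
  else ""
  lab <- if (!is.null(node$label) && nzchar(node$label)) quote_label(node$label) else ""
  len <- if (!is.null(node$length) && !is.na(node$length))
    paste0(":", fmt_len(node$length)) else ""
  paste0(s, lab, len)
}

upgma_to_nodes <- function(tree) {
  build <- function(k, parent_height) {
    if (k < 0) {
      list(label = tree$labels[-k], length = parent_height, children = NULL)
    } else {
      h <- tree$node_height[k]
      list(label = NULL, length = parent_height - h,
           children = lapply(tree$merge[k, ], build, parent_height = h))
    }
  }
  root_h <- tree$node_height[nrow(tree$merge)]
  root <- build(nrow(tree$merge), root_h)
  root$length <- NULL  # root has no branch
  root
}

#' Write a tree to Newick format
#'
#' One-line Newick string with branch lengths (10 significant digits) and a
#' terminating semicolon. Labels containing Newick-reserved characters
#' (whitespace, parentheses, commas, colons, semicolons, brackets, quotes)
#' are single-quoted with embedded quotes doubled, and round-trip through
#' [read_newick()]; write -> read -> write is byte-identical.
#'
#' @param tree an `upgma_tree` or a nested newick node list (as returned by
#'   [read_newick()]).
#' @param path optional file path; when `NULL` the string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  root <- if (inherits(tree, "upgma_tree")) upgma_to_nodes(tree) else tree
  s <- paste0(node_to_newick(root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a Newick tree
#'
#' Recursive-descent parser for the standard Newick dialect: nested
#' parentheses, optional labels (bare or single-quoted with `''` escapes),
#' optional `:length` branch lengths, terminating semicolon.
#'
#' @param x a file path or a Newick string.
#' @return a nested node list: each node has `label`, `length`, `children`.
#' @export
read_newick <- function(x) {
  s <- if (file.exists(x) && !grepl("[();]", basename(x))) readLines(x, warn = FALSE) else x
  s <- paste(s, collapse = "")
  s <- trimws(s)
  pos <- 1L
  nch <- nchar(s)
  peek <- function() if (pos <= nch) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L

  parse_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character()
      repeat {
        ch <- peek()
        if (ch == "") stop("unterminated quoted label", call. = FALSE)
        advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= nch && !substr(s, pos, pos) %in% c(",", ")", "(", ":", ";"))
        advance()
      substr(s, start, pos - 1L)
    }
  }

  parse_node <- function() {
    node <- list(label = NULL, length = NA_real_, children = NULL)
    if (peek() == "(") {
      advance()
      kids <- list()
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", pos, call. = FALSE)
      }
      node$children <- kids
    }
    lab <- parse_label()
    if (nzchar(lab)) node$label <- lab
    if (peek() == ":") {
      advance()
      start <- pos
      while (pos <= nch && grepl("[-+0-9.eE]", substr(s, pos, pos))) advance()
      node$length <- as.numeric(substr(s, start, pos - 1L))
    }
    node
  }

  root <- parse_node()
  if (peek() != ";") stop("missing terminating semicolon", call. = FALSE)
  root$length <- NULL
  root
}
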