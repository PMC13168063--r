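#' Factorial ANOVA for one trait
#'
#' Fixed-effects linear-model ANOVA decomposing a trait over the trial
#' factors: Salt (NaCl level), Cultivar (genotype), their interaction
#' (the G-by-E term), and Replicate. Sums of squares are Type II by
#' default, which is order-invariant and robust to the mild imbalance left
#' by record-level QC; Type I (sequential, in the order Salt, Cultivar,
#' Replicate, Salt:Cultivar) is available. The interaction is only tested
#' when residual degrees of freedom remain after fitting it; otherwise it
#' is reported as untestable and dropped from the fit. Factors observed at
#' a single level are dropped with a warning. p values below 1e-300 are
#' floored so that -log10(p) caps at 300.
#'
#' @param records QC'd `pheno_table`.
#' @param trait trait column to analyse.
#' @param ss_type `"II"` (default) or `"I"`.
#' @return an `anova_result`: data.frame with one row per tested factor plus
#'   `Residuals` — columns `term`, `sum_sq`, `df`, `statistic` (F),
#'   `p_value`, `neg_log10_p` — with attributes `trait` and `untestable`.
#' @export
factorial_anova <- function(records, trait, ss_type = c("II", "I")) {
  stopifnot(inherits(records, "pheno_table"), trait %in% TRAITS)
  ss_type <- match.arg(ss_type)
  d <- records[!is.na(records[[trait]]), , drop = FALSE]
  if (nrow(d) < 4L) stop("too few observations for ANOVA on ", trait, call. = FALSE)
  d$Salt <- factor(d$concentration)
  d$Cultivar <- factor(d$variety)
  d$Replicate <- factor(d$replicate)
  d$y <- d[[trait]]

  terms <- c("Salt", "Cultivar", "Replicate")
  single <- terms[vapply(terms, function(t) nlevels(d[[t]]) < 2L, logical(1))]
  if (length(single)) {
    warning("factor(s) with a single observed level dropped: ",
            paste(single, collapse = ", "))
    terms <- setdiff(terms, single)
  }
  if (!length(terms)) stop("no factor has two or more levels", call. = FALSE)

  with_int <- all(c("Salt", "Cultivar") %in% terms)
  untestable <- character()
  make_formula <- function(interaction) {
    rhs <- terms
    if (interaction) rhs <- c(rhs, "Salt:Cultivar")
    stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  }
  fit <- lm(make_formula(with_int), data = d)
  if (with_int && stats::df.residual(fit) <= 0L) {
    untestable <- "Salt:Cultivar"
    with_int <- FALSE
    fit <- lm(make_formula(FALSE), data = d)
  }

  tab <- if (ss_type == "II") {
    # car::Anova refuses a perfect fit (RSS = 0); fall back to computing the
    # Type II sums of squares directly from residual-SS differences
    a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
    if (!is.null(a)) {
      data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]], df = a[["Df"]],
                 statistic = a[["F value"]], p_value = a[["Pr(>F)"]],
                 stringsAsFactors = FALSE)
    } else {
      type2_ss_manual(d, terms, with_int)
    }
  } else {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]], df = a[["Df"]],
               statistic = a[["F value"]], p_value = a[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  }
  tab$p_value[!is.na(tab$p_value) & tab$p_value < 1e-300] <- 1e-300
  tab$neg_log10_p <- -log10(tab$p_value)
  attr(tab, "trait") <- trait
  attr(tab, "untestable") <- untestable
  attr(tab, "ss_type") <- ss_type
  class(tab) <- c("anova_result", "data.frame")
  tab
}

# Type II SS by explicit model comparison, honouring marginality: the null
# model for a term omits every term containing it; used when the fit is
# perfect and the standard route declines. F and p are degenerate there
# (zero residual variance): F = Inf for a non-zero SS, p = 0.
type2_ss_manual <- function(d, terms, with_int) {
  rhs_formula <- function(tt) {
    if (!length(tt)) return(stats::as.formula("y ~ 1"))
    stats::as.formula(paste("y ~", paste(tt, collapse = " + ")))
  }
  rss_df <- function(tt) {
    f <- lm(rhs_formula(tt), data = d)
    c(rss = sum(stats::resid(f)^2), df = stats::df.residual(f))
  }
  all_terms <- c(terms, if (with_int) "Salt:Cultivar")
  full <- rss_df(all_terms)
  rows <- list()
  for (term in all_terms) {
    contains <- if (term %in% c("Salt", "Cultivar") && with_int)
      c(term, "Salt:Cultivar") else term
    null_terms <- setdiff(all_terms, contains)
    alt_terms <- c(null_terms, term)
    r0 <- rss_df(null_terms); r1 <- rss_df(alt_terms)
    ss <- max(r0["rss"] - r1["rss"], 0)
    df <- r0["df"] - r1["df"]
    rows[[term]] <- data.frame(term = term, sum_sq = unname(ss),
                               df = unname(df), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(term = "Residuals", sum_sq = unname(full["rss"]),
                               df = unname(full["df"])))
  mse <- full["rss"] / max(full["df"], 1)
  tab$statistic <- ifelse(tab$term == "Residuals", NA_real_,
                          ifelse(mse > 0, (tab$sum_sq / tab$df) / mse,
                                 ifelse(tab$sum_sq > 1e-12, Inf, NaN)))
  tab$p_value <- ifelse(is.na(tab$statistic) | is.nan(tab$statistic), NA_real_,
                        stats::pf(tab$statistic, tab$df, full["df"],
                                  lower.tail = FALSE))
  rownames(tab) <- NULL
  tab
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Factorial ANOVA (Type %s SS) for %s\n",
              attr(x, "ss_type"), attr(x, "trait")))
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 5)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- format.pval(df$p_value, digits = 3)
  df$neg_log10_p <- round(df$neg_log10_p, 2)
  print(df, row.names = FALSE)
  if (length(attr(x, "untestable")))
    cat("untestable (no residual df):", paste(attr(x, "untestable"), collapse = ", "), "\n")
  invisible(x)
}

#' Pearson trait correlations at one concentration
#'
#' Pairwise-complete Pearson correlations among the four traits across
#' varieties at a representative NaCl level (100 mM in the default
#' pipeline), with two-sided p values from the t transform of r on n - 2
#' degrees of freedom and the four-star significance ladder
#' (`*` p<0.05 ... `****` p<0.0001). A zero-variance trait yields `NA`
#' entries with the reason recorded.
#'
#' @param tm a `trait_matrix`.
#' @param concentration NaCl level (mM) at which to correlate.
#' @return a `correlation_result`: list with matrices `r`, `p`, `stars`,
#'   `n` (pairwise sample sizes), `concentration`, and `notes`.
#' @export
correlation_matrix <- function(tm, concentration = 100) {
  stopifnot(inherits(tm, "trait_matrix"))
  d <- tm[tm$concentration == concentration, TRAITS, drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 varieties at ", concentration, " mM", call. = FALSE)
  k <- length(TRAITS)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(TRAITS, TRAITS))
  notes <- character()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      x <- d[[i]]; y <- d[[j]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (sum(ok) < 3L || var(x[ok]) == 0 || var(y[ok]) == 0) {
        notes <- c(notes, sprintf("%s~%s: undefined (zero variance or n < 3)",
                                  TRAITS[i], TRAITS[j]))
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix(p_stars(p), k, k, dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = n,
                 concentration = concentration, notes = notes),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson trait correlations at %g mM NaCl\n", x$concentration))
  cat("(upper triangle: r; lower triangle: significance)\n")
  k <- nrow(x$r)
  grid <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    grid[i, j] <- if (j > i) formatC(x$r[i, j], digits = digits, format = "f")
    else if (j < i) x$stars[i, j]
    else "1"
  }
  print(as.data.frame(grid))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
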