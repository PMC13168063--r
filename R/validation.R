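#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification of qPCR data against a reference gene
#' and a control condition. Technical replicates are averaged at the Ct
#' level per (gene, variety, condition, biological replicate); then
#' dCt = Ct_target - Ct_reference per biological replicate,
#' ddCt = dCt_treated - mean(dCt_control), and fold change = 2^-ddCt.
#' Fold changes are reported per biological replicate and summarized as
#' mean +/- SD; the control condition's fold change is 1 by construction
#' (of its mean ddCt). Adding a constant to all Ct values leaves the result
#' unchanged (reference normalization).
#'
#' @param ct data.frame with columns `gene`, `variety`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`.
#' @param control value of `condition` identifying the unstressed control
#'   (default `"control"`).
#' @return data.frame with one row per (gene, variety, non-control
#'   condition): `ddct` (mean over biological replicates), `fold_change`
#'   (= 2^-ddct), `fold_mean` and `fold_sd` (across biological replicates),
#'   `n_bio`.
#' @examples
#' ct <- data.frame(gene = "g", variety = "v",
#'                  condition = rep(c("control", "salt"), each = 1),
#'                  bio_rep = 1, tech_rep = 1,
#'                  ct_target = c(24, 22), ct_reference = c(20, 20))
#' ddct_fold_change(ct)$fold_change  # 4
#' @export
ddct_fold_change <- function(ct, control = "control") {
  need <- c("gene", "variety", "condition", "bio_rep", "tech_rep",
            "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(ct$ct_reference)))
    stop("missing reference-gene Ct", call. = FALSE)
  if (any(is.na(ct$ct_target))) stop("missing target Ct", call. = FALSE)
  if (any(ct$ct_target < 0) || any(ct$ct_reference < 0))
    stop("negative Ct value", call. = FALSE)
  if (!control %in% ct$condition)
    stop("control condition '", control, "' absent", call. = FALSE)

  # collapse technical replicates at the Ct level
  agg <- aggregate(ct[c("ct_target", "ct_reference")],
                   by = ct[c("gene", "variety", "condition", "bio_rep")],
                   FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference

  out <- list()
  for (g in unique(agg$gene)) for (v in unique(agg$variety[agg$gene == g])) {
    sub <- agg[agg$gene == g & agg$variety == v, ]
    ctrl <- sub$dct[sub$condition == control]
    if (!length(ctrl))
      stop("no control dCt for gene ", g, ", variety ", v, call. = FALSE)
    for (cond in setdiff(unique(sub$condition), control)) {
      dd <- sub$dct[sub$condition == cond] - mean(ctrl)
      folds <- 2^(-dd)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, variety = v, condition = cond,
        ddct = mean(dd), fold_change = 2^(-mean(dd)),
        fold_mean = mean(folds),
        fold_sd = if (length(folds) > 1) sd(folds) else NA_real_,
        n_bio = length(folds), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Potassium/sodium ratio
#'
#' K+/Na+ content ratio per dry weight; higher values indicate better ion
#' homeostasis under salt stress.
#'
#' @param k potassium content (>= 0).
#' @param na sodium content (> 0).
#' @return k / na, vectorized.
#' @export
k_na_ratio <- function(k, na) {
  assert_number(k, "k", lower = 0)
  if (any(!is.finite(na)) || any(na <= 0))
    stop("Na content must be positive: K+/Na+ undefined", call. = FALSE)
  k / na
}

#' Two-group comparison with significance stars
#'
#' Two-sided two-sample t test (Welch by default; Student's with
#' `var_equal = TRUE`) with the three-star ladder used for
#' control-vs-treatment physiology panels: `*` p<0.05, `**` p<0.01,
#' `***` p<0.001, else `ns`. When both groups are constant the test
#' degenerates: equal means give p = 1 (`ns`), different means p = 0.
#'
#' @param values_a,values_b numeric replicate values (>= 2 each).
#' @param var_equal assume equal variances (Student's t) instead of Welch.
#' @param thresholds star cutoffs, loosest first.
#' @return list with `p_value`, `star`, `statistic`, `method`.
#' @export
group_compare <- function(values_a, values_b, var_equal = FALSE,
                          thresholds = c(0.05, 0.01, 0.001)) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    p <- if (mean(values_a) == mean(values_b)) 1 else 0
    return(list(p_value = p, star = p_stars(p, thresholds),
                statistic = NA_real_, method = "degenerate (zero variance)"))
  }
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  list(p_value = tt$p.value, star = p_stars(tt$p.value, thresholds),
       statistic = unname(tt$statistic), method = tt$method)
}
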