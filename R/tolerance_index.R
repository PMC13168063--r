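#' Salt tolerance index
#'
#' The relative-value index STI = T_stress / T_control: the ratio of a trait
#' under salt stress to the same trait under control conditions. 1 means no
#' reduction; values above 1 (stress-stimulated growth) are legal and are
#' not clamped.
#'
#' @param t_stress trait value under stress (>= 0).
#' @param t_control trait value under control conditions (> 0).
#' @return numeric STI value(s); vectorized.
#' @examples
#' salt_tolerance_index(50, 100)   # 0.5
#' salt_tolerance_index(100, 100)  # 1
#' @export
salt_tolerance_index <- function(t_stress, t_control) {
  assert_number(t_stress, "t_stress", lower = 0)
  if (!is.numeric(t_control) || any(!is.finite(t_control)) || any(t_control <= 0))
    stop("control value is zero or negative: STI undefined", call. = FALSE)
  t_stress / t_control
}

#' Germination rate
#'
#' Proportion of germinated seeds among all seeds tested.
#'
#' @param n_germinated count of germinated seeds (0..n_total).
#' @param n_total total seeds tested (> 0).
#' @return proportion in \[0, 1\].
#' @export
germination_rate <- function(n_germinated, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_germinated < 0) || any(n_germinated > n_total))
    stop("n_germinated must lie in [0, n_total]", call. = FALSE)
  n_germinated / n_total
}

#' Recompute STI for every variety and stress level
#'
#' Forms STI = trait(stress level) / trait(control level) from an aggregated
#' trait matrix, for each variety and each non-control concentration.
#' Varieties whose control cell is missing or zero are reported with status
#' `"undefined_control"` rather than silently dropped.
#'
#' @param tm a `trait_matrix` from [aggregate_replicate_means()].
#' @param trait which trait underlies the index (default plant height, the
#'   pipeline's primary STI trait).
#' @param control_level concentration (mM) treated as the unstressed control.
#' @return data.frame with columns `variety`, `concentration`, `trait`,
#'   `t_stress`, `t_control`, `sti`, `status`.
#' @export
sti_table <- function(tm, trait = "plant_height", control_level = 0) {
  stopifnot(inherits(tm, "trait_matrix"), trait %in% TRAITS)
  levels_ <- sort(unique(tm$concentration))
  if (!control_level %in% levels_)
    stop("control level ", control_level, " mM absent from the table", call. = FALSE)
  stress_levels <- setdiff(levels_, control_level)
  rows <- list()
  for (v in unique(tm$variety)) {
    ctrl <- tm[[trait]][tm$variety == v & tm$concentration == control_level]
    ctrl <- if (length(ctrl)) ctrl[1L] else NA_real_
    for (s in stress_levels) {
      ts <- tm[[trait]][tm$variety == v & tm$concentration == s]
      ts <- if (length(ts)) ts[1L] else NA_real_
      ok <- !is.na(ctrl) && ctrl > 0
      rows[[length(rows) + 1L]] <- data.frame(
        variety = v, concentration = s, trait = trait,
        t_stress = ts, t_control = ctrl,
        sti = if (ok && !is.na(ts)) ts / ctrl else NA_real_,
        status = if (!ok) "undefined_control" else if (is.na(ts)) "missing_stress" else "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
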