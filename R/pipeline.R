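#' Pipeline run configuration
#'
#' Exactly one of `input` (path to a long-format phenotype table) or
#' `simulation` (a [sim_config()]) must be given. The remaining fields set
#' the analysis knobs: control level, representative concentration for the
#' correlation heatmap, K for K-means, TOPSIS criterion mode and weights,
#' and the seed recorded in the run manifest.
#'
#' @param input path to a phenotype table, or `NULL`.
#' @param simulation a [sim_config()], or `NULL`.
#' @param control_level control NaCl level (mM).
#' @param correlation_level representative level for trait correlations.
#' @param k number of K-means groups.
#' @param qc QC rules from [qc_rules()].
#' @param sti_trait trait underlying the recomputed STI.
#' @param topsis_mode `"trait_means"` (each trait averaged across all salt
#'   levels; 4 criteria) or `"at_level"` (the 4 traits at
#'   `correlation_level`).
#' @param topsis_weights `"equal"` or `"entropy"` or a numeric vector.
#' @param n_top,n_bottom extremes to select from the TOPSIS ranking.
#' @param seed integer seed for the stochastic stages (K-means; and the
#'   simulation when no seed is set in `simulation`).
#' @param out_dir directory for stage artifacts, or `NULL` to keep results
#'   in memory only.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       control_level = 0, correlation_level = 100,
                       k = 3, qc = qc_rules(), sti_trait = "plant_height",
                       topsis_mode = c("trait_means", "at_level"),
                       topsis_weights = "equal",
                       n_top = 30, n_bottom = 5,
                       seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' or 'simulation' must be set", call. = FALSE)
  structure(list(input = input, simulation = simulation,
                 control_level = control_level,
                 correlation_level = correlation_level,
                 k = k, qc = qc, sti_trait = sti_trait,
                 topsis_mode = match.arg(topsis_mode),
                 topsis_weights = topsis_weights,
                 n_top = n_top, n_bottom = n_bottom,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(obj, name, out_dir, manifest) {
  if (is.null(out_dir)) return(manifest)
  path <- file.path(out_dir, paste0(name, ".csv"))
  df <- as.data.frame(obj)
  if (!is.null(rownames(obj)) && !identical(rownames(obj), as.character(seq_len(nrow(df)))))
    df <- cbind(id = rownames(obj), df)
  write.csv(df, path, row.names = FALSE)
  manifest$artifacts[[name]] <- list(path = path,
                                     md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full salt-tolerance screening pipeline
#'
#' Executes the stages in order: load or simulate -> QC -> replicate
#' aggregation -> STI recomputation -> dose-response summaries -> per-trait
#' factorial ANOVA -> trait correlations -> wide matrix -> Z-score ->
#' Euclidean distances -> UPGMA + Newick -> PCA -> K-means -> TOPSIS ->
#' extreme selection. Each stage's table is written to `out_dir` (when set)
#' along with the Newick tree and a JSON manifest of artifact checksums;
#' re-running with the same configuration reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @return a `salt_screen` object: list carrying every stage result
#'   (`qc_report`, `trait_matrix`, `sti`, `dose_response`, `anova`,
#'   `correlation`, `wide`, `tree`, `newick`, `pca`, `clusters`, `topsis`,
#'   `selection`, `truth` when simulated, and `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(package_version = as.character(packageVersion("saltrank")),
                   seed = config$seed, timestamp = format(Sys.time()),
                   artifacts = list())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  records <- stage("load", {
    if (!is.null(config$input)) load_phenotype_table(config$input)
    else {
      sim <- config$simulation
      trial <- simulate_trial(sim)
      truth <- trial$truth
      trial$records
    }
  })

  qc <- stage("qc", quality_control(records, config$qc))
  tm <- stage("aggregate", aggregate_replicate_means(qc$records))
  sti <- stage("sti", sti_table(tm, trait = config$sti_trait,
                                control_level = config$control_level))
  dr <- stage("dose_response", dose_response_table(tm))
  anovas <- stage("anova", {
    out <- lapply(TRAITS, function(tr) factorial_anova(qc$records, tr))
    names(out) <- TRAITS
    out
  })
  corr <- stage("correlation", correlation_matrix(tm, config$correlation_level))
  wide <- stage("wide_matrix", build_wide_matrix(tm))
  zs <- stage("zscore", zscore_standardize(wide, constant = "zero"))
  dmat <- stage("distance", euclidean_distance_matrix(zs))
  tree <- stage("upgma", upgma(dmat))
  pca <- stage("pca", pheno_pca(zs))
  clusters <- stage("kmeans", kmeans_cluster(pca, k = config$k, seed = config$seed))

  ts <- stage("topsis", {
    crit <- topsis_criteria(tm, mode = config$topsis_mode,
                            level = config$correlation_level)
    w <- config$topsis_weights
    w <- if (identical(w, "equal")) NULL
         else if (identical(w, "entropy")) entropy_weights(crit)
         else w
    topsis(crit, weights = w)
  })
  selection <- stage("selection",
                     rank_and_select(ts, min(config$n_top, length(ts$score)),
                                     min(config$n_bottom,
                                         length(ts$score) - min(config$n_top, length(ts$score)))))

  # artifacts
  if (!is.null(out_dir)) {
    manifest <- write_stage(tm, "trait_matrix", out_dir, manifest)
    manifest <- write_stage(sti, "sti_table", out_dir, manifest)
    manifest <- write_stage(dr, "dose_response", out_dir, manifest)
    for (tr in TRAITS)
      manifest <- write_stage(as.data.frame(anovas[[tr]]),
                              paste0("anova_", tr), out_dir, manifest)
    manifest <- write_stage(corr$r, "correlation_r", out_dir, manifest)
    manifest <- write_stage(corr$stars, "correlation_stars", out_dir, manifest)
    manifest <- write_stage(as.matrix(dmat), "distance_matrix", out_dir, manifest)
    nwk_path <- file.path(out_dir, "tree.nwk")
    write_newick(tree, nwk_path)
    manifest$artifacts[["tree"]] <- list(path = nwk_path,
                                         md5 = unname(tools::md5sum(nwk_path)))
    manifest <- write_stage(pca$scores, "pca_scores", out_dir, manifest)
    manifest <- write_stage(pca$loadings, "pca_loadings", out_dir, manifest)
    manifest <- write_stage(data.frame(variety = names(clusters$cluster),
                                       cluster = clusters$cluster),
                            "clusters", out_dir, manifest)
    manifest <- write_stage(data.frame(variety = names(ts$score),
                                       score = ts$score, rank = ts$rank),
                            "topsis_ranking", out_dir, manifest)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(config = config, qc_report = qc$report, records = qc$records,
                 trait_matrix = tm, sti = sti, dose_response = dr,
                 anova = anovas, correlation = corr, wide = wide,
                 standardized = zs, tree = tree,
                 newick = write_newick(tree), pca = pca,
                 clusters = clusters, topsis = ts, selection = selection,
                 truth = truth, manifest = manifest),
            class = "salt_screen")
}

# criteria table for the TOPSIS stage: per-variety trait values, either
# averaged across all salt levels or taken at a single level
topsis_criteria <- function(tm, mode = "trait_means", level = 100) {
  W <- build_wide_matrix(tm)
  if (mode == "at_level") {
    cols <- paste0(TRAITS, "_", level)
    miss <- setdiff(cols, colnames(W))
    if (length(miss)) stop("criterion absent: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    X <- W[, cols, drop = FALSE]
    colnames(X) <- TRAITS
  } else {
    X <- sapply(TRAITS, function(tr)
      rowMeans(W[, grep(paste0("^", tr, "_"), colnames(W)), drop = FALSE]))
  }
  X
}

#' Dose-response summary table
#'
#' For every trait and NaCl level: the across-variety mean, SD and n of the
#' replicate-aggregated values, plus the same summaries computed separately
#' per replicate (to display replicate consistency). A single-variety table
#' yields `NA` SDs, flagged in the `note` column.
#'
#' @param tm a `trait_matrix` from [aggregate_replicate_means()].
#' @return data.frame with columns `trait`, `concentration`, `replicate`
#'   (`"pooled"` or the replicate number), `mean`, `sd`, `n`, `note`.
#' @export
dose_response_table <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  reps <- attr(tm, "replicates")
  rows <- list()
  add <- function(trait, conc, rep_lab, x) {
    x <- x[!is.na(x)]
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = trait, concentration = conc, replicate = rep_lab,
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_,
      n = length(x),
      note = if (length(x) <= 1) "sd undefined (n <= 1)" else "",
      stringsAsFactors = FALSE)
  }
  for (tr in TRAITS) for (conc in sort(unique(tm$concentration))) {
    add(tr, conc, "pooled", tm[[tr]][tm$concentration == conc])
    if (!is.null(reps))
      for (r in sort(unique(reps$replicate)))
        add(tr, conc, as.character(r),
            reps[[tr]][reps$concentration == conc & reps$replicate == r])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-QC dataset checks
#'
#' Computes the headline dataset-level quantities of a screening run from a
#' phenotype table: the record count retained after QC, and the PC1/PC2
#' variance-explained percentages of the Z-scored variety x
#' (trait x concentration) matrix.
#'
#' @param records a `pheno_table` (loaded or simulated).
#' @param qc QC rules.
#' @return list with `n_records_retained`, `n_varieties`, `pc1_pct`,
#'   `pc2_pct`.
#' @export
supplementary_checks <- function(records, qc = qc_rules()) {
  q <- quality_control(records, qc)
  tm <- aggregate_replicate_means(q$records)
  zs <- zscore_standardize(build_wide_matrix(tm), constant = "zero")
  pc <- pheno_pca(zs)
  list(n_records_retained = q$report$n_retained,
       n_varieties = length(unique(q$records$variety)),
       pc1_pct = 100 * pc$variance_explained[1],
       pc2_pct = 100 * pc$variance_explained[2])
}

#' @export
print.salt_screen <- function(x, ...) {
  cat("Salt-tolerance screening run\n")
  print(x$qc_report)
  cat(sprintf("  varieties: %d; NaCl levels: %s mM\n",
              length(unique(x$trait_matrix$variety)),
              paste(sort(unique(x$trait_matrix$concentration)), collapse = "/")))
  ve <- round(100 * x$pca$variance_explained[1:2], 1)
  cat(sprintf("  PCA: PC1 %.1f%%, PC2 %.1f%%; K-means K = %d\n",
              ve[1], ve[2], x$clusters$k))
  cat("  TOPSIS top:", paste(head(x$selection$top, 5), collapse = ", "), "...\n")
  cat("  TOPSIS bottom:", paste(head(x$selection$bottom, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.salt_screen <- function(object, ...) {
  print(object)
  cat("\nPer-trait ANOVA (-log10 p):\n")
  for (tr in TRAITS) {
    a <- object$anova[[tr]]
    keep <- a$term != "Residuals"
    cat(sprintf("  %-17s %s\n", tr,
                paste(sprintf("%s=%.1f", a$term[keep], a$neg_log10_p[keep]),
                      collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.salt_screen <- function(x, ...) {
  dr <- x$dose_response
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (tr in TRAITS) {
    d <- dr[dr$trait == tr & dr$replicate == "pooled", ]
    plot(d$concentration, d$mean, type = "b", pch = 19,
         xlab = "NaCl (mM)", ylab = tr, main = tr, ...)
  }
  invisible(x)
}
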