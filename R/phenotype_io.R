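#' Read a long-format phenotype table
#'
#' Reads a delimited trial table with one row per (variety, replicate, NaCl
#' concentration) observation and the four phenotypes: plant height (mm),
#' root length (mm), germination rate, and salt tolerance index. Column
#' names are matched case-insensitively against canonical names plus any
#' synonyms supplied in `dialect`. Germination values in (1, 100] are taken
#' to be percentages and are coerced to proportions (flag `UNIT_COERCED`);
#' unparseable numeric cells become `NA` with a `MISSING` flag rather than
#' aborting the load. Variety labels are whitespace-trimmed and upper-cased.
#'
#' @param path path to a comma- or tab-delimited text file (a spreadsheet
#'   exported to CSV works as-is).
#' @param dialect optional list with elements `sep` (`","`/`"\t"`, default
#'   sniffed from the header line) and `synonyms`, a named list mapping
#'   canonical column names to acceptable aliases, e.g.
#'   `list(variety = c("genotype", "cultivar"))`.
#' @return a `pheno_table`: a data.frame with columns `variety`, `replicate`,
#'   `concentration`, `plant_height`, `root_length`, `germination_rate`,
#'   `sti`, plus a `flags` attribute logging per-cell QC flags
#'   (`row`, `trait`, `flag`, `detail`).
#' @seealso [quality_control()], [aggregate_replicate_means()]
#' @export
load_phenotype_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- dialect$sep %||% if (grepl("\t", header)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty table: ", path, call. = FALSE)

  canonical <- c("variety", "replicate", "concentration", TRAITS)
  syn <- list(
    variety = c("variety", "variety_name", "genotype", "cultivar", "line", "variety_id"),
    replicate = c("replicate", "rep", "replicate_number", "block"),
    concentration = c("concentration", "conc", "nacl", "nacl_mm", "salt_concentration",
                      "treatment", "nacl_concentration"),
    plant_height = c("plant_height", "height", "shoot_height", "plant_height_mm"),
    root_length = c("root_length", "root", "root_length_mm"),
    germination_rate = c("germination_rate", "germination", "germ_rate", "germination_percent"),
    sti = c("sti", "salt_tolerance_index", "tolerance_index")
  )
  for (nm in names(dialect$synonyms %||% list()))
    syn[[nm]] <- unique(c(syn[[nm]], dialect$synonyms[[nm]]))

  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  have <- norm(names(raw))
  idx <- integer(length(canonical)); names(idx) <- canonical
  for (nm in canonical) {
    hit <- which(have %in% norm(syn[[nm]]))
    if (length(hit) == 0L)
      stop("missing required column '", nm, "' in ", path, call. = FALSE)
    idx[nm] <- hit[1L]
  }

  flags <- list()
  note <- function(row, trait, flag, detail) {
    flags[[length(flags) + 1L]] <<- data.frame(
      row = row, trait = trait, flag = flag, detail = detail,
      stringsAsFactors = FALSE)
  }

  num_col <- function(col, nm) {
    x <- suppressWarnings(as.numeric(raw[[idx[nm]]]))
    bad <- which(is.na(x) & nzchar(trimws(raw[[idx[nm]]])))
    for (r in bad) note(r, nm, "MISSING", paste0("unparseable value '", raw[r, idx[nm]], "'"))
    blank <- which(!nzchar(trimws(raw[[idx[nm]]])))
    for (r in blank) note(r, nm, "MISSING", "blank cell")
    x
  }

  out <- data.frame(
    variety = toupper(trimws(raw[[idx["variety"]]])),
    replicate = suppressWarnings(as.integer(raw[[idx["replicate"]]])),
    concentration = suppressWarnings(as.numeric(raw[[idx["concentration"]]])),
    stringsAsFactors = FALSE
  )
  for (tr in TRAITS) out[[tr]] <- num_col(tr, tr)

  # germination given as a percentage: anything in (1, 100] is coerced
  pct <- which(!is.na(out$germination_rate) & out$germination_rate > 1 &
                 out$germination_rate <= 100)
  if (length(pct)) {
    out$germination_rate[pct] <- out$germination_rate[pct] / 100
    for (r in pct) note(r, "germination_rate", "UNIT_COERCED", "percent -> proportion")
  }
  over <- which(!is.na(out$germination_rate) & out$germination_rate > 1)
  if (length(over)) {
    out$germination_rate[over] <- NA_real_
    for (r in over) note(r, "germination_rate", "MISSING", "value > 100, unusable")
  }

  attr(out, "flags") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), trait = character(), flag = character(),
               detail = character(), stringsAsFactors = FALSE)
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Build a phenotype table from in-memory data
#'
#' Convenience constructor giving data.frames the `pheno_table` class and an
#' empty flag log, so simulated or hand-built data enter the pipeline on the
#' same footing as loaded files.
#'
#' @param df data.frame with the canonical columns `variety`, `replicate`,
#'   `concentration`, `plant_height`, `root_length`, `germination_rate`, `sti`.
#' @return a `pheno_table`.
#' @export
as_pheno_table <- function(df) {
  need <- c("variety", "replicate", "concentration", TRAITS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, need]
  df$variety <- toupper(trimws(as.character(df$variety)))
  if (is.null(attr(df, "flags")))
    attr(df, "flags") <- data.frame(row = integer(), trait = character(),
                                    flag = character(), detail = character(),
                                    stringsAsFactors = FALSE)
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Default quality-control rules
#'
#' Outliers are judged by a robust z-score, |x - median| / (1.4826 * MAD),
#' computed within each (trait, concentration) stratum; records exceeding
#' the threshold in any trait are removed. Strata with fewer than
#' `min_stratum` observations are left untouched (logged). When the MAD
#' collapses to zero (a majority of identical values) the scale falls back
#' to the normal-consistent mean absolute deviation (1.2533 x); a fully
#' constant stratum treats any deviation beyond `eps` as outlying.
#'
#' @param threshold robust z cutoff (default 4 — conservative).
#' @param min_stratum minimum stratum size for the rule to apply.
#' @param eps absolute slack used when the stratum is entirely constant.
#' @return a list of rules for [quality_control()].
#' @export
qc_rules <- function(threshold = 4, min_stratum = 3, eps = 1e-8) {
  assert_number(threshold, "threshold", lower = 0)
  list(threshold = threshold, min_stratum = min_stratum, eps = eps)
}

#' Quality-control a phenotype table
#'
#' Flags missing trait values (already marked at load time or `NA` in the
#' table) and stratum-wise robust-z outliers, removes outlier records, and
#' returns the retained table together with a reconciling report. Records
#' with a missing value in one trait are retained for the other traits.
#' Deterministic for fixed rules; applying it twice yields the same set.
#'
#' @param records a `pheno_table`.
#' @param rules output of [qc_rules()].
#' @return list with elements `records` (retained `pheno_table`) and
#'   `report` (class `qc_report`): counts `n_input`, `n_retained`,
#'   `n_flagged_missing`, `n_flagged_outlier` and the per-rule `log`.
#' @export
quality_control <- function(records, rules = qc_rules()) {
  stopifnot(inherits(records, "pheno_table"))
  n_input <- nrow(records)
  log <- attr(records, "flags")

  outlier_rows <- integer()
  for (tr in TRAITS) {
    for (conc in unique(records$concentration)) {
      stratum <- which(records$concentration == conc & !is.na(records[[tr]]))
      if (length(stratum) < rules$min_stratum) {
        if (length(stratum) > 0L)
          log <- rbind(log, data.frame(row = NA_integer_, trait = tr, flag = "RULE_SKIPPED",
                                       detail = sprintf("stratum conc=%g has %d obs (< %d)",
                                                        conc, length(stratum), rules$min_stratum)))
        next
      }
      x <- records[[tr]][stratum]
      med <- median(x)
      s <- mad(x)  # 1.4826 * median absolute deviation
      dev <- abs(x - med)
      # MAD collapses to 0 when a majority of the stratum is identical;
      # fall back to the scaled mean absolute deviation, then to exact ties
      if (s == 0) s <- 1.2533 * mean(dev)
      out <- if (s > 0) which(dev / s > rules$threshold) else which(dev > rules$eps)
      for (j in out) {
        r <- stratum[j]
        log <- rbind(log, data.frame(
          row = r, trait = tr, flag = "OUTLIER",
          detail = sprintf("robust z %.2f at conc=%g (median %.4g)",
                           if (s > 0) dev[j] / s else Inf, conc, med)))
        outlier_rows <- c(outlier_rows, r)
      }
    }
  }
  outlier_rows <- sort(unique(outlier_rows))
  retained <- if (length(outlier_rows)) records[-outlier_rows, , drop = FALSE] else records
  attr(retained, "flags") <- log
  class(retained) <- c("pheno_table", "data.frame")

  missing_rows <- unique(log$row[log$flag == "MISSING"])
  missing_rows <- union(missing_rows,
                        which(apply(is.na(records[TRAITS]), 1, any)))
  report <- structure(list(
    n_input = n_input,
    n_retained = nrow(retained),
    n_flagged_missing = length(missing_rows[!is.na(missing_rows)]),
    n_flagged_outlier = length(outlier_rows),
    log = log
  ), class = "qc_report")
  list(records = retained, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Phenotype QC report\n")
  cat(sprintf("  input records:   %d\n", x$n_input))
  cat(sprintf("  retained:        %d\n", x$n_retained))
  cat(sprintf("  missing-flagged: %d\n", x$n_flagged_missing))
  cat(sprintf("  outliers removed:%d\n", x$n_flagged_outlier))
  invisible(x)
}

#' Aggregate replicates into a trait matrix
#'
#' Averages trait values across replicates for every (variety,
#' concentration) cell. Seedling-level averaging happens upstream (each
#' record already carries the within-replicate mean); this step forms the
#' across-replicate arithmetic mean of the available replicates. Cells with
#' no observation are `NA`. The per-replicate values are retained in the
#' `replicates` attribute for dose-response plots.
#'
#' @param records QC'd `pheno_table`.
#' @return a `trait_matrix`: data.frame keyed by (`variety`,
#'   `concentration`) with one column per trait.
#' @export
aggregate_replicate_means <- function(records) {
  stopifnot(inherits(records, "pheno_table"))
  if (nrow(records) == 0L) stop("no records to aggregate", call. = FALSE)
  key <- interaction(records$variety, records$concentration, drop = TRUE)
  agg <- aggregate(records[TRAITS], by = list(variety = records$variety,
                                              concentration = records$concentration),
                   FUN = function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  agg <- agg[order(agg$variety, agg$concentration), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- records[, c("variety", "replicate", "concentration", TRAITS)]
  class(agg) <- c("trait_matrix", "data.frame")
  agg
}

#' Write / read the canonical trait-matrix CSV
#'
#' Full-precision (17 significant digits) CSV so that write -> read
#' round-trips reproduce the matrix exactly.
#'
#' @param tm a `trait_matrix`.
#' @param path output path.
#' @return `write_trait_matrix` returns `path` invisibly;
#'   `read_trait_matrix` returns a `trait_matrix`.
#' @export
write_trait_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "trait_matrix"))
  out <- data.frame(variety = tm$variety,
                    concentration = sprintf("%.17g", tm$concentration),
                    stringsAsFactors = FALSE)
  for (tr in TRAITS)
    out[[tr]] <- ifelse(is.na(tm[[tr]]), "", sprintf("%.17g", tm[[tr]]))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  tm <- data.frame(variety = raw$variety,
                   concentration = as.numeric(raw$concentration),
                   stringsAsFactors = FALSE)
  for (tr in TRAITS)
    tm[[tr]] <- suppressWarnings(as.numeric(raw[[tr]]))
  attr(tm, "replicates") <- NULL
  class(tm) <- c("trait_matrix", "data.frame")
  tm
}
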