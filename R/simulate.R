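#' Configuration for the synthetic multi-gradient trial generator
#'
#' Defaults emulate a germination/seedling screening trial: 120 varieties,
#' NaCl at 0/50/100/150 mM, two replicates, five seedlings measured per
#' replicate for the growth traits. Varieties fall into three latent
#' tolerance classes. Growth traits decline exponentially with
#' concentration, `value = baseline * exp(-s * c)`, with the per-genotype
#' sensitivity s drawn around its class mean; roots are more salt-sensitive
#' than shoots (`root_sensitivity_multiplier`). Germination declines on the
#' logit scale only beyond `germination_threshold`, mirroring its stability
#' under mild salinity.
#'
#' @param n_varieties number of genotypes.
#' @param concentrations NaCl levels in mM; must include 0 (control).
#' @param n_replicates independent replicates per variety x level.
#' @param seedlings_per_replicate seedlings averaged per replicate for the
#'   growth traits.
#' @param class_proportions named proportions of tolerant / intermediate /
#'   sensitive genotypes; must sum to 1.
#' @param baseline_means control-condition means: plant height (mm), root
#'   length (mm), germination (proportion).
#' @param genotype_sd SD of genotype baseline effects per trait (mm, mm,
#'   logit units).
#' @param sensitivity_by_class class-mean exponential decline rate per mM.
#' @param gxe_sd SD of the genotype-specific sensitivity around its class
#'   mean (the G-by-E term).
#' @param noise_sd replicate/seedling noise SD per trait (mm, mm, logit).
#' @param root_sensitivity_multiplier factor (> 1) scaling root sensitivity
#'   relative to shoot sensitivity.
#' @param germination_threshold concentration (mM) below which germination
#'   is unaffected.
#' @param germination_sensitivity_scale converts the growth-trait decline
#'   rate to a logit-per-mM decline for germination.
#' @param seed integer; the single source of randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_varieties = 120,
                       concentrations = c(0, 50, 100, 150),
                       n_replicates = 2,
                       seedlings_per_replicate = 5,
                       class_proportions = c(tolerant = 0.25, intermediate = 0.5,
                                             sensitive = 0.25),
                       baseline_means = c(plant_height = 150, root_length = 100,
                                          germination_rate = 0.95),
                       genotype_sd = c(plant_height = 1, root_length = 0.8,
                                       germination_rate = 0.03),
                       sensitivity_by_class = c(tolerant = 0.0015,
                                                intermediate = 0.004,
                                                sensitive = 0.008),
                       gxe_sd = 0.0004,
                       noise_sd = c(plant_height = 6, root_length = 5,
                                    germination_rate = 0.25),
                       root_sensitivity_multiplier = 1.4,
                       germination_threshold = 50,
                       germination_sensitivity_scale = 10,
                       seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (!0 %in% concentrations)
    stop("concentrations must include the 0 mM control", call. = FALSE)
  if (any(baseline_means <= 0))
    stop("baselines must be positive", call. = FALSE)
  assert_number(gxe_sd, "gxe_sd", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(genotype_sd, "genotype_sd", lower = 0)
  assert_number(sensitivity_by_class, "sensitivity_by_class", lower = 0)
  structure(list(
    n_varieties = as.integer(n_varieties),
    concentrations = sort(unique(concentrations)),
    n_replicates = as.integer(n_replicates),
    seedlings_per_replicate = as.integer(seedlings_per_replicate),
    class_proportions = class_proportions,
    baseline_means = baseline_means,
    genotype_sd = genotype_sd,
    sensitivity_by_class = sensitivity_by_class,
    gxe_sd = gxe_sd,
    noise_sd = noise_sd,
    root_sensitivity_multiplier = root_sensitivity_multiplier,
    germination_threshold = germination_threshold,
    germination_sensitivity_scale = germination_sensitivity_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-gradient salt-stress trial
#'
#' Generates a complete phenotype table plus the ground truth behind it.
#' Class sizes are fixed by rounding the class proportions (remainder to
#' the intermediate class) so every class is represented deterministically.
#' Growth-trait records are means of `seedlings_per_replicate` noisy
#' seedling values truncated at zero; germination noise acts on the logit
#' scale. The STI column is computed from the simulated values via
#' [salt_tolerance_index()] against the same replicate's control record,
#' so a zero-sensitivity, zero-noise configuration yields STI = 1
#' everywhere. All randomness flows from `config$seed`; a fixed seed gives
#' byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `records` (a `pheno_table`) and `truth` (a
#'   `truth_table`: per-variety class, baselines, per-trait sensitivities
#'   and the latent tolerance score, the negative mean sensitivity).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_varieties
  ids <- sprintf("V%03d", seq_len(n))

  props <- config$class_proportions
  counts <- floor(props * n)
  counts["intermediate"] <- counts["intermediate"] + (n - sum(counts))
  classes <- rep(names(props), times = counts[names(props)])
  classes <- sample(classes)  # shuffle class labels over ids

  bm <- config$baseline_means; gsd <- config$genotype_sd
  base_h <- pmax(bm["plant_height"] + rnorm(n, 0, gsd["plant_height"]), 1)
  base_r <- pmax(bm["root_length"] + rnorm(n, 0, gsd["root_length"]), 1)
  base_g_logit <- qlogis(bm["germination_rate"]) + rnorm(n, 0, gsd["germination_rate"])

  s_base <- pmax(config$sensitivity_by_class[classes] + rnorm(n, 0, config$gxe_sd), 0)
  s_height <- s_base
  s_root <- s_base * config$root_sensitivity_multiplier
  s_germ <- s_base * config$germination_sensitivity_scale

  truth <- data.frame(
    variety = ids, class = classes,
    baseline_height = base_h, baseline_root = base_r,
    baseline_germ = plogis(base_g_logit),
    s_height = s_height, s_root = s_root, s_germ = s_germ,
    latent = -(s_height + s_root + s_germ) / 3,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("truth_table", "data.frame")

  concs <- config$concentrations
  reps <- seq_len(config$n_replicates)
  k <- config$seedlings_per_replicate
  nsd <- config$noise_sd
  thr <- config$germination_threshold

  grid <- expand.grid(replicate = reps, concentration = concs,
                      g = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$g, grid$concentration, grid$replicate), ]

  m <- nrow(grid)
  height <- root <- germ <- numeric(m)
  for (i in seq_len(m)) {
    g <- grid$g[i]; cc <- grid$concentration[i]
    mu_h <- base_h[g] * exp(-s_height[g] * cc)
    mu_r <- base_r[g] * exp(-s_root[g] * cc)
    height[i] <- mean(pmax(mu_h + rnorm(k, 0, nsd["plant_height"]), 0))
    root[i] <- mean(pmax(mu_r + rnorm(k, 0, nsd["root_length"]), 0))
    lg <- base_g_logit[g] - s_germ[g] * max(0, cc - thr) +
      rnorm(1, 0, nsd["germination_rate"])
    germ[i] <- plogis(lg)
  }

  records <- data.frame(
    variety = ids[grid$g], replicate = grid$replicate,
    concentration = grid$concentration,
    plant_height = height, root_length = root, germination_rate = germ,
    sti = NA_real_, stringsAsFactors = FALSE
  )

  # STI from simulated values: stress / same-replicate control, primary trait
  key <- paste(records$variety, records$replicate)
  ctrl <- records$plant_height[records$concentration == 0]
  names(ctrl) <- key[records$concentration == 0]
  records$sti <- salt_tolerance_index(records$plant_height, ctrl[key])

  list(records = as_pheno_table(records), truth = truth)
}

#' Ground-truth tolerance ranking
#'
#' Orders varieties by their latent tolerance score (negative mean of the
#' per-trait sensitivity parameters), best first; exact ties fall back to
#' lexicographic variety id.
#'
#' @param truth a `truth_table` from [simulate_trial()].
#' @return character vector of variety ids, most tolerant first.
#' @export
truth_ranking <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  truth$variety[order(-truth$latent, truth$variety)]
}
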