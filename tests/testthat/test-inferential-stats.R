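# build a balanced factorial phenotype table from a vector of y values
balanced_pheno <- function(y, varieties = c("A", "B"), concs = c(0, 100),
                           reps = 1:2) {
  g <- expand.grid(replicate = reps, variety = varieties, concentration = concs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$plant_height <- y
  g$root_length <- 1; g$germination_rate <- 0.9; g$sti <- 1
  as_pheno_table(g)
}

test_that("factor SS on a balanced toy table match the hand decomposition", {
  # y depends on Salt only: 10 at 0 mM, 6 at 100 mM, for every variety/rep.
  # Hand: grand mean 8, Salt SS = 4*(10-8)^2 + 4*(6-8)^2 = 32; all other SS 0.
  y <- c(10, 10, 10, 10, 6, 6, 6, 6)
  tab <- balanced_pheno(y)
  a <- factorial_anova(tab, "plant_height")
  ss <- setNames(a$sum_sq, a$term)
  expect_equal(unname(ss["Salt"]), 32, tolerance = 1e-9)
  expect_equal(unname(ss["Cultivar"]), 0, tolerance = 1e-9)
  expect_equal(unname(ss["Replicate"]), 0, tolerance = 1e-9)
  expect_equal(unname(ss["Residuals"]), 0, tolerance = 1e-9)

  # additive Salt + Cultivar effects, hand-decomposed
  # A rows get +1, B rows -1 on top of the salt pattern
  y2 <- c(11, 11, 9, 9, 7, 7, 5, 5)
  a2 <- factorial_anova(balanced_pheno(y2), "plant_height")
  ss2 <- setNames(a2$sum_sq, a2$term)
  expect_equal(unname(ss2["Salt"]), 32, tolerance = 1e-9)
  expect_equal(unname(ss2["Cultivar"]), 8, tolerance = 1e-9)  # 8 * 1^2
  expect_equal(unname(ss2["Residuals"]), 0, tolerance = 1e-9)
})

test_that("on balanced designs the factor SS sum to the total SS", {
  set.seed(21)
  y <- rnorm(8, 10, 2)
  a <- factorial_anova(balanced_pheno(y), "plant_height")
  expect_equal(sum(a$sum_sq), sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("F statistics are invariant to adding a constant to every observation", {
  set.seed(22)
  y <- rnorm(24, 50, 5)
  tab1 <- balanced_pheno(y, varieties = c("A", "B", "C"), concs = c(0, 50, 100, 150),
                         reps = 1:2)
  tab2 <- balanced_pheno(y + 1000, varieties = c("A", "B", "C"),
                         concs = c(0, 50, 100, 150), reps = 1:2)
  a1 <- factorial_anova(tab1, "plant_height")
  a2 <- factorial_anova(tab2, "plant_height")
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-8)
})

test_that("single-level factors are dropped and saturated interactions reported untestable", {
  set.seed(23)
  one_rep <- balanced_pheno(rnorm(8, 10), reps = 1:2)
  one_rep$replicate <- 1  # replicate has a single level now
  expect_warning(a <- factorial_anova(one_rep, "plant_height"), "Replicate")
  expect_false("Replicate" %in% a$term)

  # one observation per Salt x Cultivar cell: interaction saturates the model
  sat <- balanced_pheno(rnorm(8, 10), varieties = c("A", "B"),
                        concs = c(0, 50, 100, 150), reps = 1)
  expect_warning(a2 <- factorial_anova(sat, "plant_height"), "Replicate")
  expect_equal(attr(a2, "untestable"), "Salt:Cultivar")
  expect_false("Salt:Cultivar" %in% a2$term)
})

test_that("the F-based Salt p value agrees with a 20,000-draw permutation oracle", {
  set.seed(24)
  g <- expand.grid(replicate = 1:2, variety = c("A", "B", "C"),
                   concentration = c(0, 50, 100, 150),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- 50 - 0.015 * g$concentration + rnorm(24, 0, 2)
  g$plant_height <- y
  g$root_length <- 1; g$germination_rate <- 0.9; g$sti <- 1
  tab <- as_pheno_table(g)
  a <- factorial_anova(tab, "plant_height")
  F_obs <- a$statistic[a$term == "Salt"]
  p_F <- a$p_value[a$term == "Salt"]

  # independent oracle: Type II F for Salt via residual-sum-of-squares
  # differences on explicitly built design matrices
  Salt <- factor(g$concentration); Cultivar <- factor(g$variety)
  Replicate <- factor(g$replicate)
  X_null <- model.matrix(~ Cultivar + Replicate)
  X_salt <- model.matrix(~ Salt + Cultivar + Replicate)
  X_full <- model.matrix(~ Salt + Cultivar + Replicate + Salt:Cultivar)
  rss <- function(X, y) sum(qr.resid(qr(X), y)^2)
  df_salt <- nlevels(Salt) - 1
  df_res <- nrow(X_full) - qr(X_full)$rank
  f_stat <- function(y) {
    ss_salt <- rss(X_null, y) - rss(X_salt, y)
    (ss_salt / df_salt) / (rss(X_full, y) / df_res)
  }
  expect_equal(f_stat(y), F_obs, tolerance = 1e-8)

  B <- 20000
  set.seed(25)
  exceed <- 0L
  for (b in seq_len(B)) if (f_stat(sample(y)) >= F_obs) exceed <- exceed + 1L
  p_perm <- (exceed + 1) / (B + 1)
  expect_lt(abs(p_perm - p_F), 0.02)
})

test_that("trait correlations: closed-form cases, symmetry, unit diagonal, stars", {
  df <- data.frame(variety = sprintf("V%02d", 1:10), replicate = 1,
                   concentration = 100,
                   plant_height = 1:10, root_length = 2 * (1:10) + 1,
                   germination_rate = seq(1, 0.1, length.out = 10), sti = NA)
  set.seed(26)
  df$sti <- runif(10, 0.4, 0.9)
  tm <- aggregate_replicate_means(as_pheno_table(df))
  cr <- correlation_matrix(tm, 100)
  expect_equal(cr$r["plant_height", "root_length"], 1.0)       # y = 2x + 1
  expect_equal(cr$stars["plant_height", "root_length"], "****")
  expect_equal(cr$r["plant_height", "germination_rate"], -1.0) # y = -x
  expect_identical(cr$r, t(cr$r))
  expect_equal(unname(diag(cr$r)), rep(1, 4))
})

test_that("star ladder maps p values to the published thresholds", {
  expect_equal(p_stars(c(0.2, 0.03, 0.003, 3e-4, 3e-5)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(0.003), "**")
  # boundary values are not significant at their own threshold (strict <)
  expect_equal(p_stars(c(0.05, 0.01, 1e-3, 1e-4)), c("ns", "*", "**", "***"))
})

test_that("zero-variance traits yield NA correlations with a recorded reason", {
  df <- data.frame(variety = sprintf("V%02d", 1:6), replicate = 1,
                   concentration = 100,
                   plant_height = c(5, 7, 6, 8, 9, 4), root_length = 3,
                   germination_rate = seq(0.5, 1, 0.1), sti = 0.8)
  tm <- aggregate_replicate_means(as_pheno_table(df))
  cr <- correlation_matrix(tm, 100)
  expect_true(is.na(cr$r["plant_height", "root_length"]))
  expect_true(length(cr$notes) > 0)
})
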