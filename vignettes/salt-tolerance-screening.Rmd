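---
title: "Multi-gradient salt-tolerance screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-gradient salt-tolerance screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltrank)
```

## The screening problem

Salinity suppresses germination and early seedling growth, and genotypes
differ widely in how fast they decline as salt intensity rises. A
multi-gradient screen evaluates a germplasm panel — here the default design
is 120 varieties — across an NaCl concentration series (0, 50, 100, 150 mM)
with two independent replicates, measuring plant height (mm), root length
(mm), germination rate, and the salt tolerance index

$$\mathrm{STI} = T_\mathrm{stress} / T_\mathrm{control},$$

the ratio of a trait under stress to the same trait under control
conditions. STI = 1 means no reduction; values above 1 are legal and kept.
`saltrank` turns the raw trial table into a ranked panel: quality control,
replicate aggregation, dose–response summaries, factorial ANOVA, trait
correlations, a UPGMA dendrogram, PCA with K-means grouping, and a TOPSIS
composite ranking from which extreme tolerant/sensitive genotypes are
selected.

## Stage-by-stage model and assumptions

**Quality control.** Within each (trait, concentration) stratum a robust
z-score, $|x - \mathrm{median}| / (1.4826\,\mathrm{MAD})$, flags records
beyond a threshold of 4 (conservative; roughly 6.3 SD-equivalents under
normality would be 4 robust units only for gross errors). Strata with fewer
than 3 observations skip the rule. When the MAD collapses to zero — a
majority of identical values, common in germination scores — the scale
falls back to the normal-consistent mean absolute deviation
($1.2533 \times$), and a fully constant stratum flags only exact
deviations. Records flagged as outliers are removed; records with a
missing value in one trait remain available to the other traits. The rule
assumes within-stratum phenotype spread is unimodal; in very small panels
with strong genotype differentiation the spread *is* the signal, and the
threshold should be raised (see `qc_rules()`).

**Aggregation.** Growth traits are measured on five seedlings per
replicate and enter the table as within-replicate means; the pipeline then
averages across replicates per (variety, concentration) cell with the
plain arithmetic mean of available replicates. Cells missing after
aggregation are mean-imputed per feature column — only for the
distance/PCA/TOPSIS stages, with an imputation mask kept — and varieties
missing more than 25% of their 16 features are dropped with a warning.

**Factorial ANOVA.** Each trait is decomposed over fixed effects Salt,
Cultivar, Replicate, and the Salt × Cultivar interaction (the G×E term).
Sums of squares are Type II (order-invariant, appropriate for the mild
imbalance QC introduces); Type I is available by argument. The interaction
is tested only when residual degrees of freedom remain; otherwise it is
reported untestable and dropped from the fit. p values are floored at
1e-300 so $-\log_{10} p$ caps at 300 in plots. A perfect fit (zero
residual SS, which degenerate noise-free simulations produce) bypasses the
standard fitting route and computes the same Type II sums of squares by
explicit model comparison.

**Correlations.** Pairwise-complete Pearson r among the four traits across
varieties at a representative concentration — 100 mM by default, the level
that balances stress response and viability — with two-sided p from the t
transform on n − 2 df and the four-star ladder (\*, \*\*, \*\*\*, \*\*\*\*
at 0.05, 0.01, 0.001, 0.0001, strict inequalities).

**Wide matrix, Z-scores, distances, UPGMA.** The variety × (trait ×
concentration) matrix has 16 columns in a deterministic order (traits in
canonical order, levels ascending). Z-scoring uses the population SD
(divisor n) by default; the sample convention is available and recorded,
since it rescales distances by $\sqrt{n/(n-1)}$. The control-level STI
column is identically 1 by definition, so the pipeline standardizes it to
an all-zero column (the error-on-constant behaviour remains the default of
the standalone function). UPGMA merges the closest pair of clusters, with
new distances as size-weighted averages; node height is half the merge
distance, so the tree is ultrametric. Ties are broken by the
lexicographically smallest pair of representative labels, making output
reproducible across platforms. Trees serialize to single-line Newick with
branch lengths (10 significant digits); labels containing reserved
characters are single-quoted with `''` escapes, and write → read → write
is byte-identical.

**PCA and K-means.** PCA is run on the column-centered (already Z-scored)
matrix by SVD; variance-explained proportions are reported over all
components and sum to 1. Component signs are fixed so the
largest-magnitude loading is positive, making score plots reproducible.
K-means uses K = 3 on the PC1–PC2 scores — retained as the biologically
interpretable tolerant/intermediate/sensitive split, not a statistical
optimum — with 25 random restarts from the run seed, keeping the
lowest-inertia solution. We use multiple random restarts of the standard
`stats::kmeans` (Hartigan–Wong) rather than a k-means++ initialization; at
these problem sizes (≤ a few hundred points in 2-D) 25 restarts reach the
same optimum reliably, and the fixed seed preserves determinism.

**TOPSIS.** All four traits are benefit criteria. The default decision
matrix averages each trait across all salt levels (4 criteria per
variety), so the composite reflects performance over the whole gradient; a
traits-at-one-level mode is available. Columns are vector-normalized
(divided by their Euclidean norm; min–max available), weighted equally by
default (the evaluation declares no basis for unequal weights; entropy
weighting is offered for comparison), and each variety is scored by
relative closeness $C_i = D_i^- / (D_i^+ + D_i^-)$ to the per-criterion
ideal versus anti-ideal. Identical alternatives receive the declared
degenerate value 0.5. Ties in ranking break lexicographically by variety
id. The top 30 and a configurable bottom set are selected as extreme
materials.

**Validation layer.** Relative expression uses the standard
$2^{-\Delta\Delta C_t}$ method: technical replicates are averaged at the
Ct level, $\Delta C_t = C_t^\mathrm{target} - C_t^\mathrm{reference}$ per
biological replicate, $\Delta\Delta C_t$ is taken against the mean control
$\Delta C_t$, and fold changes are summarized across biological replicates
as mean ± SD. Group comparisons (enzyme activities, MDA, proline, ion
contents, K⁺/Na⁺ ratio) use Welch's t by default — with n = 3 biological
replicates, equality of variances is not worth assuming; Student's t is
available — and the three-star ladder. Note that some published panels
mix star conventions in their captions; this package applies the standard
three-star ladder (\* 0.05, \*\* 0.01, \*\*\* 0.001) throughout the
validation layer.

## The synthetic trial generator

`simulate_trial()` emulates the screening design so every stage is
testable without external data. Each genotype belongs to a latent class
(tolerant/intermediate/sensitive, proportions 0.25/0.5/0.25) with an
exponential dose–response for growth traits,

$$\mathrm{value} = \mathrm{baseline}_g \, e^{-s_{g,\mathrm{trait}}\, c} + \varepsilon,$$

where the per-genotype sensitivity $s_g$ is drawn around its class mean
(0.0015 / 0.004 / 0.008 per mM; at 150 mM these give STI ≈ 0.80 / 0.55 /
0.30, the qualitative tolerant-to-sensitive spread a screening gradient is
designed to expose) with G×E spread `gxe_sd = 4e-4`. Root sensitivity is
1.4 × shoot sensitivity (roots respond to salinity earlier and more
strongly); germination declines on the logit scale only beyond 50 mM,
mirroring its stability under mild salt, with a logit-per-mM scale of
10 × $s_g$. Growth noise is additive Gaussian per seedling (6 mm height,
5 mm root), truncated at zero, averaged over 5 seedlings per replicate;
germination noise (0.25) acts on the logit. The STI column is computed
from the simulated records themselves via the same-replicate control, so
a zero-sensitivity, zero-noise configuration yields STI = 1 exactly. All
randomness flows from the single config seed; a fixed seed reproduces the
trial byte for byte.

Ground truth per variety — class, baselines, per-trait sensitivities and
the latent tolerance score (the negative mean of the per-trait
sensitivities) — is returned alongside, and `truth_ranking()` orders
varieties by it for recovery tests.

**What the generator deliberately does not emulate.** Baseline (control
condition) genotype effects are kept small (SDs of 1 mm height, 0.8 mm
root, 0.03 logit germination): the simulated panel differs chiefly in
*salt response*, not intrinsic vigour. This is what makes the recovery
benchmarks well-posed — the latent truth is defined purely by
sensitivities, and independent baseline variation is irreducible noise for
any composite phenotype ranking. Real germplasm panels have substantially
larger baseline heterogeneity (often 5–10% CV), plus spatial/block
effects, germination-time dynamics, and non-exponential response shapes,
none of which are modelled. Passing the recovery tests therefore
demonstrates that the pipeline's arithmetic and ordering logic are
correct, not that TOPSIS rankings of real trials recover "true" tolerance
with these accuracies.

## Numerical choices and degenerate inputs

- Germination values in (1, 100] are interpreted as percentages and
  coerced to proportions with a `UNIT_COERCED` flag; the canonical internal
  form is a proportion in [0, 1].
- Zero or missing control values make STI undefined: the scalar function
  errors, and `sti_table()` reports per-variety `undefined_control` rows
  rather than dropping them.
- `upgma()` enforces exact symmetry of its input ((D + Dᵀ)/2) and refuses
  NA/NaN/Inf distances.
- Equal TOPSIS closeness scores and equal latent truth scores break ties
  lexicographically by variety id, and the degenerate all-identical
  decision matrix scores 0.5 everywhere.
- Two groups that are both constant cannot be t-tested; `group_compare()`
  returns p = 1 ("ns") for equal means and p = 0 otherwise.
- Weights that do not sum to 1 are re-normalized with a warning; negative
  weights are an error.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data: 200 random decision matrices
(≤ 6 × 5) against a brute-force TOPSIS oracle; 100 random metric distance
matrices (≤ 8 leaves) against a naive re-averaging UPGMA oracle; a
40-variety low-noise trial for rank/class recovery; 500 null simulations
(48 observations each) for ANOVA type-I calibration; 20,000- and
50,000-draw permutation oracles for the F and Welch p values; and the
full-size 120 × 4 × 2 design for dataset-level summaries. These sizes keep
a complete run in the order of seconds while leaving the Monte-Carlo
tolerances (±0.02 on permutation agreement, [0.03, 0.07] on the type-I
band) comfortably above their standard errors.

## Known limitations

- The ANOVA treats Replicate as a fixed factor (its significance is part
  of the reporting), not a random block; no mixed-model variant is
  offered.
- No multiple-testing correction is applied across the trait ×
  concentration grid of correlation tests — each heatmap cell is a
  marginal test.
- Mean imputation before distance/PCA shrinks variance slightly; with
  more than trace missingness a model-based imputation would be
  preferable.
- The UPGMA implementation is quadratic per merge (cubic overall), fine
  for hundreds of varieties but not for tens of thousands of leaves.
- TOPSIS weights, normalization and criterion set are declared defaults,
  not estimates; rankings can be sensitive to them, which is why the
  entropy-weight alternative is reported side by side rather than adopted.
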