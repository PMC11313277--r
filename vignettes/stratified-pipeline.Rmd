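---
title: "Methods: sex-stratified differential expression, pathway enrichment, and literature impact"
author: "strataTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataTx)
library(SummarizedExperiment)
```

# The problem

Case/control bulk RNA-seq cohorts are usually analyzed with both sexes
pooled and sex as a covariate. When the disease biology differs between
the sexes, this pooling averages away signals that exist in only one
sex. strataTx instead runs the *identical* analysis independently within
each stratum (female AD vs female CTL, male AD vs male CTL), compares the
two resulting pathway landscapes, and asks — for each enriched pathway —
how strongly that pathway already co-occurs with the disease in the
published literature.

The package emulates the layout of a post-mortem temporal-cortex
Alzheimer's cohort: two strata (female: 36 controls / 28 cases; male: 39
controls / 16 cases; 119 subjects in total), with Age, RNA integrity
number (RIN) and post-mortem interval (PMI, hours) as nuisance
covariates, PMI partially missing.

# Pipeline stages

## PMI imputation

Missing PMI values are replaced by the fixed sentinel **−1**
(`imputePMI()`). This is deliberately a pipeline stage rather than a
simulator behaviour: the simulator emits genuine missing values, so the
imputation rule itself is testable. A sentinel below the support of real
PMI values lets the linear model treat "PMI unknown" as its own
direction rather than silently assigning an average interval.

## Variance-partition gene filter

For each gene, the fixed-effect linear model

$$y_g = \beta_0 + \beta_1\,\mathrm{Age} + \beta_2\,\mathrm{RIN} +
\beta_3\,\mathrm{PMI} + \beta_4\,\mathrm{Dx} + \varepsilon$$

is fitted on `log2(count/sizeFactor + 1)` expression, with diagnosis
coded CTL = 0, AD = 1. Each term is attributed its *marginal*
$\Delta R^2$ (full-model $R^2$ minus the $R^2$ of the model without that
term), the attributed fractions are rescaled to sum to $R^2_{full}$, and
the residual fraction is $1-R^2_{full}$, so the five fractions sum to
one (enforced to within $10^{-8}$ in the tests). Genes with zero
expression variance are flagged (residual 1, attributions 0).

Design choices made here, with reasons:

* **Fixed effects, not a mixed model.** All four covariates are
  continuous or two-level; random-effect machinery would add nothing at
  this design size. This is a deliberate simplification.
* **Marginal $\Delta R^2$ attribution.** For correlated covariates the
  marginal contributions need not sum to $R^2_{full}$; the rescaling
  makes the output a proper partition while preserving the relative
  attribution. Collinear designs are rejected with the offending
  covariate named, never silently dropped.
* **Expression scale.** The variance model runs on normalized
  log2 expression. Running it on raw counts would let library size
  masquerade as covariate signal; the log transform is this package's
  choice and is stated as such.
* **Filter threshold.** `filterGenes()` keeps genes whose diagnosis
  fraction is at least `minDiagnosisFraction` (default **0.01**). No
  canonical threshold exists for this filter; 0.01 removes genes whose
  variance is essentially all nuisance while retaining weak true
  signals, and it is exposed in the configuration.

## Differential expression

The per-gene model is a negative binomial (NB) log-linear GLM with the
same four terms and `log(sizeFactor)` offset:

* **Size factors** are median-of-ratios: for each sample, the median
  over always-detected genes of the ratio to the gene's geometric mean,
  rescaled to geometric mean one (`computeSizeFactors()`).
* **Dispersion** ($\alpha$, with $\mathrm{var} = \mu + \alpha\mu^2$) is
  a per-gene method-of-moments estimate pooled across the two diagnosis
  cells: $\hat\alpha = \max\!\big(0, \sum_c w_c (s^2_c - \bar\mu_c) /
  \sum_c w_c \bar\mu_c^2\big)$, $w_c = n_c - 1$. An optional loess
  trend shrinkage exists (`shrink = TRUE`) but is off by default so the
  estimator's calibration is transparent. This desk-scale estimator
  replaces full empirical-Bayes machinery on purpose: the downstream
  stages do not depend on the DE engine's refinements, and at these
  group sizes (16–60 per cell) the moment estimator recovers the
  generative $\alpha$ well (verified in the tests).
* **Wald test.** Each gene is fitted by IRLS at its fixed $\hat\alpha$
  (through `stats::glm.fit` with the `MASS` NB family), and the
  diagnosis coefficient is tested against the standard normal with its
  unscaled covariance SE. The log2 fold change is
  $\hat\beta_4/\ln 2$, **positive = up in AD**. The direction of the
  published fold-change notation is ambiguous; "up-regulated in AD"
  language throughout the source analysis fixes this convention.
* **Numerical guards.** p-values are floored at $10^{-300}$ before any
  $\log_{10}$; genes that fail to converge, fit singularly, or are all
  zero are flagged and excluded from ranking, never assigned values.
* **Multiple testing** is Benjamini–Hochberg (`adjustBH()`, a thin
  wrapper over `stats::p.adjust` adding missing-value handling and
  range validation).

## Ranking and pre-ranked enrichment

Genes are ordered by the rank statistic $-\log_{10}(p)\times
\mathrm{L2FC}$, descending, with ties broken by lexicographic gene id so
the ordering is fully deterministic. Enrichment uses the **raw**
p-value; reporting (volcano tables, top-20 gene lists) uses the
**adjusted** p-value — both statistics are available because the two
conventions serve different purposes (the ranking only needs a monotone
gene ordering; reported gene lists should reflect FDR).

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: hits increment by $|r_i|^{exponent}/N_R$, misses decrement by
$1/(N-k)$; ES is the extremum of largest magnitude, sign preserved, and
$|ES|\le 1$ always. A tie between the positive and negative extremum
resolves to the positive one (documented, deterministic). The
implementation is checked exactly against an exhaustive position-by-
position oracle on all subsets of small universes and against an
independent external implementation.

The null is **gene-sampling**: `nPerm` random same-size subsets of the
ranked universe, seeded per set size so results do not depend on
collection order, shared across equal-size sets, and shared across
strata (both strata face the same null and identical strata give
identical tables). Then:

* $NES = ES / \overline{|ES_{null}|}$ over nulls of matching sign;
* $p = (1 + \#\{\text{same-sign nulls with } |ES_{null}| \ge |ES|\}) /
  (1 + \#\{\text{same-sign nulls}\})$ — sign-matched exceedance with a
  +1 pseudocount so $p$ is never 0;
* $q$ is Benjamini–Hochberg across all tested pathways. This is simpler
  and monotone compared to the FDR-by-NES-binning variant some GSEA
  implementations use, and is a deliberate divergence from them.

**A consequence worth knowing:** the attainable p floor is
$\approx 2/n_{perm}$, so with $n_{perm}=1000$ a BH q below 0.05 is only
reachable when at most ~25 pathways are tested together. The
synthetic-mode default collection is therefore 20 random sets plus the
planted sets; for larger collections raise `nPerm` proportionally.

Defaults follow pre-ranked convention: `exponent = 1`,
`minSize = 15`, `maxSize = 500`, `nPerm = 1000`, all configurable.

## Cross-stratum comparison

Pathways significant at $q < 0.05$ are intersected and differenced per
direction (`compareStrata()`); by construction
`unique + shared = total` within each stratum and direction, which the
suite asserts as the worked arithmetic example (168/36 and 46/25 totals
with 40/22 shared give 128/14 and 6/3 unique).

## Literature impact Z-score

For a pathway label, the relatedness proportion is
$r = \text{co-mentions with the disease} / \text{total mentions}$; the
impact score is $Z = (r - \bar r_{null})/s_{null}$ against a null of
`nNull = 1000` pathways sampled **without replacement** from a pathway
universe and scored the same way. Choices the source procedure leaves
open, decided here and kept configurable:

* **One shared null** for all scored pathways (per-pathway resampling
  would only add Monte Carlo noise to a comparison across pathways).
* **Zero-denominator convention** $r = 0$, flagged in the output.
* **Query normalization**: underscores/hyphens to spaces, lower-cased,
  multi-word labels quoted as exact phrases, disease term joined by AND.
* The **disease term** is a plain configuration string, so the
  statistic works for any disease literature.

Counts come from a pluggable provider: the fixture provider replays a
JSON count cache (all tests run on it), the live provider speaks the
NCBI E-utilities count interface (network-dependent; live counts drift
and are never test oracles). Queried counts are cached to JSON so
repeated runs issue no duplicate queries; provider failures mark a label
unscored after retries, never fabricate counts.

# The synthetic cohort generator

`simulateCohort()` draws NB counts as a gamma–Poisson mixture with
$\mathrm{var} = \mu + \alpha\mu^2$:

| parameter | default | meaning |
|---|---|---|
| strata | female 36/28, male 39/16 | CTL/AD group sizes |
| `baselineMeanLog` | log(100), sd 1 | per-gene log baseline mean |
| `dispersionLog` | log(0.15), sd 0.5 | log-normal $\alpha$, typical of bulk brain RNA-seq |
| `deFraction` | 0.1 | genes with a true diagnosis effect per stratum |
| `effectSizeLog2` | mean 1, sd 0.25 | magnitude of true L2FC, random sign |
| `covariateEffectScale` | 0.05 | sd of per-gene covariate coefficients per standardized unit |
| `pmiMissingRate` | 0.1 | chance a PMI entry is missing |
| `libsizeLogSd` | 0.2 | log-normal library-size spread |

Age is uniform over 60–95 years; RIN and PMI are truncated normals
(RIN 8 ± 1 on [5, 10]; PMI 12 ± 6 h on [1, 40]) — the simplest
structures that make the variance-partition stage non-trivial.
Covariates enter the log-mean linearly through small gene-specific
coefficients using *fixed* standardization constants, so effects are
comparable across strata and runs. Identical configurations (including
the seed) reproduce bit-identical cohorts.

What the generator deliberately does **not** emulate: read-level data,
batch effects beyond the three covariates, gene–gene correlation, and
outlying samples. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under the stated model — not that
real temporal-cortex data meet that model. Because the published
analysis depends on a controlled-access accession, a dated pathway
release and live literature counts, its real-data pathway tallies are
not reproducible at desk scale; the suite instead verifies the internal
set arithmetic of those tallies and the recovery/calibration properties
on simulated cohorts at the same group sizes.

# Determinism and seeds

Every stochastic stage takes a seed. The pipeline holds one master seed
and derives per-stage seeds with `deriveSeed(master, stageTag)` (a fixed
integer hash, always below $2^{31}$), so stages are independently
reproducible and adding a stage never shifts another stage's stream.
All generators restore the caller's RNG state. The run manifest written
with every report bundle contains the full configuration; in synthetic
(fixture) mode, `configFromManifest()` + `runStratifiedPipeline()`
reproduce every output file bit for bit, which the suite asserts.

# Problem sizes used by the test-suite

The suite exercises: 2000-gene null cohorts at 60 + 60 for Wald
calibration, 1000 genes for fold-change recovery, n = 500 samples for
variance-share recovery (±0.05), 1000 permutations for planted-pathway
recovery, 200 random sets for null calibration, and a 1300-label corpus
with a 1000-pathway null for the impact score. These sizes were chosen
as the smallest at which the Monte Carlo error of each check is clearly
inside its assertion band.

# Known limitations

* The moment dispersion estimator is biased upward when strong
  covariate effects inflate within-cell variance; the default simulator
  keeps nuisance effects modest, and real data with strong confounding
  would warrant the trend-shrinkage option or an empirical-Bayes engine.
* The gene-sampling GSEA null ignores inter-gene correlation (as does
  any pre-ranked permutation of gene labels), so q-values on correlated
  real data are optimistic.
* The literature statistic inherits every bias of keyword queries:
  synonym blindness, no MeSH expansion, and name collisions between
  pathway labels and unrelated phrases.
* A pathway universe whose labels nearly all have zero mentions yields
  a degenerate null; the implementation refuses to score in that case
  rather than return infinite Z values.

# A worked micro-example

```{r example, message = FALSE, warning = FALSE}
cfg <- simConfig(nGenes = 300,
                 strata = data.frame(label = c("female", "male"),
                                     nCTL = c(14L, 14L), nAD = c(12L, 12L)),
                 deFraction = 0.1, seed = 7)
bundle <- runStratifiedPipeline(
    pipelineConfig(simConfig = cfg, nPerm = 300, minSize = 10, seed = 7))
bundle
```

The planted pathway for each stratum (`TRUE_DE_FEMALE`, `TRUE_DE_MALE`)
should surface in that stratum's enrichment table with direction
matching the net sign of its planted effects, while the random sets
stay near the null.
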