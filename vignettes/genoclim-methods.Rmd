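---
title: "Methods: a population-level gene-by-climate interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population-level gene-by-climate interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoclim)
```

## The scientific question

Population mean levels of approach/avoidance personality traits
(Extraversion, Neuroticism) differ across nations. One candidate mechanism
is phenotypic plasticity under thermal stress: if dopaminergic brain
function modulates how strongly rewards are weighted against risks,
populations whose dopamine system genes are, on aggregate, more "efficient"
should drift towards approach traits — but only where the climate is
demanding, because benign climates weaken both the reward and the risk side
of the ledger. Statistically this is a gene-by-environment (GxE)
interaction at the population level: the slope of trait means on a gene
index should be conditional on climatic demand.

genoclim implements each stage of that analysis as a tested component, and
ships a synthetic-data generator so the whole chain can be validated without
any proprietary trait data or literature curation.

## The gene-system index

The unit of genetic information is a literature **sample**: one study
population's frequency of a designated allele of one of nine dopaminergic
polymorphisms (the DAT1 40-bp VNTR coded as 9-repeat carrier frequency,
six DRD2 SNPs, the DRD3 Ser9Gly and the DRD4 C-521T; see
`dopamine_polymorphisms()`). Three conventions matter:

* **Orientation** (`orient_allele()`): each polymorphism has one canonical
  allele; frequencies reported on the other allele are complemented. The
  DAT1 entry is a carrier frequency rather than an allele frequency — it is
  stored in the same `[0, 1]` field and treated identically downstream.
* **Aggregation** (`aggregate_population()`): multiple samples per
  population are combined by the sample-size-weighted mean. Exact duplicate
  contributions are an error; resolving near-duplicate study populations
  requires bibliographic knowledge and is deliberately left to data
  curation.
* **Index construction** (`build_gene_index()`): Pearson correlations of
  the nine frequency columns are computed on pairwise-complete rows, the
  matrix is smoothed to positive semidefiniteness, and the first principal
  component defines the composite.

Pairwise-complete correlation matrices are routinely indefinite, so the PCA
is run on a repaired matrix. The repair is the conventional eigenvalue clip:
eigenvalues are floored at `1e-6`, the matrix is rebuilt and rescaled to
unit diagonal. The operation is idempotent (up to the rescaling tolerance)
and leaves PSD inputs untouched; both properties are tested.

Eigenvector signs are arbitrary, so the component is **anchored**: the DAT1
9-repeat loading is constrained positive, which reproduces the mixed-sign
loading pattern expected for these polymorphisms (e.g. a negative Taq1A A1
loading coexisting with a positive DAT1 loading). Population **scores** are
the loading-weighted sum of z-scored frequencies with weights renormalised
over the items a population actually has (at least 5 of 9 required);
compared with regression-method factor scores this choice is robust to
missing cells, strictly monotone in every oriented frequency, and needs no
covariance inverse. It is deliberately exposed as a separate function so the
scoring rule can be swapped. Scores are reported raw and linearly rescaled
to 0–100 (`scale_0_100()`), where 0/100 are the lowest/highest *observed*
populations.

Two diagnostics mirror the published analysis: **composite reliability** as
standardized Cronbach's alpha `k r / (1 + (k-1) r)` computed from the mean
inter-item correlation after reflecting negatively loaded items, and
**cross-level congruence** — Tucker's phi between loading vectors obtained
at the sample level (one row per literature sample) and at the population
level. Phi is reported per component with signs aligned, since component
orientation is arbitrary on each side. Alpha is computed on the smoothed
matrix, the same matrix the PCA consumes.

## Climatic demand

`climatic_demand()` scores a population's thermal stress as the sum of
absolute deviations from 22 °C of four values: lowest and highest
temperatures of the coldest month and of the hottest month. The measure is
nonnegative, zero only at the optimum, and weakly increasing as any
temperature moves away from 22 °C on its own side. No latitude adjustment
is applied — unadjusted deviations are the more conservative choice for
climate effects.

## The moderated regression engine

`fit_moderated()` is ordinary least squares on **mean-centred** variables:
the reduced model contains the centred index, the centred demand and any
centred covariates / treatment-coded dummies; the full model adds their
product. Reporting follows the incremental logic:

* the variance partition `R2_full = R2_main + delta_R2` holds exactly;
* the interaction's incremental F is
  `delta_F = delta_R2 / ((1 - R2_full) / (n - p_full))` on
  `(1, n - p_full)` df, which equals the squared t of the product term (a
  tested internal identity);
* p values are reported two-sided and one-sided; the one-sided value uses
  the a priori direction of the hypothesis (positive interaction for
  approach traits such as Extraversion, negative for Neuroticism) and is
  half the two-sided p when the estimate's sign matches, its complement
  otherwise;
* **simple slopes** are probed at plus/minus one SD of the centred
  moderator (SD computed over the model's complete cases), with the delta
  method SE `sqrt(var b1 + z0^2 var b3 + 2 z0 cov(b1, b3))` — identical to
  refitting with the moderator recentred at the probe, which is how the
  tests validate it;
* coefficients are also reported with **standardized predictors**
  (`standardize = TRUE`; the outcome stays on its own scale), since
  published coefficient tables of this kind do not always state the
  predictor scale.

`bootstrap_interaction()` resamples populations — the analysis's
observation unit — with replacement, refits the full design, and reports a
percentile CI and the sign-based two-tailed bootstrap p. Centring and dummy
coding are done once on the original data; a resample whose design is rank
deficient (e.g. a dummy level vanishes) is redrawn and counted, capped at
ten times the requested B. The resampling is fully determined by its seed.

`hierarchical_controls()` enters ordered blocks and reports each block's
incremental R-squared and F (via `anova()` on the nested fits); the
increments sum exactly to the final R-squared. The two published control
orders are supported directly: wealth + parasite stress before the genetic
terms, and the climate-economic competitor (demand, wealth and their
product) before the dopamine terms.

`outlier_screen()` computes squared Mahalanobis distances from the
multivariate centroid, refers them to a chi-square with as many df as
variables, and flags rows at Bonferroni-adjusted p < 0.05.
`adjust_pvalues()` defaults to Bonferroni. The published analysis names
neither its multivariate outlier test nor its multiple-testing adjustment;
both choices here are the field's defaults and are isolated behind their
own functions so they can be replaced.

## The synthetic-data generator

`simulate_dataset()` emulates the data structure the analysis assumes:

* each population draws a latent dopamine factor `u ~ N(0, latent_sd^2)`;
  its true frequency on polymorphism j is
  `plogis(qlogis(base_freq[j]) + loading[j] * u)` with the published
  mixed-sign loadings as defaults, so the one-factor, mixed-sign
  correlation structure is built in;
* each population contributes 2–12 literature samples of 50–400
  participants; observed frequencies add binomial sampling noise
  (`Binomial(2N, p) / 2N`, attenuated by `freq_noise_sd` in `[0, 1]`; 0
  switches noise off entirely, which is what makes exact end-to-end
  identities testable). Samples report the canonical or the complementary
  allele at random, so the orientation step is always exercised;
* four monthly temperature extremes are constructed so the demand formula
  recovers a target drawn uniformly over `climate_range` (10–90 °C-sum by
  default);
* the generator's **true index** is this package's own index construction
  applied to the noise-free frequency matrix, scaled 0–100 — so "truth" is
  defined on exactly the scale the pipeline estimates; trait means then
  follow `Y = b0 + b1 DA + b2 CD + b3 DA CD + e` on the mean-centred true
  index and demand, one independent noise replicate per instrument (three
  by default, mirroring the three personality inventories);
* wealth and parasite stress are linear combinations of the standardized
  demand and index chosen to echo the correlation pattern reported for
  national wealth and historical pathogen prevalence (about +0.4 and −0.74
  with demand, −0.67 with each other); continents are four contiguous
  blocks of the latent ranking, so continent dummies genuinely absorb
  population structure.

Default conditions: 40 populations (the published trait overlaps span
27–38 nations), `beta = (50, 1.5, 1.0, 0.8)` and `trait_noise_sd = 5` —
the conditions under which parameter recovery and test size are asserted —
and full binomial sampling noise.

**What the generator does not emulate.** Real population frequency data are
noisier at the population level than a pure one-factor model: the synthetic
first component explains nearly all variance and the composite alpha
approaches 1, whereas the published index reports 47% and alpha = 0.85.
Linkage, Hardy–Weinberg structure, item-level questionnaire noise,
duplicate-study contamination and spatial autocorrelation of nations are
all out of scope. Passing tests therefore demonstrate that the *machinery*
is correct (estimators recover generating parameters, tests hold their
size, congruence diagnostics behave), not that real data meet the model's
assumptions.

## Numerical and design choices

* Correlations require at least 3 complete pairs per variable pair and
  error on zero-variance columns; estimates are clamped to `[-1, 1]`.
* PSD floor `1e-6`; PSD acceptance for the PCA at `-1e-8`; the trace
  identity (eigenvalues sum to k) is tested at `1e-8`.
* Perfect fits (noiseless data, `R2 = 1`) report an infinite incremental F
  with p = 0 rather than failing, so noiseless identity tests can run
  through the standard path; `delta_f()` itself enforces `R2 < 1`.
* Dummy reference level: alphabetically first, deterministic.
* Bootstrap CI: plain percentile quantiles at the requested level.
* Every pipeline artifact embeds an MD5 hash of the run configuration plus
  the seed; rerunning from written intermediate CSVs reproduces the
  in-memory run (tested).
* All randomness is locally seeded: generator and bootstrap restore the
  caller's RNG state.

Problem sizes used in the test suite were chosen to make the checks sharp
but cheap: 500 Monte-Carlo replicates for recovery and size (binomial 99%
band around the nominal 0.05), 200 replicates for bootstrap null coverage
at B = 400, and 40-population datasets throughout — the published study's
own order of magnitude.

## Worked example

```{r, eval = FALSE}
run <- run_pipeline(list(
  seed = 7,
  synthetic = list(),                 # default study conditions
  analysis = list(bootstrap = 1000, controls = TRUE)))
print(run)
run$index$phi          # cross-level Tucker congruence
run$summary            # Table-style report, one row per instrument
```

## Known limitations

* The scoring rule (renormalised loading-weighted z composite) and the
  reliability convention (alpha on the smoothed, reflected correlation
  matrix) are explicit choices where the published description is silent;
  both are isolated functions and can be swapped.
* Only the first component feeds the index; additional components are
  reported (eigenvalues, congruence) but unused.
* One generating coefficient vector is shared by all instruments; the
  generator cannot express instrument-specific effect sizes.
* No mixed-effects or spatial modelling: populations enter as independent
  observations, as in the published analysis.
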