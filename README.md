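# genoclim

Population-level gene-by-environment analysis: does a composite index of
dopaminergic gene-system function predict national personality trait means
only under high climatic stress?

Cross-national differences in Extraversion and Neuroticism have been linked
to phenotypic plasticity under thermal stress. The hypothesis is a classic
GxE interaction at the population scale: in demanding climates (very hot or
very cold), populations whose dopamine transporter/receptor genes suggest a
more efficient reward system shift towards behavioural approach traits,
while in temperate climates the genotypes barely differentiate. genoclim
implements that analysis as a reusable, fully tested R pipeline, with a
synthetic-data generator standing in for the literature-curated allele
frequencies and the proprietary trait inventories.

## What it computes

**Gene-system index.** From sample-level frequencies of nine dopaminergic
polymorphisms (DAT1 40-bp VNTR as 9R carrier frequency, six DRD2 SNPs, DRD3
Ser9Gly, DRD4 C-521T), oriented to canonical alleles and aggregated per
population by the sample-size-weighted mean
`f_p = sum(n_i f_i) / sum(n_i)`, the package builds a composite via
principal components of the PSD-smoothed pairwise correlation matrix.
Population scores are loading-weighted sums of z-scored frequencies
(weights renormalised over available items) rescaled to 0–100. Diagnostics:
standardized Cronbach's alpha `k r / (1 + (k-1) r)`, and Tucker's
congruence `phi = sum(x y) / sqrt(sum(x^2) sum(y^2))` between sample-level
and population-level components.

**Climatic demand.** `CD = sum_{4 temps} |T - 22 °C|` over the lowest and
highest temperatures of the coldest and the hottest month.

**Moderated regression.** OLS on mean-centred variables,
`Y = b0 + b1 DA + b2 CD + b3 DA·CD (+ covariates, continent dummies)`,
reporting the R² partition (`R²_full = R²_main + ΔR²`), the interaction's
incremental `ΔF = ΔR² / ((1 - R²_full)/(n - p))` on `(1, n - p)` df,
one-sided p under the a priori direction, simple slopes at ±1 SD of CD with
delta-method SEs, a percentile bootstrap over populations for `b3`,
hierarchical control models (wealth + parasite stress; the
climate-economic `CD×wealth` competitor), a Mahalanobis/chi-square outlier
screen, and Bonferroni adjustment.

## Worked example

```r
library(genoclim)
run <- run_pipeline(list(seed = 7, synthetic = list(),
                         analysis = list(bootstrap = 1000)))
print(run$index)
```

```
Gene-system index over 9 polymorphisms, 40 populations scored
  PC1 eigenvalue 8.88 (99% of variance); PC1-3 together 100%
  reliability: alpha = 1.00 (mean inter-item r = 0.99)
  cross-level Tucker phi: 1.00, 0.84, 0.78
  oriented PC1 loadings:
rs28363170  rs1800497  rs1079597  rs1800498     rs6275     rs6277  rs1799732
      0.99      -0.99      -1.00       1.00       0.99      -1.00       0.98
    rs6280  rs1800955
      1.00       0.99
```

The synthetic populations share one latent dopamine factor, so the first
component dominates (cleaner than real data, where it explains ~47%), its
cross-level congruence is 1.00, and the mixed loading signs follow the
anchoring convention (DAT1 9R positive). The fitted interaction model for
one instrument:

```r
print(run$fits$NEO$raw)
```

```
Moderated regression (n = 40, direction = positive)
              term estimate     se        t p_two p_one
       (Intercept)  48.4993 2.4165  20.0699     0     0
          dopamine   1.7153 0.0914  18.7665     0     0
            demand   1.3069 0.1020  12.8094     0     0
 dopamine_x_demand   0.7953 0.0038 207.3745     0     0
R2: main 0.0280 + interaction 0.9712 = full 0.9992
Delta-F(1, 36) = 43004.17, p = 0.0000; model F(3, 36) = 14747.78
Simple slopes:
    at       z0    slope     se         t df p_one p_two
 -1 SD -24.1194 -17.4668 0.1221 -143.0085 36     1     0
 +1 SD  24.1194  20.8975 0.1375  151.9884 36     0     0
```

The generator's interaction coefficient was 0.8; the fit recovers 0.795
with a tight bootstrap CI (`run$summary$boot_ci_low/high`), and the simple
slopes show the signature pattern: the gene index predicts the trait
strongly at +1 SD of climatic demand and the slope reverses/vanishes at
−1 SD (here the main-effect structure makes it negative).

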