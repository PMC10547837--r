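---
title: "Landscape versus environment: methods behind richscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape versus environment: methods behind richscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richscape)
```

## The question the package addresses

Urban landscapes retain vertebrate diversity to very different degrees, and
two families of explanations compete: *landscape factors* — how much of each
land-use class a landscape contains (composition) and how the classes are
arranged (configuration) — and *environmental factors* — climate, topography,
and latitude. `richscape` implements the full analysis chain needed to weigh
the two: class-level landscape metrics from categorical land-use rasters,
assembly of a per-landscape predictor table, collinearity pruning, best-subset
Poisson regression, and adjusted-R² variation partitioning, with cross-group
comparison of the resulting fractions. A neutral-landscape synthetic module
generates all inputs from a known model, so every stage can be validated
quantitatively without any GIS download.

## Landscape metrics

All metrics operate on an integer-coded grid with square cells of known side
length (meters); code 0 is background/nodata. A *patch* is a maximal connected
set of same-class cells. For class $l$ with patches $p$:

* **Class area** $ca_l = \sum_p a_{p,l}$ (m²), where $a_{p,l}$ is cell count
  times cell area.
* **Edge sum** $es_{l,m}$: the number of 4-neighbor cell faces separating
  classes $l$ and $m$, times the cell size (m).
* **Patch cohesion**
  $coh_l = \bigl[1 - \tfrac{\sum_p P_{p,l}}{\sum_p P_{p,l}\sqrt{c_{p,l}}}\bigr]
  \bigl[1 - \tfrac{1}{\sqrt{C_r}}\bigr]^{-1} \times 100$,
  with $P_{p,l}$ the patch perimeter in cell faces, $c_{p,l}$ the patch area
  in cells, and $C_r$ the total number of grid cells (background included).
  A class filling the grid scores exactly 100; a single-cell patch scores 0.
* **Edge density** $ed_l = \sum_m es_{l,m} / A \times 10^4$ (m/ha), $A$ the
  total landscape area in m².
* **Largest patch index** $LPI = \max_p a_{p,l} / A \times 100$ (%).

Three conventions are deliberate choices, exposed as arguments:

* **Patch connectivity defaults to 8** (the FRAGSTATS convention) and is
  configurable to 4; perimeter and edge faces are always counted on the
  4-neighborhood, because a perimeter is made of cell *faces*, not corners.
* **The boundary rule defaults to inclusive**: grid-boundary faces and faces
  against background count toward a class's edge total (and hence edge
  density). Interior-only counting is available by flag, since other tools
  default to it.
* $c_{p,l}$ (patch area in cells) is used in both positions of the cohesion
  numerator and denominator; this makes the index dimensionless and bounded,
  matching the standard COHESION definition.

Every metric is checked in the test suite against an independent brute-force
oracle (hand-looped flood fill and exhaustive face enumeration) on hundreds
of random small grids, under both connectivities and both boundary rules.

## From metrics to models

`assemble_predictors()` inner-joins metrics, environmental covariates, and
richness counts on the landscape id, tags every predictor as landscape or
environmental, stores latitude as absolute latitude, and standardizes
predictors to mean 0 / variance 1 *within each analysis group*.
Standardization makes coefficients mutually comparable in magnitude across
predictors, which is how cross-group model tables are usually read; it is
configurable off. Rows with missing values are dropped and logged, never
imputed; zero-variance predictors are dropped with a warning.

`prune_collinear()` removes predictors stepwise until no retained pair has
Pearson $|r| > 0.7$. Which member of an offending pair to drop is not
determined by the threshold alone, so the rule is fixed for reproducibility:
the member with the larger mean absolute correlation against all remaining
predictors goes; ties drop the later column in canonical order. The procedure
is deterministic and the post-condition (max $|r| \le 0.7$) is asserted in
tests.

`fit_poisson()` fits $\log E(Y) = \beta_0 + \sum_i \beta_i x_i$ by IRLS
(relative deviance tolerance $10^{-8}$, at most 100 iterations), and reports
a deviance pseudo-R², $R^2_{dev} = 1 - D_{res}/D_{null}$, with an
Ezekiel-style adjustment
$R^2_{adj} = 1 - (1 - R^2_{dev})\,(n-1)/(n-k-1)$. This is the most common
GLM analogue of the adjusted R² and makes the model tables and the variation
partition mutually consistent, since both use the same quantity. Plain
Poisson is fitted throughout — no overdispersion correction — because the
downstream partition is defined on deviance explained; a dispersion
diagnostic can be computed from the reported deviance and degrees of freedom.

`best_subset()` enumerates *every* subset of the candidate predictors
(including the empty model) and returns the fit minimizing an information
criterion — BIC by default, AIC by flag. BIC is the default because subset
selection precedes variation partitioning here, and a conservative criterion
keeps spurious predictors out of both matrices. Ties break toward fewer
predictors, then lexicographically. Enumeration is capped at 20 candidates
($2^{20}$ fits) unless a subset-size cap is given. Non-converged or
boundary fits are excluded from the ranking. The enumeration is cross-checked
in tests against a naive double-loop over `stats::glm` + `BIC()`.

## Variation partitioning

With the selected predictors split back into the landscape set and the
environmental set, three fits (landscape-only, environment-only, union) give
adjusted pseudo-R² values $R^2_L$, $R^2_E$, $R^2_{LE}$, and the fractions

* unique landscape $a = R^2_{LE} - R^2_E$,
* shared $b = R^2_L + R^2_E - R^2_{LE}$,
* unique environment $c = R^2_{LE} - R^2_L$,
* unexplained $d = 1 - R^2_{LE}$,

which sum to one by construction. Adjusted-R² partitions can legitimately
produce small negative fractions; these are *reported as computed* with a
warning flag, because truncating at zero would silently break the
sum-to-one identity that the tests and downstream comparisons rely on. If
selection leaves one set empty the partition degenerates to a single-set R²;
this is flagged, never silent. The two calibration facts the tests verify:
independently generated predictor sets give a shared fraction centered on
zero, and a common latent factor loading on both sets makes it positive.

`partition_all()` applies the chain per (group × taxon). Groups below a
minimum sample size (default 30) are skipped and logged: with up to ~18
candidate predictors, exhaustive selection on a handful of landscapes is
meaningless, which is why very small realms are excluded rather than fitted.

## Group comparison

`summarize_richness()` computes Tukey boxplot statistics with
linear-interpolation quantiles (R type 7) and 1.5·IQR fences; outliers are
reported by landscape id. `compare_fractions()` pools a chosen fraction over
the (group × taxon) cells on each side of a contrast, then runs a one-way
ANOVA across sides plus pairwise two-sided t-tests with a pooled SD (so a
two-side comparison reproduces the classical $F = t^2$ identity, asserted in
tests). Pooling rather than pairing by taxon is a deliberate choice: the
fraction values on each side are treated as exchangeable replicates of the
realm-level quantity. Pairwise p-values are Holm-adjusted by default
("none" is available); Holm is conservative and makes no independence
assumptions.

## The synthetic study generator

`generate_dataset()` emulates the inputs of a global urban-vertebrate study
without any of its data:

* **Land use**: a modified-random-clusters neutral landscape. Bernoulli seed
  cells at the *aggregation* probability are clustered (4-connectivity),
  clusters are assigned to classes chasing the target proportions (largest
  remaining deficit first, targets scaled to the seeded-cell total), and the
  remaining cells adopt the class of a random assigned 8-neighbor,
  iteratively. Aggregation 0 degenerates to i.i.d. per-cell draws;
  values near 1 give large contiguous blocks. Percolation occasionally
  yields one giant cluster that no whole-cluster assignment can balance, so
  draws whose realized composition deviates more than 5 percentage points
  from target (or miss a positive-target class) are redrawn from derived
  seeds, at most 25 times. This keeps composition on target without
  sacrificing determinism.
* **Covariates**: latitude from a per-group belt; temperature and
  precipitation means decline with absolute latitude while their
  seasonalities rise with it; elevation is log-normal with a non-negative
  CV. A latent factor with configurable loading shifts both forest cover
  and climate, inducing a landscape–environment correlation (and hence a
  positive shared fraction) when the loading is non-zero.
* **Richness**: $Y \sim \text{Poisson}(\exp(\beta_0 + \sum \beta_i x_i))$
  per taxon, with coefficients on the standardized predictor scale, drawn
  *after* within-group standardization so that fitted and generative
  coefficients are directly comparable. Taxa are independent given the
  predictors, mirroring analyses that model taxa separately.

Default conditions emulate the study design this pipeline targets: six
realm-like groups totalling 505 landscapes (one group of 7, below the
modelling minimum, exercising the skip path), 30 m cells,
forest/wetland/built-up/other classes at proportions 0.25/0.05/0.35/0.25
with aggregation 0.55, and realm-plausible intercepts (log mean counts
near 5.0 for mammals, 5.8 for birds, 2.3 for amphibians) with standardized
effects of magnitude 0.3–1.0 — the range in which published urban-richness
model tables sit. The default candidate list (class area, cohesion, edge
density of the three named habitat classes, plus the forest/built-up edge
sum and seven covariates) matches the ~18-candidate scale such studies use;
LPI is computed and reported but not used as a predictor.

Two presets, `synth_config_regime("environment")` and
`synth_config_regime("landscape")`, put the generative weight on one factor
set (large coefficients on climate/latitude versus on forest amount and
configuration, latent loading 0). They represent the qualitative contrast
between temperate realms, where climate dominates richness variation, and
tropical fast-urbanizing realms, where landscape structure carries more of
it; the pipeline must rank the unique fractions accordingly, and the
replicated tests check it does in both directions.

What the generator does *not* emulate: spatially autocorrelated climate
surfaces, species range geometry, observation error in richness counts, and
spatial autocorrelation among landscapes. Passing tests therefore show the
*pipeline* is correct and well calibrated under a known generative model —
not that any particular empirical fraction estimate is right.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: cohesion of an absent class or a
one-cell landscape is `NA` (its normalizer is undefined), an empty landscape
has no LPI, a class missing from one landscape contributes zero class area
with a warning, and correlation pruning refuses fewer than 3 rows. All
randomness flows through explicit integer seeds; derived per-landscape seeds
stay below $2^{31}$.

The replicated simulation studies run at sizes chosen to make their targets
sharp while keeping a full check runnable on a laptop: parameter recovery
and partition calibration at $n = 1000$ observations with 50 replicates;
regime discrimination with 60 landscapes per group on 32×32 grids, 40
replicates per regime in the tests and 20 in the acceptance script; the
full synthetic study at 32×32. Grid size affects only the sampling noise of
the metrics, not any tested identity.

## Known limitations

* Exhaustive enumeration is exponential; beyond ~15 candidates a run is
  noticeably slow in R, and the hard cap is 20.
* The GeoTIFF reader handles plain single-band integer TIFFs and requires
  an explicit cell size (no geotransform parsing); ESRI ASCII grids are the
  fully supported interchange format.
* No spatial autocorrelation handling, no overdispersion modelling, and no
  significance testing of individual fractions by permutation.
* Adjusted-R² fractions can be slightly negative; consumers should treat
  values within a few hundredths of zero as zero.
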