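# richscape

Quantifying how much of the variation in urban vertebrate species richness
is explained by **landscape structure** (the composition and spatial
configuration of land-use classes) versus the **abiotic environment**
(climate, topography, latitude), across groups of landscapes such as
biogeographic realms.

`richscape` is aimed at landscape ecologists and macroecologists who have —
or want to simulate — a set of categorical land-use rasters (one per
landscape/city), a table of environmental covariates, and per-landscape
richness counts for one or more taxa. It implements the full chain as
composable, pipe-friendly functions:

1. **Landscape metrics** on categorical rasters: class area
   $ca_l = \sum_p a_{p,l}$, pairwise edge length $es_{l,m}$, patch cohesion
   $coh_l = \bigl[1-\tfrac{\sum_p P_{p,l}}{\sum_p P_{p,l}\sqrt{c_{p,l}}}\bigr]\bigl[1-\tfrac{1}{\sqrt{C_r}}\bigr]^{-1}\times 100$,
   edge density $ed_l = \sum_m es_{l,m}/A \times 10^4$ (m/ha), and the
   largest patch index $LPI$ (%), with configurable 4/8 patch connectivity
   and boundary rules.
2. **Predictor assembly**: join metrics, covariates, and counts; absolute
   latitude; within-group standardization; stepwise pruning of collinear
   predictors (Pearson $|r| > 0.7$).
3. **Best-subset Poisson regression**: exhaustive enumeration of predictor
   subsets for $\log E(Y) = \beta_0 + \sum_i \beta_i x_i$ under BIC (or
   AIC), with significance-coded coefficient tables and an adjusted
   deviance pseudo-R², $R^2_{adj} = 1-(1-R^2_{dev})(n-1)/(n-k-1)$.
4. **Variation partitioning**: unique-landscape, unique-environment,
   shared, and unexplained fractions from the adjusted R² of three nested
   fits; the four fractions sum to one by construction.
5. **Group comparison**: Tukey boxplot summaries with outlier ids, and
   ANOVA + pairwise t-tests contrasting fractions between sets of groups.
6. **Synthetic data**: a modified-random-clusters neutral landscape
   generator plus correlated covariates and Poisson richness from known
   coefficients, so the whole pipeline is testable end to end without GIS
   data.

Results are tibbles; fitted objects support `tidy()`/`glance()`, and
`autoplot()`/`plot_richness_box()` provide ggplot2 graphics.

## Worked example

Metrics on a tiny hand-made raster (30 m cells):

```r
library(richscape)

r <- cat_raster(matrix(c(1L,1L,2L,1L,3L,3L,2L,3L,3L), 3, 3), cell_size = 30)
label_patches(r, connectivity = 8)
#> # A tibble: 4 × 5
#>   class patch cell_count  area perimeter_cells
#> 1     1     1          3  2700               8
#> 2     2     1          1   900               4
#> 3     2     2          1   900               4
#> 4     3     1          4  3600               8

compute_metrics(r, class_map = c(Forest = 1L, Builtup = 3L))
#> # A tibble: 8 × 3
#>   metric class           value
#> 1 ca     Forest         2700
#> 2 coh    Forest           63.4
#> 3 ed     Forest          296.
#> 4 ca     Builtup        3600
#> 5 coh    Builtup          75
#> 6 ed     Builtup         296.
#> 7 es     Forest.Builtup   60
#> 8 lpi    <NA>             44.4
```

Class 1 ("Forest") covers 3 cells = 2700 m²; its single patch exposes 8
cell faces; the largest patch anywhere (class 3, 4 cells) holds 44.4 % of
the landscape.

A complete synthetic study in the landscape-dominated regime — generate 60
landscapes, compute metrics, prune, select, partition:

```r
cfg   <- synth_config_regime("landscape", n = 60, dim = 32)
d     <- generate_dataset(cfg, seed = 2024)
parts <- partition_all(d$table, min_n = 30)
tidy(parts)[, c("group","taxon","r2adj_full","frac_unique_landscape",
                "frac_shared","frac_unique_environment","frac_unexplained")]
#>   group  taxon r2adj_full frac_unique_landscape frac_shared
#> 1    G1 mammal      0.943                 0.936     -0.0127
#>   frac_unique_environment frac_unexplained
#> 1                  0.0192           0.0573
```

The generating model put its weight on forest amount and configuration, and
the partition recovers that: 93.6 % of richness variation is unique to the
landscape matrix against 1.9 % unique to the environment (the small
negative shared fraction is a normal feature of adjusted-R² partitions and
is reported as computed). Swapping in
`synth_config_regime("environment")` reverses the ranking.

`run_pipeline()` wraps the same chain (synthetic or file-based input, YAML
config) and writes metrics, model tables, partition and comparison CSVs,
plus a JSON run manifest.

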