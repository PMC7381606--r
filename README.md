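# biomeclock

Dating the origin and latitudinal spread of a biome from the divergence
times of its sister species.

## The problem

Fossil and isotopic records of when open, grassy biomes such as African
savanna replaced forest are sparse and patchy in space. A dated phylogeny
of the regional flora offers a complementary clock: when two species that
are each other's closest relatives (**a sister pair**, a "cherry" on the
tree) both live in the same biome, their divergence most plausibly
happened inside it — no ancestral-state reconstruction needed. Each such
divergence time is then a *minimum* age for the biome where the pair
occurs, and the *oldest* divergences, traced across latitude, record how
the biome spread.

`biomeclock` implements this procedure end to end:

1. **Sister pairs** — enumerate strictly bifurcating cherries whose two
   tips share a biome label, with node ages (Ma) and optional HPD
   intervals; apply age caps and named exclusions as configuration.
2. **Latitudinal gradient** — for each pair, the mean of the two species'
   mean latitudes (single-species fallback; ranges truncated north of a
   cutoff). Because only the oldest splits are informative, the model is a
   τ-quantile regression (τ = 0.90, 0.95 — the top 10% / 5% of oldest
   ages):

   `Q_age(τ | lat) = β₀ + β₁ · lat`

   The estimator minimizes the check loss
   `Σ ρ_τ(y_i − β₀ − β₁ x_i)`, `ρ_τ(u) = u(τ − 1[u<0])`, solved exactly
   (vertex solution of the underlying linear program). Coefficient
   uncertainty comes from the **Markov chain marginal bootstrap**
   (999 resamples by default), with t = slope/s.e. on n − 2 df.
   `predict_biome_age()` converts the fitted line into an establishment
   age at any latitude.
3. **Phylogenetic signal** — biome membership as a binary trait, scored
   with the **D-statistic**: the observed sum of sister-clade differences
   scaled between its expectations under tip-shuffle (D = 1, random) and
   threshold-Brownian (D = 0, conserved) nulls, each with permutation
   p-values (1000 permutations by default).
4. **Geographic projection** — pair ages overlaid on a 0.1° grid (mean
   observed age, species richness, and regression-predicted age per
   cell), written as ESRI ASCII rasters plus a long CSV.
5. **Synthetic data** — birth–death trees, threshold-Brownian biome
   labels, and a uniform-ceiling age model whose conditional τ-quantile
   is exactly τ(β₀ + β₁·lat), giving every stage a closed-form
   parameter-recovery target.

Latitudes are signed decimal degrees (south negative) throughout; use
`report_slope(fit, "degrees_south")` for the positive-southward
convention.

## Worked example

```r
library(biomeclock)

scenario <- synthetic_scenario(seed = 42, n_tips = 400, prevalence = 0.4,
                               beta0 = 16, beta1 = 0.4)
data <- simulate_dataset(scenario)     # tree, labels, 46 savanna pairs, ranges

fit <- fit_age_gradient(data$pairs, tau = 0.90, n_resamples = 999, seed = 42)
fit
#> Quantile regression (tau = 0.90, n = 46)
#>   intercept 15.08, slope 0.396 (check loss 22.629)
#>   MCMB (999 resamples): slope s.e. 0.1003, t = 3.95, p = 0.000281
```

The generating truth says the 0.90-quantile line has slope
τ·β₁ = 0.36 and intercept τ·β₀ = 14.4; the fit recovers both within its
bootstrap uncertainty, and the MCMB t-test correctly rejects a flat
gradient. Predicting establishment ages:

```r
predict_biome_age(fit, c(-1, -30))
#>   latitude age_ma lower upper extrapolated
#> 1       -1  14.7   8.95 16.2  FALSE
#> 2      -30   3.20  2.91  9.31 TRUE
```

i.e. the biome is estimated to be ~15 Ma old near the equator but only
~3 Ma old at 30° S — the southward-expansion signature the method is
designed to detect. Phylogenetic signal of the labels (simulated as
Brownian-threshold, so D should be near 0):

```r
biome_dstat(data$tree, data$species, "savanna", n_perm = 1000, seed = 42)
#> D-statistic: D = 0.105 (d_obs = 82.103, prevalence 0.40, 1000 permutations)
#>   p(random null, d <= obs) = 0.0000; p(Brownian null, d >= obs) = 0.1890
```

Projection onto a grid:

```r
grid <- project_ages(data$pairs, data$cells, resolution = 0.5) |>
  predict_age_map(fit)           # 1416 cells with mean_age, richness,
autoplot(grid, "mean_age")       # predicted_age layers
```

`run_pipeline(pipeline_config(...))` chains all stages and writes a run
directory (`pairs.csv`, per-τ fit JSONs, `dstat.json`, grid rasters,
`summary.json`, `config.lock.json`), deterministic given its seed. With a
real dated Newick tree, a `species,biome` table and per-species presence
cells, the same calls reproduce a full empirical analysis; named
outlier pairs and a 25 Ma age cap can be supplied via `filter_pairs()` or
the pipeline config.

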