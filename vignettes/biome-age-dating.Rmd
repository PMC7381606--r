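---
title: "Dating biome origin and spread from sister-species divergences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating biome origin and spread from sister-species divergences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomeclock)
```

## The model and its assumptions

The package estimates the age of a biome, and how that age varies with
latitude, from a dated ultrametric phylogeny of the regional flora and a
biome classification of its species. The reasoning chain is:

1. **Within-biome sister pairs date the biome from below.** If two tip
   species are each other's sole closest relatives (a cherry) and both are
   classified in the same biome, the parsimonious reading is that their
   divergence happened within that biome. The divergence time of the pair
   is then a *minimum* age for the biome where the pair occurs: the biome
   must be at least that old for the split to have happened inside it.
   Restricting attention to cherries avoids reconstructing ancestral biome
   states, which is the step this design deliberately sidesteps; the cost
   is that mixed cherries and same-biome tips under polytomies carry no
   usable signal and are excluded (the latter are counted in a report).
   Downstream code treats the resulting ages strictly as lower bounds —
   nothing in the package ever reports a biome age as an upper bound.

2. **Only the oldest splits are informative about first spread.** A biome
   present at some latitude for `A` Ma can host splits of any age in
   `(0, A]`; young splits say nothing about `A`. The natural regression is
   therefore through an upper conditional quantile of age given latitude:
   `Q_age(τ | lat) = β₀ + β₁·lat` with τ = 0.90 or 0.95. This is a
   modelling assumption, not a theorem: it holds exactly when splits
   accumulate uniformly in time under a latitude-linear ceiling (the
   synthetic generator's construction) and approximately whenever split
   density near the ceiling is latitude-stable.

3. **Biome membership must be phylogenetically conserved for (1) to make
   sense.** If species hopped biomes freely, a shared label would say
   little about where a divergence happened. The D-statistic quantifies
   this: the observed sum of sister-clade differences of the binary
   membership trait is scaled between its expectation under random tip
   shuffles (D = 1) and under a threshold-Brownian model (D = 0). Low D
   justifies attributing divergences to the shared biome.

Two further standing assumptions: present-day ranges approximate the
latitudes where lineages diverged (so large range shifts since divergence
bias the gradient), and divergence times from the chronogram are taken at
face value, with HPD intervals propagated only as a bracketing
sensitivity (below).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| τ (quantile level) | — | 0.90 and 0.95 | top 10%/5% of oldest ages; both fitted so their agreement can be checked |
| truncation latitude | signed degrees | 0 (equator) | ranges north of the cutoff are dropped before averaging; +15 is the shipped sensitivity setting for sparsely sampled northern ranges |
| max pair age | Ma | none (25 in sensitivity mode) | removes ancient splits that predate any plausible biome age and act as leverage points |
| MCMB resamples | — | 999 | chain length for coefficient uncertainty; first 10% discarded as burn-in |
| D permutations | — | 1000 | replicates per null distribution |
| grid resolution | degrees | 0.1 | cell size of the projection grid, half-open cells anchored at (0, 0) |

Latitude is handled internally as signed decimal degrees, south negative.
With that convention a biome that is older toward the equator and younger
southward has a *positive* slope (age rises as latitude increases from
−30° to 0°). Maps and figures that use a "degrees south" axis flip the
sign; `report_slope()` performs the flip and records which convention
produced any reported number, and grids refuse to accept a fit whose
convention does not match theirs.

## The quantile-regression estimator

The τ-quantile line minimizes the check loss
`Σ ρ_τ(y_i − a − b·x_i)`. For the two-parameter model an optimum of this
piecewise-linear convex objective lies at a vertex — a line through at
least two data points. The solver exploits this directly: starting from
the τ-order statistic of `y`, it repeatedly "rotates" the current line
around one of its active points, solving each rotation exactly as a
weighted median over candidate slopes to the other points, and stops when
neither active point admits an improving rotation. That stopping condition
checks the directional derivative along all four edge directions at the
vertex, which certifies global optimality for a convex piecewise-linear
function of two variables (in non-degenerate position). Ties among optima
are possible with duplicated points; they are broken deterministically
(stable sort, smallest breakpoint index) and the achieved check loss is
reported so ties can be audited. The test suite verifies the solver
against an exhaustive all-pairs enumeration on every random instance with
n ≤ 60, and against closed-form recovery targets at n = 2000.

An alternative reading of "regression on the top 10% of oldest ages" —
ordinary least squares through the oldest decile of pairs — is provided as
`fit_age_gradient(..., method = "oldest_subset")`. It conditions on the
marginal age distribution rather than the conditional one, so it is not
the canonical estimator here, but it is useful as a sensitivity check; the
two modes agree in sign whenever the gradient is real.

## MCMB uncertainty

Standard errors come from the Markov chain marginal bootstrap: a chain of
coefficient draws in which each coefficient is updated in turn by solving
its one-dimensional marginal estimating equation, with the right-hand side
a with-replacement bootstrap draw of the fitted score terms
`x_ij·ψ_τ(r̂_i)`, `ψ_τ(u) = τ − 1[u<0]`. Each marginal solve is a weighted
quantile and is exact. The chain runs on centered, scaled covariates —
this decorrelates the two updates and markedly improves mixing — and draws
are mapped back to the original scale. Numerical conventions: chain length
= number of resamples; the first 10% is burn-in; s.e. = standard deviation
of the retained draws; t = slope/s.e. with a two-sided p-value from
Student's t on n − 2 df (one defensible choice among bootstrap summaries;
the chain itself is stored so other summaries can be formed). A single
integer seed makes the whole chain reproducible and is recorded in the
output. Calibration is verified by simulation: with age independent of
latitude (n = 200, 500 replicates, 199 resamples), the slope t-test
rejects at the nominal 5% rate within binomial tolerance.

## HPD envelope

When the chronogram carries per-node HPD intervals, `fit_hpd_envelope()`
fits the same τ-line to the point ages, the upper bounds and the lower
bounds of exactly the same pairs. Because the three response columns are
pointwise ordered and positive, the fitted lines bracket the point-age fit
over the observed latitude range, bounding how dating uncertainty
propagates into establishment ages. The bracket deliberately mixes
per-node extremes that no single posterior tree realizes jointly, so it is
a conservative envelope, not a credible band. A posterior-sample workflow
(refitting across a sample of dated trees) would be the principled
alternative and is out of scope; the per-node annotation route was chosen
because it works with any annotated Newick file.

One orientation note: depending on whether ages are sorted ascending or
descending, the same upper-tail fit can be described as the 90th or the
10th quantile. The package always parameterizes τ as the quantile of the
age distribution (upper tail = large τ); callers using the opposite
orientation should pass 1 − τ.

## The D-statistic

Nodal estimates are obtained by averaging daughter values up the tree;
each internal node contributes the absolute difference of its daughter
estimates (mean over daughter pairs at polytomies — a documented deviation
risk versus strictly binary formulations, irrelevant on bifurcating
trees). Both nulls preserve the observed number of presences exactly: the
random null by shuffling tips, the Brownian null by simulating a
continuous trait along branches (variances proportional to branch lengths
in Ma, as given) and thresholding at the prevalence rank. Exact-count
thresholding, rather than matching prevalence in expectation, keeps change
sums comparable across replicates. Both permutation p-values are reported
(`p_random` small = more conserved than random; `p_brownian` small = less
conserved than Brownian) since the two-null logic of the statistic does
not single one out. If the null means cross (tiny trees, extreme
prevalence), D's denominator loses meaning and the result is flagged
unidentifiable rather than silently scaled.

## The synthetic generator — what it emulates and what it does not

The generator produces (i) pure-birth or birth-death trees conditioned on
a tip count, with branch lengths in Ma; (ii) biome labels from a Brownian
trait plus white noise of scale `noise_scale` (in units of the Brownian
tip s.d.) thresholded at the target prevalence — `noise_scale = 0` gives
maximal conservatism (D near 0), large values approach shuffled labels
(D near 1); and (iii) pair latitudes uniform on a span (default 30° S to
the equator) with ages drawn Uniform(0, β₀ + β₁·lat), defaults β₀ = 16 Ma
at the equator and β₁ = 0.4 Ma/degree, so predicted equatorial ages sit in
the mid-Miocene range and decline to a few Ma at 30° S — the regime the
method targets. The uniform-ceiling model was chosen because its
conditional quantiles are linear in latitude, making τ·β₁ and τ·β₀ exact
recovery targets; it is a test harness, not a biological claim. Presence
cells are scattered around the pair latitude (s.d. 1.5°, clipped to the
span so truncation does not bias the mean) with arbitrary longitudes.

What the generator does *not* emulate: realistic richness or range-size
distributions, spatial autocorrelation of ranges, range movement since
divergence, biased taxon sampling, or dating error correlated across
nodes. Passing the synthetic recovery tests therefore demonstrates that
the estimators are correct and calibrated under the stated model — not
that real data satisfy that model.

A master seed expands into per-stage seeds (`split_seed()`), so the tree,
the labels and the latitudes are independently reproducible; every
simulated dataset ships its generating parameters (`truth`).

## Numerical choices and degenerate inputs

* Name normalization: trim, collapse internal whitespace to `_`,
  case-sensitive thereafter (the Newick convention).
* Ultrametricity: tip ages within 1e-6 of tree height are clamped to
  zero; larger deviations warn (published chronograms carry rounding
  noise) with a per-tip report rather than failing.
* Tips carry degenerate `[0, 0]` HPDs; HPD annotations attach to internal
  nodes only.
* Quantile solver: see above; `n < 3`, constant `x`, or τ outside (0, 1)
  are errors; fewer than 50 MCMB resamples is an error (unstable s.e.).
* Grid cells are half-open `[k·r, (k+1)·r)`; cell indices use
  `floor(coord/res)`, so coordinates exactly on a boundary follow
  floating-point division. Pair footprints count each pair once per cell
  (union of its two species' cells), preventing double-weighting where
  the species co-occur; richness counts species, not pairs. The low
  diversity hatch mask is a configurable minimum-richness threshold
  (default 1).
* Filters are configuration, not code: the 25 Ma cap and named outlier
  exclusions are parameters (order-insensitive matching, logged
  removals), applied or not per analysis since reasonable analyses may
  apply the cap only in sensitivity mode.

## Validation scale

The shipped tests run at sizes chosen to exercise each property cleanly:
quantile-fit optimality on instances up to n = 60 against exhaustive
enumeration; slope recovery at n = 2000 over 24 replicates; type-I
calibration over 500 (gradient-free) simulations with 199-resample
chains; D calibration over 100 trees of 128 tips with 200-replicate
nulls; cherry extraction versus brute force on 200 random trees up to 120
tips. The acceptance script (`scripts/acceptance.R`) recomputes the D
calibration pair from scratch at exactly that scale.

## Known limitations

* Extinction draws sister divergences backward in time; the method is
  robust only if extinction risk does not covary jointly with latitude
  and biome.
* The gradient fit is an ordinary quantile regression: no spatial
  autocorrelation correction and no phylogenetic non-independence
  correction across pairs (pairs are disjoint cherries, which removes the
  sharpest dependence, but deeper shared history remains).
* Quantile estimates at τ = 0.95 rest on few effective observations at
  typical pair counts (~10² pairs); bootstrap intervals widen
  accordingly and should be read with the fitted `n` in mind.
* The HPD envelope brackets extremes across the dating posterior rather
  than propagating it; it overstates uncertainty by construction.
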