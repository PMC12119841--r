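---
title: "Methods: tip speciation rates, their geography, and its drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tip speciation rates, their geography, and its drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the statistics, the models, the synthetic data that exercises them, and the
numerical and design choices a maintainer would want spelled out.

## 1. Tip speciation rates

The tip-level rate proxy is the inverse equal-splits statistic (widely
called *DR*). Walking from a tip to the root, each edge contributes its
length discounted by the splits passed on the way: weight 1 for the
terminal edge, then 1/2, 1/4, ... (1/m per m-furcation). The reciprocal of
that weighted path length behaves like a recent speciation rate: species
sitting on short, recently subdivided branches score high. Internally the
whole vector is computed in one preorder pass via the recurrence
`T(child) = T(parent)/m + edge_length`, which is algebraically identical to
the per-tip path sum; the test suite checks it against an explicit
path-walk oracle to 1e-10.

Assumptions worth keeping in mind: DR is a *proxy*. It is exactly the
reciprocal of a weighted branch-length average, so it is mechanically
anti-correlated with terminal branch length ("species age");
`rate_age_correlation()` quantifies that (Spearman by default, rates being
heavy-tailed). Trees must be rooted with branch lengths in consistent time
units; zero-length terminal edges are rejected rather than producing
infinite rates.

**Aggregation over a posterior.** Rates are computed per tree and combined
per species. The default combination is the arithmetic mean; the harmonic
mean is a config option (`mean_type = "harmonic"`). The choice matters:
on pure-birth trees the *harmonic* grand mean of tip DR estimates the true
speciation rate almost unbiasedly, while the arithmetic grand mean is
upward-biased by Jensen's inequality (about 1.4x at 200 tips — a property
of the statistic, reproduced identically by an independent simulator, not
of our implementation). The calibration tests therefore use the harmonic
grand mean; per-species arithmetic means remain the default for mapping
because they preserve the heavy right tail that assemblage maxima and CVs
are meant to display. Species age is operationalised as the terminal
branch length averaged across the posterior — the other defensible reading
(per-tree ages in a per-tree correlation) is exposed by running
`rate_age_correlation()` on single-tree tables.

## 2. Assemblage surfaces

Ranges live on a regular latitude–longitude grid (degree-based, unprojected;
`make_grid()`), as sets of occupied cells. The presence–absence matrix
marks a species in every cell its range touches; cells with no species are
dropped with a count. Per-cell summaries are the arithmetic mean, the
maximum, and the coefficient of variation in percent
(100 x sample sd / mean, undefined at richness 1) of the member species'
rates. CV uses the n−1 standard deviation; the conventional 30% reading
("heterogeneous assemblage") is a display threshold, not a test.

Species are classed tropical / non-tropical by the latitudinal midpoint of
their range: the cos(latitude)-weighted mean of occupied-cell centroid
latitudes (equal-degree cells shrink poleward, so this is the area-weighted
centroid; a bounding-box midpoint is available since range tools differ).
The boundary is the tropic line at 23.44° and is inclusive — a midpoint
exactly on the line is tropical. The source convention says "between" the
tropics without fixing ties, so the tie rule is ours, documented and
configurable.

## 3. The spatial-error regression

Assemblage values are strongly spatially autocorrelated, so the latitude
gradient and the driver analysis both use a simultaneous autoregressive
error model: `y = Xβ + u`, `u = λWu + ε`, `ε ~ N(0, σ²I)`. Weights are
distance-band inverse-square (`1/d²` up to a cutoff, great-circle degrees),
row-standardised by default (the ecology-standard "W" style; raw weights
are an option since sources rarely state the style). Sites with no
neighbour within the cutoff keep an all-zero row and a warning — dropping
them would silently change n.

Estimation is profile maximum likelihood: for fixed λ, β and σ² are GLS
closed forms on the filtered system `(I−λW)y = (I−λW)Xβ + ε`, and the
concentrated log-likelihood `−n/2·log σ²(λ) + log|I−λW|` is maximised over
the stationarity interval by golden-section search (tolerance 1e-9). The
log-determinant uses the eigenvalues of W, computed once (for
row-standardised W from a symmetric base the eigenvalues are real — W is
similar to a symmetric matrix — so the symmetric solver applies; this is
exact at the few-thousand-site scale the package targets, and sparse or
Chebyshev approximations are deliberately out of scope). Coefficient
standard errors are the conditional-on-λ GLS covariance; the λ standard
error comes from the numerical curvature of the profile. AIC counts
p(coefficients incl. intercept) + 2 (λ, σ²) parameters. A dedicated test
cross-checks coefficients and log-likelihoods against an independent
direct joint-ML route (dense LU log-determinant, no profiling) to 1e-4.

**Pseudo-R².** `nagelkerke_r2()` implements the standard normalisation
`(1 − exp((2/n)(L0 − L1))) / (1 − exp((2/n)L0))` with the intercept-only
*spatial* model as null, so it reports what the predictors add beyond
space. Two caveats are documented in the function: the normaliser assumes a
likelihood bounded by 1, so when a continuous model has positive null
log-likelihood the raw Cox–Snell ratio (clamped to [0,1]) is reported
instead; and with a non-spatial null the same formula would instead report
"predictor + space" jointly — callers can pass any nested null.

**Cutoff selection.** `select_cutoff()` refits the model over a ladder of
cutoffs (default 10–100° in steps of 10) and returns the AIC-minimising
one with the full table; per-cutoff failures are recorded, not fatal.

## 4. The nonparametric state-dependent speciation test

For a binary trait, the per-state rate estimate is the mean tip DR over
tips in that state, and the statistic is `Δ = λ̂₁ − λ̂₀`. The reference
method's exact estimator internals are not restated in our source, so this
estimator is defined here and checked behaviourally (type-I error, power,
label-swap antisymmetry) rather than bitwise against another codebase.

The null distribution comes from neutral trait simulations on the *same*
tree: a symmetric two-state Markov model with transition rate calibrated as
(Fitch parsimony change count of the observed trait) / (total tree length),
floored at 1/tree-length; the root state is drawn from the observed state
frequencies. Because only tip states matter, each edge is simulated by its
exact endpoint flip probability `(1 − exp(−2qt))/2`, vectorised across
replicates. Monomorphic null draws (under which Δ is undefined) are
resampled with a capped retry. The p-value is the permutation form
`p₁ = (1 + #{Δ_null ≥ Δ_obs}) / (n_null + 1)`, doubled on the smaller tail
and capped at 1; the +1 pseudocount keeps p positive. `fisse_batch()` runs
the test per posterior tree and reports across-tree mean per-state rates,
the quantity usually quoted. Defaults (n_null = 1000 for single tests;
smaller in the pipeline) are ours — sources rarely state theirs.

## 5. Bioregion drivers

**Climate-change velocity** is the local ratio of the temporal rate of
change (|current − past| / Δt, units/yr) to the spatial gradient of the
*current* surface (units/km), in km/yr. The spatial gradient uses the 3×3
average-maximum (Horn) stencil with linearly extrapolated borders, so a
linear ramp has its exact constant gradient everywhere — which gives the
closed-form test case (1 unit/km gradient + 1 unit/kyr trend = 0.001 km/yr
exactly). Cells with zero spatial gradient have undefined velocity and are
excluded from regional means rather than capped: capping would let a few
near-flat cells dominate. Velocities are computed per past horizon against
current conditions, averaged over horizons, then combined across climate
variables by the arithmetic mean (median by flag).

**Roughness** is the 3×3 max − min of elevation (edge cells use their
available neighbours), averaged per bioregion.

**NRI** measures phylogenetic clustering of co-occurring species: for each
cell with ≥2 species, observed mean pairwise patristic distance versus a
null that shuffles tip identities within the regional species pool.
Because the shuffle only relabels which species occupy the (fixed)
presence–absence matrix, richness per cell and the range-size frequency
distribution are preserved exactly. `NRI = −(MPD_obs − mean_null)/sd_null`
(positive = clustered); cells with degenerate null sd are flagged, regions
take the mean over scored cells. We compute per cell and average per
region — the other reading (one pooled regional community) is a coarser
statistic with no null variance at small n. Patristic distances are
precomputed once per tree (O(n²) memory, fine at desk scale). Doubling all
branch lengths doubles observed and null MPDs alike and leaves NRI
unchanged — an exact invariance the tests assert.

The driver model regresses per-region mean rate (mean over member cells of
the cell mean — occupancy-weighted, so wide-ranging species count where
they occur) on the six z-standardised predictors: supplied time-integrated
area, productivity and temperature tables plus computed velocity, roughness
and NRI. Standardisation makes coefficients comparable effect sizes.
Constant predictors are an error; |r| > 0.95 predictor pairs raise a
warning (a collinearity screen, not an automatic fix). Regions with no
scorable community (no cell with ≥2 species) have no NRI and are excluded
from the model sample with a message.

## 6. The synthetic world

`simulate_world()` builds every input from one seeded config, emulating the
shape of the real inputs: posterior samples of time-calibrated trees
(branch-length jitter around one true tree — posterior *topological*
uncertainty is not emulated), contiguous spreading-dye ranges with a
lognormal range-size frequency distribution, smooth climate stacks over
multiple time horizons (deterministic gradient + trend + optional smooth
noise; noise defaults to zero so velocity has a closed form),
Gaussian-smoothed elevation, and a Voronoi bioregion partition with
supplied predictor tables drawn from fixed right-skewed/Gaussian
distributions (these stand in for externally reconstructed histories and
carry no planted signal).

Two planted structures define the package's reference study conditions,
chosen once and frozen:

* **Latitude plant** (defaults: 150 species, 3× rate contrast, fast clade
  anchored at |lat| = 50° ± 6°, slow clade around the equator ± 18°, 2°…3°
  grid from 60°S–60°N, 10 posterior trees). This produces an inverse
  latitudinal gradient whose recovery (positive, significant SAR slope of
  cell mean rate on |latitude|) is a stochastic end-to-end test.
* **Driver plant** (defaults: 32 bioregions, 4 independent clades per
  region, common crown age 12, base rate 0.1/My scaled by
  `exp(0.6 × score)` where the score is the standardised sum of the
  region's realised velocity and roughness z-values, clipped at ±2).
  Design notes, learned the hard way and worth recording: clades planted
  with a fixed *tip count* confound rate with depth — fast clades come out
  shallow on very long stems, and the stem then dominates their tips'
  equal-splits sums, crushing the signal. Fixed *age* clades let richness,
  not depth, absorb the rate. Several independent clades per region average
  out clade-level rate noise; clipping the score stops a single extreme
  region from owning the whole plant; tighter ranges (median 4 cells)
  limit cross-region bleed. Climate noise is switched on (sd 0.5) in these
  worlds because velocity must vary among regions to be a usable predictor.

What passing tests on these worlds shows — and what it does not: the
pipeline recovers planted gradients and driver effects of realistic
magnitude through the full stack (rates → gridding → spatial models), with
correct null behaviour (type-I error, NRI null consistency). It does not
validate DR as an estimator on real, incompletely sampled phylogenies, nor
polygon-based range processing (ranges here are native cell sets; the
analysis only ever consumes the presence–absence matrix), nor equal-area
projection effects — coordinates are geographic degrees throughout, as in
the degree-based distance conventions the models use.

## 7. Problem sizes, determinism, interfaces

Reference problem sizes (used by the tests and the acceptance script, and
comfortably desk-scale): tip-rate oracle checks on 100 trees of ≤50 tips;
Yule calibration on 200 trees of 200 tips; 500 neutral replicates
(n_null = 500) for the type-I error of the state-dependent test on 100-tip
trees; spatial-error recovery on a 20×20 lattice over 100 fits; NRI with
999 shuffles; 20 seeds for latitude-gradient recovery and 10 for driver
recovery. Every random step is seeded; the same config + seed reproduces
every output byte-identically, and each pipeline run writes a JSON manifest
(seed, config, counts) beside its CSVs.

The package speaks plain-text formats: Newick in/out for trees (via `ape`),
CSV for rates, presence–absence, traits, predictor and coefficient tables;
rasters are in-memory matrices with a CSV export. The R functions are the
interface; `sg_run_pipeline()` is the one-call orchestration, and
`scripts/acceptance.R` is a thin script over exported functions.

## 8. Known limitations

* DR is a recent-rate proxy, not a model-based estimator; no extinction or
  net-diversification inference is attempted.
* The spatial-error model's eigenvalue log-determinant is dense: thousands
  of sites are fine, hundreds of thousands are not.
* The posterior emulator varies branch lengths only; conclusions about
  topological uncertainty need real posterior samples.
* Coefficient standard errors are conditional on the fitted λ; they match
  the independent ML route on test problems but are mildly optimistic by
  construction.
* The synthetic climate is a gradient-plus-trend field; it does not emulate
  realistic paleoclimate covariance structures.
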