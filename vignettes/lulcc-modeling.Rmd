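---
title: "Modeling land use / land cover change with Markov chains, Weights of Evidence and cellular automata"
author: "lulcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling land use / land cover change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulcsim)
```

## The modeling problem

Temperate-forest regions lose primary cover through two distinct spatial
processes: *degradation* (canopy thinning, primary to secondary forest)
and *deforestation* (conversion to cleared or settled land). Given two or
more co-registered categorical land-cover maps -- here five classes:
primary forest (PF), secondary forest (SF), human settlements (HS), areas
without vegetation (AWV) and water bodies (WB) -- the package answers
three questions:

1. *How much* change occurred, and at what rates (area accounting,
   Markov transition matrices)?
2. *Where* is change likely (Weights-of-Evidence probability surfaces over
   driver rasters)?
3. *What could the landscape look like* under stationary, optimistic or
   pessimistic policy scenarios (cellular-automata projection), and how
   credible is the simulator (kappa, fuzzy similarity)?

The quantity of change is controlled entirely by the Markov chain; the
cellular automaton only decides its spatial arrangement. This separation
is the central assumption of the whole model family, and it is what the
aggregate-convergence test checks.

## Transition matrices and annualization

`estimate_matrix()` is the maximum-likelihood estimator
`P[i, j] = n(i -> j) / n(i)` on a cross-tabulation of two epochs, with the
period length attached. Classes absent at the start epoch receive identity
rows: rare classes (water bodies in dry scenes) should persist rather than
abort an analysis.

A matrix estimated over a multi-decade period must be stepped yearly, so
`annualize()` computes the principal matrix root through
eigendecomposition, `A = V D^(1/T) V^-1`. Two numerical facts shape the
implementation:

* Complex-conjugate eigenvalue pairs are harmless -- their contributions
  combine to a real root -- so only (numerically) real eigenvalues on the
  non-positive axis are an error, as is a non-invertible eigenvector
  matrix.
* The exact principal root of a perfectly ordinary, diagonally dominant
  land-cover matrix can carry small negative entries (for the shipped
  27-year example matrix, two entries around -0.001). Truncating them and
  renormalizing destroys the defining property `A^T = P`: the round-trip
  error jumps from machine precision to about 2e-2. `annualize()`
  therefore keeps the exact root by default, zeroes only sub-tolerance
  numerical noise, reports the residual negative mass in the `cleanup`
  attribute, and offers `force_stochastic = TRUE` (truncate and
  renormalize) for callers that need a proper stochastic matrix -- the CA
  uses that form, where a rate perturbation of order 1e-3/year is far
  below the sampling noise of allocation.

`restrict()` implements a transition whitelist by moving off-whitelist
mass onto the diagonal: a cell that may not change persists.

## Driver screening and Weights of Evidence

Weights of Evidence assume conditionally independent drivers, so pairs of
redundant drivers are screened first with Cramer's V,

    V = sqrt( chi2 / (Gamma * M) ),

where `chi2` is the chi-square statistic of the contingency between the
two binned drivers, `Gamma` the grand total and `M = min(n - 1, m - 1)`
for an `n x m` table. Pairs with `V > 0.5` are considered associated and
the member with the weaker association to the target transition is
dropped; a tie at exactly 0.5 retains both, since only values *above* the
threshold indicate association. Expected counts come from the marginals
with no continuity correction; zero marginal rows or columns are dropped
with a warning.

For one transition and one driver, the positive weight of a value range
`r` is

    W+(r) = ln[ (n(r & D) / n(D)) / (n(r & !D) / n(!D)) ],

with `D` the changed cells among the eligible (from-class) cells.
Positive weights attract the transition, negative weights repel it. Bins
with a zero changed or unchanged count get +0.5 additive smoothing on all
four counts of that bin's 2x2 table, keeping weights finite on sparse
transitions without touching well-populated bins. Continuous drivers
default to 20 equal-width bins over their observed range -- published
analyses report range endpoints but never the binning rule, so the width
is configurable and every table carries its edges.

`probability_map()` combines the tables of one transition through the
naive-Bayes odds update `odds = prior/(1-prior) * exp(sum W+)`,
`P = odds/(1+odds)`, with the annual Markov rate of the transition as the
prior and `P = 0` outside the from-class. After screening, no further
correction for residual dependence is applied.

## The cellular automaton

Per yearly step and per whitelisted transition `i -> j`:

1. **Demand.** `round-down-with-carry(n_i * P[i, j])` cells. The carry
   accumulator makes multi-step totals unbiased even for rates far below
   one cell per year; allocation shortfalls are added back to the carry,
   so unmet demand rolls into later years instead of vanishing.
2. **Expander** (a configurable fraction of the demand): converts
   from-class cells 8-adjacent to existing target patches, sampled without
   replacement proportionally to the probability surface, recomputing the
   frontier as patches grow. Unmet expansion cascades to the patcher in
   the same step.
3. **Patcher**: seeds new patches at probability-weighted locations; each
   patch grows to a lognormal target size (parameterized by mean and
   variance in hectares, truncated at the remaining demand), preferring
   high-probability neighbours. The `isometry` factor (>= 1) multiplies
   the weight of candidates by `isometry^(k - 1)` with `k` the number of
   patch members among their 8 neighbours, so larger values give rounder
   patches.
4. **Dynamic drivers** (e.g. distance to the current cleared-area extent)
   are recomputed by an exact Euclidean distance transform; a class that
   has vanished yields an all-`Inf` raster, which the binning maps to the
   top bin.

All randomness flows through one seeded generator: identical seeds give
bitwise-identical landscapes. The 8-neighbourhood, the lognormal patch
sizes and the expander/patcher split follow common practice in
patch-based land-change simulators; the sources this package draws on do
not publish their patch parameters, so `patch_params()` defaults (1 ha
mean, 0.5 ha^2 variance, isometry 1.5, expander fraction 0.5) are
explicit configuration, echoed into every run manifest rather than
hard-coded.

## Scenarios

A scenario multiplies annual off-diagonal rates (and optionally the patch
parameters) by configurable factors and re-absorbs the difference into
the diagonal; a row whose scaled off-diagonal mass reaches 1 makes the
scenario infeasible and raises an error naming the row. The suggested
defaults are 1.5 (pessimistic) and 0.5 (optimistic); the stationary
scenario leaves everything untouched. Published projections in this
domain state the *direction* of such modifications but not their
magnitude, so the factors are mandatory, named configuration. Human
settlements and water bodies are frozen to persistence by default, since
projected share tables in the motivating literature hold them constant;
freezing removes both the class's outbound row and all inbound flow.

## Validation

`kappa_index()` is Cohen's kappa on the cell-level confusion matrix.
`fuzzy_similarity()` scores a cell as matched if the class one map shows
there occurs anywhere within the `w x w` window of the other map
(constant fuzziness), averages over valid cells in both directions and
reports the minimum -- the conservative two-way variant of the
Hagen-style multi-resolution comparison. Windows are clipped at map
edges so small test grids stay fully defined. One-way and
exponential-decay (`2^(-d/halving)`) variants are selectable because the
lineage of published implementations is ambiguous about both choices.
Under the constant kernel the score is non-decreasing in window size and
window 1 equals raw agreement.

Distances attached to windows support two conventions: half-width
(`(w-1)/2 * cell_size`; a 7x7 window of 30 m cells spans 90 m from the
focal cell) and full-width (`w * cell_size`, 210 m for the same window).
Full-width is the default because published similarity curves in this
domain label the 7x7 agreement as 210 m.

## The synthetic study generator

No real study maps are distributed with the package, so every end-to-end
claim is tested on synthetic regions with known parameters:

* **Landscapes** are Gaussian-smoothed noise fields thresholded at the
  share quantiles: realized shares match requests up to ties, patch
  scale follows the autocorrelation length, and everything is
  deterministic per seed. A cluster-growth generator would look more
  organic but is much harder to parameterize; smoothing + thresholding
  was chosen for controllability.
* **Drivers** cover the three families used by deforestation models:
  proximity (exact distance to random polyline "roads"), density
  (kernel-smoothed point counts per km^2) and topographic (fractal
  elevation with slope in degrees via central differences, and a
  topographic position index with a 5-cell default radius).
* **Histories** step each cell with the annual Markov rates, multiplied
  by planted `exp(W+)` odds factors inside declared driver ranges and
  renormalized so the aggregate expected demand still matches the
  matrix. The planted weight is therefore recoverable as the contrast
  between the mean in-range and out-of-range W+ (for small rates the
  log-odds contrast equals the planted value; cumulative multi-year
  saturation biases it upward by roughly 0.1 at the default rates, well
  inside the +/-0.3 recovery band the tests use).

What the generator does *not* emulate: classification error in the input
maps, georeferencing artifacts, climate covariates, roads that grow over
time, or any real geography. Passing recovery tests therefore demonstrate
the correctness of the estimators and the allocator, not the realism of
any particular regional projection.

## Test design notes

* Demand rounding is deterministic by construction, so across-seed
  variance of realized aggregate shares can collapse to zero when every
  demand is met. The aggregate-convergence test therefore adds the a
  priori carry-drift bound -- at most one cell per whitelisted
  transition-year per class -- to the 3-standard-error Monte-Carlo band.
  This bound was fixed from the rounding analysis before the test was
  first run.
* The null-driver Weights-of-Evidence check (independent driver, no
  planted effect) uses 5 equal-count-scale bins on 10^4 cells with a
  balanced change mask, so each bin's weight has a standard error of
  about 0.04 and the |W+| < 0.15 envelope corresponds to roughly 3.5
  standard errors.
* Problem sizes in the test-suite and acceptance runs -- 200x200 histories
  for parameter recovery, 20-seed batches of 100x100 CA runs, 10-seed
  scenario ordering over 33 years -- were chosen so each recovery target
  has comfortable statistical power while a full run of the suite stays
  in the minutes range on a single core.

## Known limitations

* Grids are plain matrices: maps must be pre-aligned, and GeoTIFF
  georeference tags are neither read nor written (the ESRI ASCII format
  round-trips exactly and is the native interchange format here).
* Rate-of-change columns printed in published accounting tables are not
  reproduced; their formula is unstated, and the compound annual rate
  `((A2/A1)^(1/dt) - 1) * 100` provided by `annual_change_rate()` is this
  package's own summary, not a reconstruction.
* Spatially varying (per-region) transition matrices, road-growth
  submodels and agent-based extensions are out of scope.
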