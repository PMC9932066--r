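---
title: "Methods: quantitative plant-pollinator networks along urbanisation gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative plant-pollinator networks along urbanisation gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## Scope and model of the data

`pollinet` analyses quantitative bipartite flower-visitation networks
collected at a set of grassland patches along an urbanisation gradient.
The observational unit is an interaction record: one visitor taxon touching
the reproductive parts of one flowering plant species during one sampling
round at one site, with a visit count. Pooling all rounds of a site gives
the site's network — a plant × visitor count matrix \(a_{ij}\) with
\(m = \sum_{ij} a_{ij}\) interactions — represented by the S4 class
`BipartiteNetwork`. Visitors belong to four groups: wild bees, hoverflies,
butterflies and the managed honey bee. Networks can be aggregated on the
visitor side to genus resolution (plants stay at species level), since
taxonomic resolution is known to affect network metrics.

## The five network metrics

* **Connectance** — realised links over possible links,
  \(\#\{a_{ij}>0\}/(RC)\).
* **NODF nestedness** (0–100) — computed on the binarised matrix; a pair of
  rows (or columns) with *strictly* different fills contributes
  \(100\, o/\min(f_1,f_2)\), where \(o\) is the count of shared presences;
  equal fills contribute 0 (the decreasing-fill rule). NODF is the mean over
  all row pairs and column pairs. The implementation is cross-checked in the
  test suite against both a direct pairwise-definition oracle and
  `vegan::nestednodf`.
* **Modularity Q** — Barber's quantitative bipartite modularity,
  \(Q = \tfrac1m \sum_{ij}\big(a_{ij} - \tfrac{r_i c_j}{m}\big)\,
  \delta(g_i, g_j)\),
  maximised over joint assignments of plants and visitors to modules by
  simulated annealing (see below).
* **H2′ network specialisation** (0 generalised, 1 specialised) — the
  two-dimensional Shannon entropy \(H_2 = -\sum p_{ij}\ln p_{ij}\)
  standardised between the extreme entropies attainable under the observed
  margins: \(H_2' = (H_{max}-H_2)/(H_{max}-H_{min})\).
* **d′ visitor specialisation** — the Kullback–Leibler divergence between a
  visitor's use of plants and plant availability \(q_i = r_i/m\),
  standardised between the extremes attainable by an integer allocation of
  the visitor's \(A_j\) visits with per-plant capacity \(r_i\). The network
  summary is the unweighted mean of d′ over visitor species (an
  abundance-weighted option exists).

### Exact versus heuristic standardisation bounds

The H2′ and d′ bounds are a design decision, because the published
definitions leave the extremal tables implicit. When the space of
margin-consistent integer tables (or capped allocations) is small enough to
enumerate — the regime of every oracle test, and of small empirical
networks — the bounds are computed **exactly** by constrained enumeration.
Otherwise the package falls back to standard heuristics: \(H_{max}\) from
the outer product of the margins (the continuous maximum), \(H_{min}\) from
greedy largest-cell allocation; \(d_{max}\) by filling plants in increasing
order of availability (capped at their totals), \(d_{min}\) by
largest-remainder proportional allocation. Results are clamped to
\([0,1]\). The switch is governed by an enumeration budget
(`exactLimit`), not by matrix size per se. Consequences worth knowing:
heuristic bounds can differ slightly from the exact extremes, so H2′/d′
values of large networks carry a small method-dependent component — which
cancels in the null-standardised Δ quantities below, because bounds depend
only on the margins and are therefore *identical* for the observed network
and every fixed-margin null draw (they are computed once per margin set).

### The annealing schedule

`bipartiteModularity()` anneals single-node reassignments (plus occasional
module merges, probability 0.05) under geometric cooling (factor 0.99),
with the initial temperature set to the largest absolute entry of the
modularity matrix, \(5(R+C)\) proposals per level, and termination after 25
levels without improvement (cap 200 levels). Each chain ends with a greedy
refinement sweep that alternates optimal reassignment of columns given rows
and vice versa until a local optimum; by default 3 independent chains are
run and the best kept. All of this is exposed via `saParameters()` and is
deterministic given a seed. On networks with up to ~12 nodes the optimiser
matches an exhaustive-search oracle in well over 95% of restarts (the
oracle enumerates row set partitions only and attaches each column to its
best module, which is exact because Q separates over columns once the row
partition is fixed). Modularity is scale-free: multiplying all counts by a
positive integer leaves Q unchanged, unlike H2′/d′ whose integer bounds see
the finer granularity.

## Null models and the Δ-transformation

Because raw network metrics depend strongly on network size and sampling
intensity, each metric \(N\) is reported together with
\(\Delta N = N - \bar N_r\), the departure from the mean over fixed-margin
random tables drawn by Patefield's algorithm (`stats::r2dtable`). Defaults
follow field practice for site-level visitation networks: 1000 draws per
metric and 100 for the annealing-based modularity, where null draws are
budget-matched to a single annealing restart per draw. Draws on which a
metric is undefined are rejected and resampled with a logged count (this is
defensive; margins built from observed networks cannot produce zero lines).

## Landscape module

**3D connectivity.** The index extends Hanski's incidence-function
connectivity \(S_i = \sum_{j \ne i} e^{-\alpha d_{ij}} A_j\) to a cityscape
by inflating distance with vertical obstruction:
\(d^{eff}_{ij} = d_{ij} + \lambda H_{ij}\), where \(H_{ij}\) is the summed
height of buildings within a 25 m corridor of the straight centroid-to-
centroid route between patches. The additive form \(d + \lambda H\) is the
simplest monotone, units-consistent choice (the exact algebraic form used
with GIS tooling in field studies is typically not printed); \(\lambda\)
defaults to 1 m of added effective distance per metre of summed height and
is exposed everywhere. \(\alpha\) defaults to 0.002 m⁻¹ (mean effective
dispersal 500 m), a typical magnitude for central-place-foraging bees.
With \(\lambda = 0\) the index is exactly Hanski's. Routes are straight
segments between centroids — true street-network routing and edge-to-edge
patch geometry are out of scope and documented as a divergence from
GIS-based workflows.

**Scale of effect.** Landscape predictors measured at 100/500/1000 m radii
are matched to each response by Pearson correlation; the radius with the
highest \(|r|\) is selected. The absolute value matters: a signed maximum
would never select strong negative relationships such as bee richness
against impervious surface. Ties break toward the smallest radius (the most
local mechanism).

## Community composition and environmental vectors

Composition analysis uses visitor species with ≥ 3 visits overall, then a
square-root transform, Wisconsin double standardisation and Bray–Curtis
dissimilarity (via `vegan`). Ordination coordinates are an input —
any standard 2-D multidimensional scaling of the prepared dissimilarity is
acceptable (the pipeline uses classical scaling; non-metric stress
minimisation is deliberately out of scope). Environmental vectors are
tested by permutation: \(R^2\) is the squared multiple correlation of the
variable on the two axes, and
\(p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(1+n_{perm})\) with 99,999
permutations by default. The add-one estimator is used deliberately: it is
unbiased under the null, cannot return 0, and bounds \(p\) below by
\(1/(1+n_{perm})\).

## Regression stage

Predictors first pass an iterative variance-inflation-factor screen
(cutoff 3, highest-VIF-first, perfect collinearity dropped immediately with
a warning). Counts are fitted by Poisson GLM; if the Pearson dispersion
\(\chi^2/\mathrm{df}\) exceeds 1.5 — a configurable threshold; field papers
state the rule but rarely the cutoff — the model is refitted as negative
binomial with ML dispersion. Continuous responses use Gaussian LMs. Model
choice is exhaustive over all predictor subsets of size ≤ 3 (guarding
against overfitting at n ≈ 11 sites) ranked by AIC. Pseudo-R² for GLMs is
\(1 - \text{deviance}/\text{null deviance}\). Residuals are screened for
spatial autocorrelation with Moran's I under row-normalised
inverse-distance weights (the weighting is a documented choice, also
configurable) using the normal approximation; a significant result sets a
`gls_recommended` flag — the generalised-least-squares refit itself is
delegated. Patch size enters models natural-log-transformed. p-values are
reported unadjusted, matching standard practice in this literature. Small
meta-statistics complete the stage: one-sample t-tests of Δ-metrics
against zero, and Pearson correlation plus paired t-tests comparing metrics
between species- and genus-level networks.

## The synthetic-data generator

The generator exists so that every downstream stage is exercised end to end
without field data. It emulates the design of an 11-site urban
dry-grassland visitation survey:

* **Landscape** — patches placed uniformly in a 10 × 10 km region; a latent
  urbanisation gradient plus radius-specific noise yields impervious
  percentages at 100/500/1000 m whose pairwise correlation is calibrated to
  `crossScaleCorr` (default 0.8; the latent loading is
  \(\sqrt{\rho}\) so that the between-radius correlation is \(\rho\));
  patch areas log-uniform on 0.2–15 ha; building counts scale with local
  impervious cover, positions uniform in each site's neighbourhood, heights
  uniform on 4–30 m.
* **Communities** — species pools of 105 bees, 38 hoverflies, 22
  butterflies (plus the honey bee) and 70 plants, with genus structure,
  lognormal commonness and one latent trait per species on \([0,1]\).
  Per-site richness is Poisson with log-linear responses: bees decline with
  impervious surface at 500 m (−0.012 per percentage point), butterflies at
  100 m (−0.02), hoverflies are flat, honey-bee visits and flower abundance
  increase (+0.02 at 100 m, +0.01 at 500 m). Bare-soil cover is generated
  collinear with impervious surface (r ≈ 0.92) so that the VIF screen has a
  realistic casualty. These magnitudes are free parameters of the design,
  not estimates of any particular survey (field papers print directions and
  P-values, not link-scale slopes); they were fixed once, by the
  requirement that an 11-site study detects the bee and butterfly declines
  at moderate power, and are exposed in `syntheticConfig()`.
* **Visits** — per present visitor, a negative-binomial total (dispersion
  2; overdispersed counts are the ecological norm, and they exercise the
  NB branch of the model ladder) with group-specific mean rates calibrated
  so wild bees dominate interactions (≈ 54%) with hoverflies, butterflies
  and the honey bee minor, allocated across the site's plants with
  probability \(\propto\) plant abundance
  \(\times\, e^{-s\,|t_v - t_p|}\), where `s = specialisationStrength`
  (default 4), then spread uniformly over 8 sampling rounds. At \(s = 0\)
  visitation is exchangeable (rank-1 expected matrix); above \(s \approx 2\)
  trait matching structures the networks strongly enough that the classical
  Δ sign pattern emerges (Δ-connectance and Δ-NODF below zero,
  Δ-modularity above zero, by one-sample t-test across sites).

What the generator does **not** emulate: within-season phenology, weather-
dependent detectability, spatially clustered urban morphology, and
morphospecies ambiguity. Passing tests therefore demonstrate correctness of
the statistical machinery under the declared generative model, not the
field realism of any particular dataset.

## Numerical choices and degenerate inputs

* 1×1 networks: H2′ defined as 0 (flagged `degenerate`); NODF is an error;
  Δ-connectance is exactly 0 because connectance is margin-determined.
* Margin-proportional matrices give H2′ = mean d′ = 0; diagonal
  equal-margin matrices give both = 1; the all-ones matrix has Q = 0.
* Percentage shares use commercial rounding (half away from zero), so
  printed survey tallies reproduce exactly.
* Permutation p-values use the add-one estimator; annealing ties break by
  first-found; scale-of-effect ties break toward the smallest radius.
* All stochastic stages are seeded; the pipeline derives per-stage seeds
  from the master seed by fixed offsets so stages replay in isolation, and
  the run manifest records seeds, timings and a config fingerprint.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations are sized for tight
feedback loops: metric oracles run on 200 random networks of up to ~9
nodes with exhaustive enumeration as reference; the end-to-end pipeline
runs the full default 11-site design with 300 null draws per metric (30
for modularity, each a single annealing restart); recovery simulations use
100 replicates at n = 300 observations and 1000 replicates for test-size
calibration. These sizes are package choices; all of them can be raised
through the exported arguments.

## Known limitations

* Heuristic H2′/d′ bounds on large networks are approximations with a
  one-sided clamp; exact enumeration is used whenever affordable.
* Simulated annealing gives no optimality certificate on large networks;
  restarts and the refinement sweep mitigate but do not eliminate this.
* The Moran's I check uses a normal approximation (adequate at n ≈ 11 on
  the evidence of permutation comparisons in the test suite); the GLS refit
  it may recommend is out of scope.
* Corridors are straight centroid segments; building data enter only
  through summed heights.
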