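---
title: "Ellipsoid niche models, equivalency tests and ancestral niche reconstruction"
author: "nichellipse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipsoid niche models, equivalency tests and ancestral niche reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichellipse)
```

## The scientific problem

When a widespread lineage diversifies in allopatry, pairwise tests of
present-day niches can show "divergence" even if no descendant ever evolved
into novel environmental space: descendants may simply *partition* a broad
ancestral niche, each occupying a different subset of it. Distinguishing
true niche evolution from partitioning (against the null of conservatism)
requires three things done together:

1. a *fundamental*-niche estimate per taxon — here a minimum volume
   ellipsoid (MVE) in environmental space, deliberately simple and convex;
2. a *background-similarity* equivalency test for every taxon pair that
   conditions on what environments each taxon could have reached (its
   accessible area, **M**); and
3. an *ancestral reconstruction* of niche occupancy that also conditions
   on accessibility, so that a taxon is never coded "absent" from
   environments it never had access to.

`nichellipse` implements this whole chain, plus a virtual-species
simulator that generates worlds with known truth under the three canonical
scenarios — partitioning, conservatism, divergence — so every stage can be
validated without any data download.

## Occurrence preparation

Records pass through a fixed, logged sequence: coordinate-uncertainty
filter (strictly greater than 10 km removed — the boundary value is kept;
records with no stated uncertainty are retained by default), locality
deduplication (coordinates rounded to 1e-4°, earliest record kept),
breeding-season windows (April–July for Northern-Hemisphere migrants,
October–January — wrapping the year boundary — for Southern-Hemisphere
migrants, residents unfiltered), clipping to the taxon's M polygon
(boundary-inclusive), and spatial thinning. Whether thinning should precede
or follow M-clipping is not dictated by anything structural; the package
fixes the order uncertainty → dedupe → dates → M-clip → thin and records
each step's counts in a prep log, so reruns are idempotent.

Thinning is a seeded greedy pass: records are visited in a shuffled order
and kept iff they are ≥ `min_km` (great-circle, Earth radius 6371 km) from
everything already kept. The greedy rule was chosen over stochastic
"remove-one-of-the-closest-pair" variants because it *guarantees* the
pairwise distance constraint, is O(n·kept), and is exactly reproducible
from the seed; the retained set is maximal (every dropped record is within
`min_km` of a kept one). Typical thresholds are 20 km for widespread taxa
and 10 km for localized ones.

## The ellipsoid niche model

`fit_mve()` is a resampling MVE in the Rousseeuw tradition: each random
(d+1)-point subset proposes its mean and covariance; the covariance is
inflated by the h-th smallest squared Mahalanobis distance so the
candidate covers h = ⌈inclusion · n⌉ points; the smallest-volume candidate
wins. All C(n, d+1) subsets are enumerated when there are at most
`n_subsets` (default 5000) of them, which makes small instances exact and
testable against brute force. Candidates whose subset covariance has
reciprocal condition number below 1e-10 are skipped: near-collinear
subsets (common with gridded environmental values) otherwise produce
numerically meaningless inverses and spurious "small" volumes. The 90%
default inclusion tolerates vagrants and georeferencing error without
discarding much signal from range-restricted taxa. The shape matrix is
used raw (coverage scaling only, no chi-square consistency rescaling):
the object of interest is the geometric set of tolerable environments,
not an asymptotically unbiased covariance estimate.

Suitability is `exp(-d²/2)` of the model's Mahalanobis distance — a
strictly monotone, bounded transform equal to a multivariate normal
density up to normalization; a linear `1 - d/d_max` alternative is
available (`transform = "linear"`). Because overlap statistics are
computed on sum-normalized surfaces, the choice of monotone transform is
consequential and therefore explicit and configurable. Binary maps use
Gamma quantiles fitted by maximum likelihood to the occurrence distance
distribution (which is right-skewed); cutoffs at 75–99% data inclusion
are strictly nested. The Gamma is fitted to raw distances, not squared
ones, matching the skewed-distance rationale.

Models are fitted on the retained raw environmental variables by default.
PCA (`pca_importance()`, correlation-matrix PCA by default because
environmental variables carry incommensurate units) is used for reporting
relative variable importance as squared-loading percent contributions,
not as a pre-transform — though nothing prevents fitting on leading PC
scores if a user prefers.

## The equivalency test and its score

For a pair (A, B), Schoener's
D = 1 − ½·Σ|p_A − p_B| is computed between the two sum-normalized
suitability surfaces over the *union* of the two Ms' usable cells — a
symmetric extent containing every environment accessible to either taxon.
Each observed D is then referred to two null distributions: 100 models
fitted to random cells drawn from A's M (each compared against B's fixed
model), and vice versa. The number of random points per null model
defaults to the occurrence count of the M's own species — equal sampling
effort, so the null reflects "a species of the same data size sampling
this background at random". Rank p-values use the +1 correction,
p = (1 + #{null ≤ D_obs})/(N + 1), so neither tail is unreachable at
N = 100, and ties count into the lower tail (conservative for divergence
claims). With two-tailed α = 0.05 the pair is scored:

* **−2** — both p < 0.025: divergence supported against both backgrounds;
* **−1** — exactly one p < 0.025 (the other central): possibly diverging;
* **0** — both central, or the contradictory one-low/one-high pattern
  (flagged `conflict`);
* **+1 / +2** — one/both p > 0.975: overlap higher than background
  expectation, i.e. conservatism stronger than chance.

## Ancestral reconstruction over accessibility-aware bins

Each environmental variable is discretised into equal-width bins (default
20) spanning the union of all taxa's M value ranges. A taxon's bin is
`present` when it intersects the central quantile interval of its
occurrence values (default 95%, i.e. 5% total trim — the same outlier
tolerance philosophy as the 90% ellipsoid; `trim = 0` disables),
`uncertain` when the bin lies wholly outside the taxon's accessible value
range, and `absent` otherwise. Absent bins strictly between present bins
are recoded present: niches are assumed interval-shaped along single
variables. Equal-width binning over the accessible union was chosen
because it keeps bins commensurable across taxa; the count is
configurable.

Per bin, ancestral states are reconstructed by minimum-change
(Fitch/Hartigan) parsimony with `uncertain` treated as missing
(compatible with both states); the downpass union count equals the true
minimum (verified against exhaustive enumeration in the tests). Nodes
whose minimum-change state is not unique are reported `ambiguous`.
Branch gains/losses are counted on one canonical minimum resolution:
children inherit the parental state when compatible, and remaining ties
resolve toward presence. The tie direction matters only for bookkeeping
of symmetric cases; resolving toward presence mirrors the view that an
ancestor of taxa occupying complementary bins plausibly occupied their
union, which is exactly the partitioning hypothesis the method exists to
examine. Maximum-likelihood (Mk) reconstruction is a deliberate non-goal
of this version.

Missing taxa known from independent evidence to form a sister pair can be
grafted with `graft_taxon()`, which inserts the new tip at the midpoint
of the sister's terminal branch (the new node halfway between the sister
tip and its parent node; the alternative reading — midpoint of the whole
root path — is noted but not implemented). All other pairwise tip path
lengths are unchanged.

## The virtual-species simulator

`make_world()` builds: (i) standardized smooth environmental layers
(seeded white noise convolved with a Gaussian kernel, exact edge
renormalisation); (ii) a Yule tree (or a user tree); (iii) true ellipsoid
niches evolved under the chosen scenario; (iv) disjoint vertical-strip
Ms, emulating allopatric breeding ranges; (v) occurrences sampled
uniformly over the M cells whose environment lies inside the true niche
at the chi-based cutoff (default 95%), with sub-cell jitter. True niches
are defined directly in environmental space so that ground truth
coincides with the estimand of `fit_mve()`, making recovery tests
well-posed.

Default study conditions, fixed once: 80 × 80 one-degree grids, 2
environmental variables, kernel radius 2 cells, niche scale
(`niche_width`) 0.3 standardized environmental units, 100 occurrences per
taxon, divergence offset 6 Mahalanobis units. The offset exceeds twice
the sampling-cutoff radius (2·√χ²₀.₉₅(2) ≈ 4.90), so diverged true
ellipsoids are strictly disjoint; the niche scale keeps both the
ancestral and the displaced niche well represented among standardized
layer values (a displaced centre sits 1.8 units from the layer mean,
where cells are still common). Scenario geometry: partitioning splits the
parent ellipsoid at each binary node along its widest axis into two
disjoint sub-ellipsoids (split semi-axis 0.45·a at centre offset ±0.5·a,
perpendicular axes scaled by √0.5, which keeps every child boundary point
inside the parent — the worst-case parent Mahalanobis radius is 0.92);
conservatism copies the root niche; divergence displaces one designated
tip along a random direction. Optional Brownian jitter of centres
(`step_sd`) can be superimposed on any scenario.

What the simulator does *not* emulate: real covariance structure among
climate variables, anisotropic or non-convex niches, sampling bias within
M, georeferencing error, or non-stationary spatial autocorrelation.
Passing the synthetic validation therefore shows that the machinery is
correct and well calibrated under its own assumptions — not that any
particular empirical data set satisfies those assumptions.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle where
one exists: exhaustive (d+1)-subset enumeration and exhaustive
shortest-interval search for the MVE; exhaustive labelling enumeration
for parsimony (trees ≤ 6 tips); an O(n²) pairwise distance scan for
thinning; a textbook scalar ray-caster (and `mgcv::in.out`) for
point-in-polygon; `cluster::clusGap` (with squared-distance dispersion,
`d.power = 2`, and the uniform-over-range reference) for the gap
statistic; and closed forms for Schoener's D, PCA reconstruction and
Mahalanobis surfaces.

The statistical calibration of the equivalency test is checked by
simulation: under conservatism (identical true niches, disjoint Ms) the
−2 rate across 50 simulated pairs must stay ≤ 0.10; under divergence
(disjoint true ellipsoids) it must reach ≥ 0.80. These runs use 50 null
replicates per direction, 100 occurrences per taxon, 60 × 60 grids and
reduced candidate-subset counts (200–300) — sizes chosen so the whole
validation completes in about a minute while Monte-Carlo error stays
well inside the pass margins; the same quantities are recomputed from
scratch by `scripts/acceptance.R`. Centre-recovery is measured at
n ∈ {25, 100, 400} over 20 seeded worlds and must decrease on average
with n; these worlds use finer 100 × 100 grids so that the limited
number of distinct cell values inside a niche does not put a
discretization floor under the error.

## Numerical choices and degenerate inputs

* NA propagates by union across raster layers, so every retained cell has
  a complete environmental vector.
* Grids are cell-centre addressed, row 1 northernmost; point lookup is
  nearest cell centre.
* Polygon membership uses the even-odd rule and counts boundary points as
  inside; self-intersecting rings are flagged but remain well-defined
  under even-odd evaluation, so no geometry "repair" is needed.
* `fit_mve()` refuses n ≤ d and all-identical points; `gamma_thresholds()`
  refuses constant distances and fewer than 5 points, and jitters exact
  zeros by machine epsilon.
* Background null fits retry a singular random draw up to 10 times before
  failing; the simulator refuses niche/M combinations with acceptance
  probability < 1e-4 (a species cannot occur where its niche is absent).
* All stochastic stages take explicit integer seeds and are bit-reproducible;
  seeded evaluation never disturbs the caller's RNG state.

## Known limitations

* The raster format is the plain-text ESRI ASCII grid; layers must be
  co-registered in lon/lat — there is no reprojection or resampling.
* Polygon input is GeoJSON (Polygon/MultiPolygon features with a `taxon`
  property).
* The equivalency test inherits the usual caveats of background
  similarity testing: its null is "random sampling of the accessible
  background", not an explicit evolutionary model, and the comparison
  extent (union of Ms) affects D's absolute scale.
* Parsimony reconstruction reports one canonical minimum; alternative
  minimum-change histories are summarised only through `ambiguous` flags.
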