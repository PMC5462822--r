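---
title: "Delimiting areas of endemism and composition breaks from point occurrences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting areas of endemism and composition breaks from point occurrences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Biogeographic regionalization hypotheses — for instance, that the land
between two large rivers (an interfluve) is an area of endemism (AoE)
bounded by the rivers — are often drawn from expert range maps rather
than tested against occurrence data.  `endemap` implements a pipeline
for such tests from point records alone: it delimits AoEs by kernel
interpolation of range overlap (GIE) and by parsimony analysis of
endemicity (PAE), quantifies how well individual species fit candidate
areas, maps spatial turnover in species composition (dissimilarity →
ordination → kriging), traces maximum-difference barriers with
Monmonier's algorithm, and classifies the resulting composition rasters.
Every stage is validated by parameter recovery on synthetic data with
planted structure, because real occurrence databases at this scale are
rarely shareable in full.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

# Data model

Occurrences are `(taxon, lon, lat)` points in WGS84 decimal degrees.
All metric computations use the haversine great-circle distance on a
sphere of radius 6371 km; near the equator, where the motivating
applications live, lon/lat grids are nearly equal-area, and degree grids
with km-based range categories follow field practice.  Grids are
half-open (`[west, east) x (south, north]`), so boundary records fall in
exactly one cell — the convention matters only for records exactly on
cell edges and is stated in `grid_spec()`.

Records are collapsed to binary presences per cell; raw per-cell record
counts are retained as a sampling-effort signal.  Cells with fewer than
ten records are excluded before dissimilarity analyses
(`filter_cells_by_records()`, configurable), since poorly sampled cells
inflate dissimilarities.  Duplicate records are kept in the counts but
never create duplicate presences.

# Geographical interpolation of endemism

Each taxon is summarized by its range centroid (unweighted coordinate
mean — at the range sizes involved, at most ~2150 km, the difference
from a spherical centroid is negligible) and the distance from the
centroid to the farthest record.  Taxa are binned into eleven range-size
categories with upper bounds 100, 200, 400, 600, 800, 1000, 1200, 1400,
1600, 2000 and 2150 km; larger ranges are clamped into the last category
with a warning, since the method is designed for regional endemics.

Per category, the centroids are interpolated with a quartic (biweight)
kernel, \(K(d) = \tfrac{3}{\pi h^2}\left(1 - (d/h)^2\right)^2\) for
\(d < h\), the common kernel-density convention of desktop GIS.  The
bandwidth equals the category's upper bound: species whose ranges span
up to \(h\) km can only show congruent overlap at that scale.  Each
category surface is rescaled to \([0, 1]\) by its own maximum, and the
consensus is the sum of the rescaled layers (a pixelwise maximum is
available via `assembly = "max"`).  The default pixel size is 0.1°; the
recovery analyses below use 0.25° to keep run times in seconds — at
three or more pixels per kernel bandwidth the surfaces are already
smooth.

## Delineation

Turning the consensus into discrete areas required a genuine design
decision, and the obvious rule — threshold the consensus at a fraction
of its global maximum — fails structurally.  Standardization gives
every category layer a maximum of 1, so categories whose bandwidth
approaches the study-window scale contribute a smooth background of
0.7–1.0 over most of the window.  Summed over several widespread
categories this background exceeds any global-fraction threshold, and
the thresholded set collapses into a single component regardless of how
strong the planted signal is.  We verified this on the synthetic
benchmarks: with the plain rule the three planted areas are always
swallowed by one window-spanning component.

`delineate_aoes()` therefore works category-aware when given a full
`gie_result`:

1. **Admission.**  A category layer enters delineation only if it passes
   two gates computed on a coarse calibration grid (default 1.5°):
   *patchiness* — its max/mean contrast reaches `contrast_min`
   (default 3), which excludes the saturated near-uniform layers; and
   *congruence* — its maximum kernel stacking depth exceeds, at
   permutation level `alpha` (default 0.05, 99 replicates), what the
   same number of centroids placed uniformly at random over the window
   produces at the same bandwidth.  Stacking beyond chance is the
   defining property of synendemy; a layer indistinguishable from
   random placement carries no congruence signal.  In unstructured
   simulations the per-category contrasts sit between about 2 and 5,
   while planted endemic classes reach 6–30, so the patchiness default
   separates the regimes with a wide margin.
2. **Components.**  The admitted standardized layers are summed and the
   8-connected pixel components above `threshold_frac` (default 0.3) of
   that sum's maximum become candidate areas.
3. **Synendemic support.**  A taxon supports an area when its centroid
   falls inside and, when records are supplied, at least
   `support_frac = 0.9` of its records fall inside — the same more-than-90%
   containment logic the species-to-area fit index uses to call a
   species "endemic of" an area.  Candidates with fewer than
   `min_synendemics = 2` supporters are dropped: an area of endemism is
   by definition the congruent ranges of at least two taxa.

For a bare `kernel_surface` the simple global-fraction rule is applied
unchanged, which is convenient for arbitrary rasters and for the
single-peak / two-peak sanity cases.  All thresholds are recorded in
the result (`attr(aoes, "admission")`, `attr(aoes, "threshold")`).

On the `three_aoes` benchmark (three disjoint 10° planted polygons with
20 endemics each over 100 widespread species) the three top-ranked areas
each recover a distinct planted polygon with mean pixel Jaccard above
0.6; on the structureless `null` benchmark no area reaches five
synendemics in 18 of 20 seeds.  The two failing seeds contain genuine
chance aggregations — several moderately widespread species whose
ranges happen to be co-contained in one region — which a
congruence-based method reports by design.

# Sampling effort and corrected correlation

`record_density_surface()` interpolates the raw records (unit mass each)
with the same quartic kernel, by default at 200 km bandwidth — a scale
chosen to show collection-locality structure without dissolving it; it
is exposed as a parameter since the choice is conventional.

Correlating two surfaces pixel-by-pixel wildly overstates significance
when both are autocorrelated.  `corrected_correlation()` implements the
modified t-test of Clifford, Richardson & Hemon (1989) with Dutilleul's
(1993) refinement in spirit: empirical spatial autocorrelation functions
of both surfaces are estimated on distance classes one pixel wide, the
variance of the sample correlation under independence is
\(\widehat{\mathrm{var}}(r) = n^{-2}\bigl(n + 2\sum_k n_k
\hat\rho_X(k)\hat\rho_Y(k)\bigr)\), the effective sample size is
\(\hat M = 1/\widehat{\mathrm{var}}(r) + 1\) (capped at the pixel
count), and the t-test uses \(\hat M - 2\) degrees of freedom.  On
white noise \(\hat M\) recovers the pixel count within a few percent;
on fields smoothed with a 2-pixel Gaussian the corrected test rejects a
true null at about the nominal 5% while the naive test rejects more
than half the time.  Pairwise distances are cached per raster geometry,
and rasters beyond 3000 pixels are thinned regularly before the pair
census.

# Species-to-area fit

For a species occupying cell set \(S\) and an area occupying cell set
\(A\) on the same grid, \(a = 100\,|S \cap A|/|S|\) is the percentage
of the distribution inside the area and \(b = 100\,|S \cap A|/|A|\) the
percentage of the area occupied; the fit index is \((a+b)/200 \in
[0,1]\).  Species distributions are operationalized as occupied grid
cells, not interpolated range polygons — extrapolating ranges to the
nearest candidate boundary would presuppose exactly the hypothesis
under test.  Only species with \(a\) above a threshold (default 90,
deliberately exposed because it is a convention, not a law) qualify as
endemic of an area.  Because it is ambiguous whether a mean fit should
average within areas first, `aoe_fit_report()` reports both the
per-area means and the pooled mean over all qualifying (species, area)
pairs.

# Composition breaks

The six-step pipeline (`composition_pipeline()`):

1. presence/absence matrix on a 1° (configurable) grid, cells with <10
   records excluded;
2. cell-to-cell Bray–Curtis dissimilarities — on binary data this *is*
   the Sørensen index \((b+c)/(2a+b+c)\); an abundance mode using
   record counts exists but is off by default, and the flavour is
   recorded on the matrix;
3. non-metric MDS (Kruskal stress-1, global model) with 100 random
   starts plus one metric start, best solution by stress; scores are
   centred; the non-metric fit is \(R^2 = 1 - \text{stress}^2\) and the
   linear fit the squared correlation between monotone-fitted and
   ordination distances (the convention of the ordination software
   family used in this field);
4. Moran's I per axis over queen-adjacent occupied cells
   (row-standardized; the weighting scheme is conventional and
   exposed), with a two-sided permutation test — the premise check
   before any interpolation;
5. ordinary kriging of each axis onto the raster with an exponential
   variogram fitted by weighted least squares (weights \(n_j/\hat\gamma_j^2\))
   to the empirical semivariogram on 15 equal-width bins, range bounded
   within \([d_{max}/100,\,10\,d_{max}]\) to keep the kriging system
   well-conditioned; a linear variogram is the fallback, with a
   warning.  The predictor is exact at data points (`$predict`), and a
   prediction-variance surface is returned;
6. an RGB composite mapping axes 1–3 to red, green and blue after
   min–max scaling to 0–255 (constant bands map to 128 with a warning).

Proprietary "empirical Bayesian kriging" is replaced by ordinary
kriging: the only premise the pipeline relies on is that the scores are
spatially autocorrelated, which step 4 tests explicitly.

Bray–Curtis is partitioned into Baselga's turnover (Simpson
dissimilarity, \(\min(b,c)/(a+\min(b,c))\)) and nestedness-resultant
(total minus turnover) components; the additive identity is exact and
is asserted to \(10^{-12}\) in the tests.

# Monmonier barriers

`build_network()` triangulates the occupied-cell centroids (Delaunay),
attaches the chosen dissimilarity to each edge, and records each edge's
dual Voronoi (Thiessen) segment, clipped to the bounding box inflated
by one cell.  `monmonier()` seeds each barrier at the uncrossed edge of
maximal dissimilarity and grows the barrier from both ends of its dual
segment, at each step crossing the adjacent uncrossed edge of greatest
dissimilarity; a tip stops at the network boundary, at a vertex used by
an earlier barrier, or upon meeting its own path.  The original
description leaves stopping and tie rules open; ours are: ties break by
the lowest `(i, j)` cell-index pair (determinism without randomness),
and no edge is ever crossed twice, which makes seed dissimilarity
non-increasing with rank.  Edges whose dual segment is clipped away
entirely act as dead ends.

On `one_river` scenarios (a north–south river crossed by each species
with probability 0.1), the first barrier's crossed edges straddle the
planted river in at least 80% of crossings, across seeds.  A practical
note baked into the benchmarks: at 1° cells the per-cell species
samples are so sparse that many adjacent cell pairs reach dissimilarity
1.0 by sampling noise alone, saturating the seed choice; at 2° cells
(40–100 records per cell) the signal dominates.  Grid resolution must
match record density, which is why the cell size is a front-line
parameter everywhere.

# Parsimony analysis of endemicity

Grid cells (2° by convention) become terminals, species presences
binary characters, and an all-absent hypothetical outgroup roots the
trees — standard PAE practice.  Characters present in every cell are
pruned (logged); singleton presences are kept but flagged as
uninformative.  The desk-scale search is random-addition sequences
refined by branch swapping (SPR by default) retaining all distinct
topologies at the best length; industrial tree-search machinery
(sectorial searches, ratchet, drifting, fusing) is out of scope at this
problem size.  On hundreds of random 6-cell matrices the heuristic
matches an exhaustive enumeration of all 945 seven-terminal topologies
(`exhaustive_search()`, the built-in oracle).  Areas are read from
clades of the strict consensus supported by at least one
non-homoplastic character: presences exactly coincident with the clade
and requiring a single step on every shortest tree.  "Unambiguous
support" could alternatively be read as Bremer-style support; the
synapomorphy reading implemented here is the stricter and more common
one in PAE.

Constrained searches force user-specified cell groups (e.g. candidate
interfluve areas) to be monophyletic: group subtrees are grown
separately and grafted into a skeleton in which each group is a single
placeholder terminal (scored on the union of member presences), so the
constraint holds by construction, then NNI moves filtered to
constraint-preserving ones refine the tree.  On small instances the
constrained length matches monophyly-filtered exhaustive enumeration,
and `extra_steps` (constrained minus unconstrained length) is zero
whenever the constraint is compatible with a shortest tree.

# Classification of composition rasters

The GIS-style unsupervised "maximum likelihood" classifier is a
Gaussian mixture with full covariances fitted by EM, which is its
statistical content.  Initialization is k-means (seeded), degenerate
covariances receive a small ridge with a warning, the log-likelihood
trace is retained and must be non-decreasing (asserted in tests; the
fitted log-likelihood matches a reference mixture implementation to
four decimals), and BIC is reported per group count in 2–11 with
selection left to the user.  `discriminant_test()` samples 100 pixels
per candidate region (uniform, without replacement; overlapping
regions are rejected), fits a linear discriminant model of the axis
scores, and reports both resubstitution and leave-one-out hit
percentages — the validation scheme is a design choice, so both are
given.

# Synthetic benchmarks: what they do and do not show

`scenario_presets()` fixes three study conditions at the scale of a
large tropical basin (extent 35° x 30°, or 20° x 20° for the river
scenario; planted areas are 10° squares, the scale of large
interfluves; species receive Poisson(30) records):

- `three_aoes`: three disjoint planted polygons, 20 endemics each, 100
  widespread species, seed 42;
- `one_river`: one north–south river, crossing probability 0.1 per
  species, 150 species, seed 11;
- `null`: 150 widespread species, no structure, seed 1.

Endemics draw a range centre uniformly inside their polygon and records
from an isotropic normal clipped to the polygon, with spread
log-uniform between 0.3° and the polygon's equivalent radius;
widespread species use 3° to half the window's smaller dimension,
clipped to the extent.  River truncation is a side-of-polyline test on
the range centre with blocked draws redrawn up to a cap; sampling
effort, when supplied as a surface, thins records proportionally.  One
global random stream is consumed in a fixed documented order, so runs
are reproducible byte-for-byte but inserting a species changes
downstream draws — accepted for simplicity.

These generators emulate the statistical structure that matters to the
pipeline — co-occurring restricted ranges, hard river edges, effort
heterogeneity — and nothing else: no environmental gradients, no
phylogenetic structure, no abundance, isotropic ranges only.  Passing
recovery tests therefore demonstrates that the algorithms detect the
structure they claim to detect at realistic scales; it does not
demonstrate that any particular empirical system has such structure,
nor calibrate error rates for real survey data, whose biases (roads,
rivers, museums) are far more structured than Poisson thinning.

Problem sizes used throughout the tests and the acceptance script —
0.25° recovery pixels, 2° dissimilarity grids for the river scenarios,
5–20 ordination starts in repeated-seed loops (100 where a single
definitive fit is reported), 99–999 permutations — were chosen so the
full validation suite runs in minutes on one core while every
qualitative conclusion is unchanged at finer settings.

# Known limitations

- Kernel mass is normalized on the plane; at bandwidths beyond ~2000 km
  spherical curvature makes the "unit mass" reading approximate (the
  categories cap at 2150 km for this reason).
- The category-admission test calibrates congruence against uniform
  random placement; faunas with strong non-endemic geographic structure
  (e.g. hard climatic gradients) will admit more categories than a
  matched null would.
- Ordinary kriging assumes a stationary isotropic variogram; the
  exponential/linear pair covers the monotone cases but not nugget-free
  periodic structure.
- The constrained parsimony search guarantees feasibility, not global
  optimality; it is validated against enumeration only at desk scale.
- `n_effective` in the corrected correlation is an estimate; with very
  few distance classes (tiny rasters) it is noisy, and the test refuses
  to report p-values when the effective sample size drops below 3.
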