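---
title: "Suitability-based human-wildlife conflict mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suitability-based human-wildlife conflict mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucisr)
```

## The model

`lucisr` implements the Land Use Conflict Identification Strategy (LUCIS)
applied to human-wildlife conflict (HWC): conflict is treated as a land-use
conflict, located wherever land that wildlife prefers is simultaneously
preferred for agriculture or human settlement. The pipeline has five
stages.

**1. Decision units.** The landscape is tessellated into square decision
units at two resolutions: 250 m cells wherever land lies within a buffer
(default 2000 m) of developed features (settlements, farms), and 1000 m
cells inside protected areas away from development, where less detail is
needed. A coarse unit is emitted only where the entire 1 km square
qualifies; otherwise it decomposes into fine cells, so the units tile the
extent exactly. All cell membership is decided by cell-center containment
in half-open cells — one stated convention, no double counting.

**2. Criterion scores.** Each leaf of a goal's hierarchy turns one source
layer into a per-unit score on the 1–9 suitability scale (1 least, 9 most
suitable): distance transforms (Euclidean, in the projected metric CRS)
for accessibility and proximity criteria, slope in degrees from the DEM,
majority-class reclassification for land cover, zonal means for
continuous fields, and binary buffer/constraint scores (1 inside, 9
outside) for regulatory rules such as the 300 m cattle-post buffer and
protected-area constraints. Cost-like criteria are inverted so proximity
scores high. Scores stay continuous; rounding to integers before
classification would discard information.

Two flavors of distance criteria are distinguished. *Accessibility*
criteria (roads, boreholes, markets) are landscape-wide gradients,
linearly rescaled between the observed minimum and maximum distance.
*Condition* criteria, which encode "optimize the use of existing
farms/cattle posts", carry a saturation radius (`max_dist_m`, default
5 km in the shipped hierarchies): the score decays linearly from 9 at the
feature to 1 at the radius and stays at the floor beyond. An extent-wide
gradient would make a farm 20 km away look meaningfully better than one
40 km away, which is not what an existing-use condition means; the
saturation form keeps the criterion local and is standard practice in
suitability modeling with decay functions.

**3. Weighted aggregation.** Criteria aggregate bottom-up through a
three-tier hierarchy (sub-objectives → objectives → goals) by weighted
linear combination (WLC), sibling weights summing to one (tolerance 0.01,
since published weight tables are printed at two decimals, e.g.
0.33/0.34/0.33). The shipped trees weight crop farming 0.7 against
livestock rearing 0.3 inside agriculture; livestock carries a
wildlife-condition objective in which predator habitat suitability
(lion 0.50, leopard 0.20, hyaena 0.20, elephant 0.10) enters *inverted*,
depressing livestock suitability where predation risk is high. The
wildlife goal is not a weight tree: per-species habitat-suitability
surfaces (an external ecological input, here synthesized) are combined
with a cell statistic — the unweighted mean by default, maximum
optionally — then zonally aggregated. Only the goal-level composite is
rescaled to 1–9; intermediate composites are left on their natural WLC
scale, which preserves monotonicity and avoids compounding rescale
artifacts (whether intermediate rescaling was ever intended is
undocumented; rescaling once at the top is the cleaner choice).

Weights can be entered directly or derived from pairwise comparison
matrices with the Analytic Hierarchy Process: the normalized principal
eigenvector (power iteration, tolerance 1e-10, at most 1e4 iterations),
with consistency index $CI = (\lambda_{max} - n)/(n - 1)$ and consistency
ratio $CR = CI/RI$ against Saaty's random-index table; $CR \le 0.1$ is
acceptable, larger values flag the judgments as inconsistent without
discarding the result. For $n \le 2$ reciprocity forces consistency and
$CR = 0$.

**4. Preference and conflict.** Each goal's suitability surface is binned
into preference levels 1–3 by Jenks natural breaks with $k = 3$ — the
exact partition of the sorted scores minimizing the within-class sum of
squared deviations (SDCM), with goodness of variance fit
$GVF = 1 - SDCM/SDAM$. The implementation is the Fisher dynamic program
made $O(k\,n\log n)$ by divide-and-conquer over the monotone argmin (the
SSE interval cost satisfies the concave quadrangle inequality), so it is
still the exact global optimum; ties break toward the lowest break
values. Above 50,000 values breaks are fitted on a deterministic evenly
spaced subsample of the sorted data and applied to all values — the
subsample is order-statistics-based, so no random seed is involved.

The conflict overlay applies the literal rules, with WL, AG, HS the
wildlife, agriculture and settlement preference levels:

* high: `WL = 3 AND (AG = 3 OR HS = 3)`
* moderate: `WL = 2 AND (AG = 2 OR HS = 2)`
* low: `WL = 1 AND (AG = 1 OR HS = 1)`

Exactly 5 of the 27 level combinations map to each conflict class and 12
map to none. Note the counterintuitive consequence, preserved
deliberately: mixed-level overlaps such as WL = 3 with AG = 2 match *no*
rule and classify as no conflict, and a missing wildlife preference
always means no HWC. Areas are accounted from true unit polygon areas
(robust to future non-square cadastral units), with shares reported at
integer and one-decimal precision.

**5. Map-removal sensitivity.** Five factor groups shared by the
agriculture and settlement trees — existing land uses, terrain
characteristics, road accessibility, water proximity, development
constraints — are removed one at a time (OAT). Surviving sibling weights
are renormalized proportionally (preserving relative importance; a
single survivor takes weight 1), nodes left childless are pruned with
their weight redistributed the same way, and the whole pipeline is re-run
per scenario, *including* a fresh Jenks fit — refitting is the only way a
removal can move class boundaries. The wildlife surface is an external
input containing none of the five factors, so removal applies to the two
human goals only. Change metrics per class are the area difference (km²)
and the percent change relative to the base class area; a zero base area
with a nonzero scenario area is reported as undefined rather than
infinite. Because every scenario reclassifies the same decision units,
class areas are conserved exactly: removal reallocates land among
classes, never creates or destroys it.

### Factor-group membership

The groups are named after shared concepts, and which criteria they
contain is a modeling decision:

* *existing land use*: existing-farms condition, distance to crop farms,
  existing livestock locations, distance to settlement — every criterion
  whose source is a current human land use. Population density is left
  in place: it is demographic pressure, not a land-use layer.
* *terrain characteristics*: the land-cover + slope sub-trees of all
  goals.
* *road accessibility*: the transport/road-access criteria.
* *water proximity*: the borehole-proximity criteria of the two
  agriculture objectives (the settlement tree has no water criterion).
* *development constraints*: the protected-area constraint criterion in
  every tree.

## The synthetic landscape

Real inputs for this kind of analysis (soil grids, DEM, cadastre,
habitat-suitability models) are typically proprietary or NGO-held, so the
package ships a seeded generator that emulates the layer inventory and
its statistical structure, making every downstream stage testable.

Continuous fields (soil pH, root-zone depth, drainage, DEM, habitat) are
Gaussian white noise smoothed with a separable Gaussian kernel of
standard deviation `field_range_m / 2` — correlation is practically zero
beyond three ranges — then affinely rescaled so the realized mean and
standard deviation match the request exactly. Roads are piecewise-linear
paths crossing the extent; settlements seed at interior road vertices;
cattle posts occupy road-adjacent cells; boreholes are uniform; a
northern block realizes `protected_fraction` exactly. Land cover is a
thresholded random field (four natural classes) overridden to cropland
and built classes where farms and settlements are rasterized, so the
categorical raster and the vector layers never disagree. Population
density is a sum of Gaussian kernels around settlements. One master seed
drives fixed per-layer seed offsets, so adding a layer never perturbs
the others.

The key knob is `farm_wildlife_overlap`: the fraction of farms placed in
the top tercile of the combined habitat surface, operationalizing farms
sitting on a wildlife corridor. Farms are sampled from the chosen habitat
stratum with probabilities decaying in road distance (`exp(-d/2000)`), so
they line up along roads — matching the observed clustering of
development — without collapsing into a single road-nearest patch.
Spreading the farms along all roads is what makes the conflict response
to the overlap knob robust: across replicate seeds, raising the overlap
from 0.1 to 0.9 does not decrease the mean high-conflict area. Defaults
(50 × 50 km at 250 m, 3 roads, 8 settlements, 40 farms of 500 m footprint,
25 boreholes, 15 cattle posts, 35% protected, 2.5 km field range, overlap
0.7) describe a semi-arid agricultural frontier of the Chobe type; none
of them is calibrated to a real region, and distributional realism
(rainfall, species movement, seasonality) is explicitly out of scope.

What passing tests on these scenes shows is therefore *structural*: the
pipeline's invariants (partition, conservation, monotonicity,
determinism) and its responses to controlled changes behave as the model
says they must. It does not show that any particular real landscape
would yield similar class shares.

## Numerical choices and degenerate inputs

* Rasters use `NA` internally for nodata; sentinels only exist on disk
  (ESRI ASCII grid). Nodata propagates through WLC and is never
  interpolated into valid cells by bilinear resampling; categorical
  layers may only be resampled nearest-neighbor.
* A constant input to the 1–9 rescale cannot be anchored at both ends;
  it maps to the midpoint 5 with a warning instead of erroring, so a
  degenerate synthetic layer does not abort a run.
* Zonal majority ties break toward the smallest class code; Jenks ties
  toward the lowest break values; both are deterministic.
* Distances are planar Euclidean in the projected CRS (the data model is
  a metric UTM zone); there is no geodesic path.
* Jenks requires at least `k` distinct values and three distinct scores
  are required for preference binning; fewer is an error, not a silent
  merge.
* The proximity rule for "near developed areas" in unit construction is
  a free parameter (default 2000 m) — the two resolutions are given by
  the design, the buffer is not.

## Problem sizes

The shipped demo runs 200 × 200 cells (40,000 fine-equivalent units,
about 30,000 decision units after coarse merging): a full
suitability–conflict pass takes a few seconds and the six-scenario
sensitivity analysis about a minute on one core. Unit tests run on
smaller scenes (40–60 cells across) chosen so each property is exercised
in seconds; the exactness of the methods does not depend on size.

## Known limitations

* Conflict classes follow the printed rules literally; whether
  mixed-level overlaps (WL = 3, AG = 2) should register as some conflict
  is unknowable from the rule set, and this implementation does not
  reinterpret it.
* The wildlife goal consumes habitat surfaces as given; no habitat
  modeling, validation, or species-specific conflict typing is included.
* Weight-perturbation and variance-based (Sobol) sensitivity are out of
  scope; map-removal OAT was chosen for transparency and low cost.
* The generator does not simulate seasonality, animal movement, or
  empirical Botswana distributions; protected areas are a single block,
  not a reserve network.
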