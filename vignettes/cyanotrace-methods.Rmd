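---
title: "Methods: automated quantification of filamentous cyanobacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated quantification of filamentous cyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanotrace)
```

## The problem

Potentially toxic filamentous cyanobacteria (trichomes of genera such as
*Planktothrix*, *Dolichospermum* or *Aphanizomenon*) are routinely
quantified by settling a fixed water sample in an Utermöhl chamber and
counting filaments under a bright-field microscope. Manual counting is slow
and operator-dependent; automating it is hard because bright-field
micrographs carry a smooth illumination gradient and little absolute
contrast, filaments cross and overlap each other, and debris fragments
trichomes into pieces that must be recognized as one organism.

`cyanotrace` implements a complete pipeline for this problem — denoising,
segmentation, skeleton tracing, spline parameterization, reconnection and
morphometry — together with the model-II regression machinery used to
compare automated against manual estimates, and a seeded synthetic scene
generator that provides ground truth for end-to-end validation.

## Edge-energy preprocessing

The first stage is a discrete 2D convolution of the image $f$ with the two
3×3 Sobel kernels, $g_v$ (vertical contrast) and $g_h$ (horizontal
contrast), recombined as the gradient magnitude

$$H = \sqrt{h_v^2 + h_h^2}, \qquad h_v = f * g_v,\; h_h = f * g_h .$$

$H$ responds to local intensity *change*, so in one operation it removes
both the background gradient (locally almost constant) and the dependence
on absolute intensity. True convolution (index-reversed kernels) is
implemented; because $H$ is a magnitude, the correlation convention would
give the identical result, which the test suite asserts. Boundaries are
zero-padded with same-size output. Zero padding makes the frame border an
artificial maximal edge, so the pipeline zeroes a 2 px border margin of
$H$ before normalizing to $[0,1]$ (`border_margin_px`).

## Segmentation

`binarize()` thresholds the normalized edge-energy image. The default
method is the **triangle (Zack) construction** rather than Otsu: the
histogram of an edge-energy image is one large near-zero background mode
with a long bright tail, and Otsu's between-class criterion then tends to
split the tail rather than separate it from the background (on synthetic
scenes this kept only the strongest few edges). Otsu and fixed thresholds
remain available, as does an optional Gaussian pre-smoothing of $H$
(`presmooth_sigma`, default 1.5 px), which widens and regularizes the
edge band so object outlines close reliably.

Because edges outline objects rather than fill them, `label_objects()`
applies a small morphological closing (radius 2 px) to seal the outline,
fills enclosed holes, smooths boundaries with an opening (radius 2 px;
ragged boundaries otherwise sprout skeleton spurs), labels 8-connected
components and discards components below `min_object_area` (30 px,
< 10 µm² at the default calibration).

Objects are classified in two tiers, following the semantics of the
validation table: an object is *filamentous* when its elongation (skeleton
length / mean width) reaches `min_elongation` (default 5), and a filament
is *of interest* when its length reaches `min_length_um` (default 50 µm)
with a mean width inside `width_range_um` (default 2–12 µm, spanning
common planktic filamentous genera). The length/width gate is applied to
**reconnected curves**, so fragments of an interrupted filament are judged
by the recombined filament, not by the pieces.

Edge-band segmentation dilates every object by a few pixels; the dilation
inflates compact debris relatively more than filaments. For the
filamentous-area statistic (Afil/Aobj) the pipeline therefore uses
dilation-corrected areas (pixels deeper than 3 px in the distance
transform), which on synthetic scenes reduces the bias of the area
fraction from roughly 13 percentage points to about 2.

## Skeleton graphs

Filament centerlines are obtained by topology-preserving Zhang–Suen
thinning (`skeletonize()`, run per object inside its bounding box).
`build_graph()` classifies skeleton pixels under **m-adjacency** — a
diagonal neighbour counts only when neither orthogonal bridge pixel is
set. Plain 8-adjacency creates spurious triangles on thinned skeletons
and with it a junction at almost every direction change; m-adjacency makes
path pixels degree-2 exactly. Endpoints (degree ≤ 1) and junctions
(degree ≥ 3, adjacent junction pixels merged to a centroid node) become
nodes; pixel paths between nodes become edges. Three clean-up passes
follow: spur branches shorter than `prune_px` (8 px ≈ 2.5 µm) are removed,
junction pairs connected by paths of ≤ 6 px are contracted and tiny
self-loops dropped (thinning of blunt caps produces such 2-cycles), and
junction nodes left with two incident edges are spliced out.

Discrete thinning erodes each skeleton end by roughly the local
half-width, and pruning can retract it further. Each free end is therefore
**extended through the mask to the object boundary**: rays are fanned
±40° around the local path direction and the path marches along the ray
that stays longest inside the object (reach credited up to a cap depth, so
body-ward rays cannot win; ties resolve toward the smallest deviation).
After extension a path runs from cap tip to cap tip.

## Spline parameterization and measurement

Each path is parameterized by cumulative chord length and fit with a cubic
least-squares B-spline per coordinate (`fit_spline()`). Interior knots are
placed at chord-length quantiles and doubled in number until the summed
squared residual is within the smoothing budget; the default budget
$n \cdot (0.5\,\text{px})^2$ absorbs pixel quantization noise without
straightening real curvature. `smoothing = 0` requests interpolation;
paths with fewer than four distinct points fall back to a flagged
polyline. Arc length is computed by 10-point Gauss–Legendre quadrature per
knot span (relative error well below $10^{-4}$ on smooth curves).

Because extended paths end at the cap tips of a round-capped ribbon, the
reported filament length subtracts half the mean width per free cap end
(the medial axis of a stadium ends half a width before its tip). Width is
the mean of $2d - 1$ (pixel-centre offset) over distance-transform values
$d$ sampled along the curve. Endpoint tangents are taken as the chord over
the last 12 px of the fitted curve — the analytic boundary derivative of a
least-squares spline wiggles at pixel scale — while curvature uses the
analytic derivatives.

## Reconnection

Interrupted filaments and crossing filaments are recombined by endpoint
matching. For every pair of endpoints on distinct curves the gates are:

* gap ≤ `max_gap_um` (15 µm; debris occlusions are short relative to
  filament length),
* tangent–tangent deviation from straight-through continuation, split
  evenly between the two ends, ≤ `max_angle_deg` (30°; a larger bend
  indicates distinct filaments),
* lateral offset of the two tips perpendicular to the joint axis ≤ 4–6 µm
  (this keeps parallel neighbours apart; the deviation/lateral
  decomposition is used because at short gaps the raw endpoint-to-endpoint
  direction is dominated by pixel-scale lateral tip offset),
* width ratio ≤ `width_ratio_max` (1.8).

Candidates are scored with
$\text{cost} = \text{gap}/\text{gap}_{max} + (\alpha_a+\alpha_b)/(2\alpha_{max}) + |\log w_a/w_b|$
and accepted greedily in cost order; each join refits one spline over the
union of the two point paths (bridging the gap) and the merged curve
re-enters the pool with fresh endpoint geometry. A curve is never joined
to itself. A final *rescue pass* reconsiders pairs that pass the gap and
width gates but fail the angle gates: the pair is accepted when a single
sparse-knot least-squares spline (one knot per 25 px) fits the two end
segments and the bridge with RMS ≤ 1.2 px — smooth continuations fit,
kinked or offset pairings do not. Both sides must contribute at least
20 px of path, so compact debris cannot chain. This least-squares
continuity test is in the same spirit as the spline-based recombination
the pipeline is built around.

The reconnection record counts accepted joins, and break events as
accepted joins plus leftover endpoint pairs that pass the gap gate
(greedily matched by gap), so the joined/events ratio is always ≤ 1.
Branch endpoints that meet at a shared junction have gap 0 and are counted
by the same rule.

## Measurement

`measure_fov()` assembles the per-image report: count and total length of
filaments of interest, the reconnection tally, the number of filamentous
objects and the filamentous area fraction, plus a per-filament table
(length, width, border contact). Lengths are reported in µm via the
calibration (default 0.32 µm/px, 5184×3456 px frames; note that
5184 × 3456 × 0.32² = 1.835 mm², slightly above the nominal 1.82 mm²
quoted for this setup — the discrepancy comes from rounding in the quoted
resolution, and the package always computes from the calibration). CSV
rows round lengths to whole micrometres, matching the integer lengths of
the validation table; full precision stays in the report object.

## Method comparison statistics

`major_axis_fit()` implements Major Axis (model II) regression — the
symmetric line fit appropriate when both variables carry error. With
centered sums of squares $S_{xx}, S_{yy}, S_{xy}$,

$$b = \frac{S_{yy} - S_{xx} + \sqrt{(S_{yy}-S_{xx})^2 + 4S_{xy}^2}}{2S_{xy}},$$

the line passes through the centroid, and $r^2$ is the squared Pearson
correlation. The slope equals the direction of the first principal
eigenvector of the 2×2 covariance matrix, which the tests use as an
independent oracle. The automated estimate is the $y$ axis and the mean
manual estimate the $x$ axis (the reference scatter plots put the
operator error bars on the horizontal axis). Significance is assessed by
a deterministic permutation test of the correlation (9,999 permutations,
fixed internal seed) since no parametric test is implied by the data.
Reported statistics follow the printing convention of two decimals for
slopes and $r^2$ and one for percentages.

The packaged dataset (`validation_table()`) holds the 40-image validation
campaign: 10 fields of view per station at four stations on three Italian
volcanic lakes, with manual counts and total lengths (mean ± sd over four
operators), automated counts and lengths, reconnection tallies,
filamentous-object counts and area fractions. `pooled_summaries()` and
`station_fit_suite()` reproduce the pooled reconstruction rate (83%),
the station mean area fractions (54.5% Caprarola, 27.4% Nemi), the pooled
fraction of filamentous objects that are of interest (19.1% at Nemi), and
the eight station × response fits, whose non-Nemi slopes span 0.96–1.18
with $r^2 > 0.84$. Whether the total-length fits should use per-image
sums or per-filament pairs is ambiguous in the source material; this
package uses the per-image sums that the table provides.

## The synthetic scene generator

`generate_scene()`/`render_scene()` emulate the statistical structure of
the original micrographs at 1/4 linear scale (1296×864 px, 0.32 µm/px;
quarter scale keeps the full test suite fast while preserving per-pixel
geometry — the full-scale frame is one configuration away). Defaults were
chosen once as the study conditions:

* filament lengths log-normal (median ≈ 120 µm, sdlog 0.45) truncated to
  60–320 µm — tens of µm to a few hundred µm per filament, over a
  millimetre of total length per frame;
* widths uniform 3–6 µm, the band of common planktic toxigenic genera;
* backbones are integrated random-walk headings (0.05 rad per 2 px step)
  with arc-like wall steering;
* bright background 0.85 with a planar gradient of amplitude 0.15,
  filament contrast 0.3, additive Gaussian noise sd 0.01, elliptical blob
  distractors (20 by default; hundreds in the heavy-noise regime);
* breaks remove gap + width of backbone arc so the registered gap (uniform
  4–12 µm, inside the 15 µm joining gate) equals the visible gap between
  the two fragment masks;
* crossings are constructed by growing a filament through a point of an
  existing one at an oblique angle.

Scenes are packed under identifiability constraints: backbones keep a
clearance larger than the segmentation dilation so distinct filaments
stay distinct objects, self-approaching walks are rejected, and free
filament tips stay at least 70 px from other tips — a chance end-to-end
alignment within the joining gate would be indistinguishable from a real
break, making the true count ill-posed for any method. Longest filaments
are placed first; on crowded frames the generator falls back to shorter
filaments and, if sequential packing dead-ends, restarts placement from a
seed-derived stream (deterministic). Everything is reproducible from the
seed.

What the generator does **not** emulate: optics (point-spread function,
depth of field), partial focus, intensity texture within trichomes,
coiled or colonial morphotypes, and debris that touches filaments.
Passing the synthetic suite therefore demonstrates the geometry and
bookkeeping of the pipeline, not photometric robustness on real
micrographs.

## Validation results the package computes about itself

The test-suite benchmarks (all regenerated at test time from seeds):

* clean scenes (10 seeds, 10 filaments each): counts recovered exactly,
  median relative total-length error ≈ 0.2–0.3%;
* interrupted scenes (10 seeds, 20 filaments, 10 breaks each): ≥ 80% of
  break events joined (observed ≈ 99%) and counts equal to truth in at
  least nine of ten scenes;
* crossing scenes: straight-through branch pairing resolves an X into the
  two underlying filaments;
* heavy blob noise (filamentous area fraction tuned to ≈ 25%): the area
  fraction is recovered within a few points of truth, but counting
  over-reports as debris chains occasionally imitate filaments — the same
  degradation the noisiest validation station shows, where the
  manual-automated agreement drops to a slope of 0.75 at $r^2 = 0.72$.

## Known limitations

* Thresholding is global; strongly non-uniform noise would need local
  thresholds.
* The greedy cost-ordered matcher is deterministic and near-optimal for
  sparse candidates but is not a global assignment; it is documented as
  replaceable.
* Width is a single mean per filament; tapering trichomes are not
  profiled.
* Genus classification, biovolume and per-mL concentrations are out of
  scope.
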