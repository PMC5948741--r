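---
title: "Methods: point-cloud and image-based weed phenotyping in phenocloud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-cloud and image-based weed phenotyping in phenocloud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocloud)
```

`phenocloud` measures single young weed plants from the outputs of a
low-cost photogrammetric (SfM‑MVS) reconstruction: it cleans and metrically
calibrates the dense point cloud, extracts plant height and leaf area,
quantifies ground-truth leaf area from overhead images of the detached
leaves, and validates estimates against truth with regression statistics.
This vignette documents the models, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## The synthetic study generator

No public dataset pairs SfM‑MVS weed reconstructions with measured traits,
so the package carries a parametric generator whose plants have *exactly*
known traits. Both morphotypes are assembled from surfaces with closed-form
one-sided areas:

* **Dicot leaves** are flat ovate sheets with half-width profile
  $w(t) = \tfrac{W}{2}\,6.75\,t(1-t)^2$ along the midrib
  ($t \in [0,1]$; the profile peaks at $t = 1/3$, giving the egg shape of a
  broad-leaved weed), folded about the straight midrib. The fold and the
  rigid placement on the stem are isometries, so the one-sided area is
  exactly $0.5625\,L\,W$.
* **Monocot leaves** are ruled straps over a sagging circular arc
  (initial elevation ≈ 55°, total bend ≈ 70°): the unit-speed leaf axis lies
  in a vertical plane and the rulings are horizontal and orthogonal to it,
  so the area element is exactly $w(s)\,ds$ with taper
  $w(s) = W(1-s/S)^{0.7}$ and total area $W S / 1.7$. A 10:1 minimum
  length-to-width ratio is enforced — the thin strap geometry is precisely
  what makes monocots hard to reconstruct.
* The **stem** is an open vertical tube of radius 0.15 cm whose length *is*
  the height trait; its lateral mesh area is recorded separately so leaf
  area can be isolated from a whole-plant triangle sum. The apical stem
  segment is left leafless (insertions span 25–80 % of the height for
  dicots, 30–95 % for monocots), as in young weeds, which also keeps the
  stem tip the highest point near the axis.

Defaults mirror a field study of young weeds: heights 4–30 cm; a basal
dicot leaf ≈ 0.75 of the height (a 12 cm, 6-leaf dicot carries ≈ 107 cm² of
leaf, the regime of a mid-sized broad-leaved weed); ten plants per species
group, with two dicot groups of contrasting stature (8–18 cm and 4–11 cm)
and one monocot group (10–30 cm).

Tessellation uses ~100 sections per leaf; because each dicot half-sheet is
planar and the monocot rulings are exact, the triangle sum agrees with the
analytic area to about $10^{-4}$ relative (tested at 0.1 %).

### Degradation model

`sample_point_cloud()` draws area-weighted uniform surface samples
(default 50 points/cm², a compromise between MVS-like density and the
quadratic cost of neighbourhood queries; the synthetic experiments below
state their sizes) and then applies, in order:

1. **leaf-tip dropout** — each leaf loses the distal part of its area, the
   samples beyond the axis position where the removed fraction begins
   (closed-form inversion of the width-profile integral). The removed
   fraction per leaf is $U\!\big(f(1-j),\,f(1+j)\big)$ with mean `f =
   tip_dropout_fraction` and spread `j = tip_dropout_jitter` (default 1).
   The jitter matters: a *constant* fraction only rescales leaf area and
   cannot degrade R², whereas reconstruction loss in the field varies with
   leaf orientation and overlap, which is what spreads the per-plant errors
   of monocots. `j = 0` gives the deterministic behaviour used in unit
   tests.
2. **ghost points** — a fraction of samples displaced 2–10 cm along the
   local face normal (random sign), mimicking MVS ghost geometry near
   surfaces rather than uniform box noise.
3. **surface noise** — isotropic Gaussian displacement (default
   σ = 0.1 cm).

`degrade_mesh()` plays the role of the meshing step (mesh reconstruction
itself is out of scope): it rebuilds each leaf truncated at its dropout
threshold — so the retained area is known *exactly* — and warps the whole
surface with a smooth low-frequency displacement field (amplitude 0.05 cm,
wavelength 5 cm). The warp tilts rather than roughens; per-vertex jitter
would inflate triangle-sum areas through roughness, which real meshes do
not show.

`build_scene()` embeds the cloud in a circular ground patch at $z = 0$
(25 points/cm²), places three 10 cm markers flat on the ground in a
triangle of radius 12 cm, divides all coordinates by the true scale (so the
export is "uncalibrated"), and optionally adds neighbour plants whose
points all lie beyond an exclusion radius; the shared ground keeps the
scene connected, which is why plant separation needs a bounding box and not
a filter.

What the generator does **not** emulate: occlusion-dependent sampling
density, colour gradients and shadows, leaf overlap merging surfaces into
solid blobs, registration error between views. Passing tests therefore
demonstrate that the *measurement* chain is correct and robust to the
modelled defects, not that any SfM system achieves these accuracies in the
field.

## Cloud processing

* `remove_statistical_outliers()` — the standard k-NN rule: remove points
  whose mean distance to their `k = 12` nearest neighbours exceeds the
  global mean by `std_ratio = 2` standard deviations. The threshold
  carries a relative $10^{-12}$ guard so floating-point jitter on
  homogeneous clouds never triggers removal. Repeated application is a
  fixed point once the outliers form a separated population (the tested
  property); on continuous noise distributions a second pass can trim
  further, as with any re-estimated threshold.
* `grid_distance_filter()` — removes points more than 0.5 cm from the
  reconstructed surface; points at exactly 0.5 cm are kept (the rule
  removes points *more than* 0.5 cm out, hence a closed interval). The
  reference surface is an explicit mesh when one exists; otherwise — the
  usual situation straight after dense reconstruction — the
  total-least-squares plane through each point's `k = 12` nearest
  neighbours (the point excluded). Both geometries are exposed because the
  choice is genuinely open; the threshold is metric, so the filter refuses
  uncalibrated clouds.
* `crop_bounding_box()` — closed-interval box retention, the stand-in for
  manual cleaning of neighbouring plants.
* `fit_ground_plane()` — 200 seeded 3-point consensus hypotheses scored by
  inliers within 0.2 cm, refined by a total-least-squares fit on the best
  inlier set, normal oriented toward the plant side.
* `calibrate_scale()` — per-marker ratio true length / observed separation;
  cm-per-unit is the unweighted mean (all markers share the same true
  length, so weighting would change nothing) and the spread is reported as
  `residual_pct`. `apply_scale()` flips the cloud's unit state and refuses
  double application.

The pipeline order is statistical filter → calibrate → grid filter → crop →
ground fit → traits: the grid filter's threshold is metric and must follow
calibration, while the k-NN statistical filter is unit-free and runs first.

## Trait extraction

**Height** follows the cylindrical stem convention: the length of a
cylinder extended from the stem base to the end of the main stem, measured
*normal to the fitted ground plane* (not along global z) so tilted terrain
behaves correctly. The stem is located as the densest 1 cm column of
*near-ground* points (a 0.5–2.5 cm slab above the plane — above surface
noise, below the canopy); binning all points instead can lock onto a leaf
column on large-leaved plants. The base point is the lowest point within
`stem_radius_cm = 1` of that axis; its ground offset is subtracted, but
clamped at zero when negative — a stem cannot start below the soil, and
subtracting the minimum of many noisy draws would bias every height up.
The cylinder radius default (1 cm) is the package's own convention: wide
enough to tolerate slightly tilted stems, narrow enough to exclude leaf
tips. `method = "max_extent"` (the maximum ground distance over the whole
cloud) is reported alongside as the fallback for strongly tilted or curved
stems, which the vertical cylinder truncates by roughly the cosine of the
tilt.

**Leaf area** is the triangle sum over the mesh. Leaves here are open
single sheets, so the sum counts each surface once; for closed thin-solid
meshes `two_sided_input = TRUE` halves it. The sum includes the stem tube —
the field protocol images detached stems together with the leaves — so
validation compares against leaves + stem; the generator records both
components so either convention is testable.

## Image-based leaf area

The detached-leaf procedure: real-valued linear RGB index (kept unclipped —
8-bit clipping destroys the bimodality that Otsu needs when coefficients
are negative), Otsu's threshold over 256 equal-width bins with class
statistics accumulated from the raw values (so the result equals an
exhaustive search over all bin edges; ties go to the smallest threshold),
foreground = index **above** the threshold (the vegetation index is built
so plants come out bright; the binary display polarity is irrelevant to the
count), and pixel-to-cm² conversion by a black 100 cm² reference square
detected in the *raw* image by darkness (max channel ≤ 40) and bounding-box
fill ratio ≥ 0.9 with 4-connected components — the square is not green, so
it must not be found through the vegetation index, and the squareness test
rejects thin dark scale bars. One guard handles the degenerate scene: in a
detached-leaf layout the white background is always the majority class, so
a "bright" class covering more than half of the non-square pixels means
there is no vegetation to separate (e.g. a square-only image) and the area
is 0.

`render_leaf_layout()` provides the synthetic counterpart: leaves flattened
isometrically (both leaf forms are developable, so silhouette area equals
one-sided area exactly), shelf-packed without overlap, rasterised at
pixel centres in seeded green hues next to a square of exactly
`round(area · px_per_cm²)` pixels. Rasterisation at 20 px/cm leaves
sub-percent area error, which is the error floor of the 2D pipeline.

## Validation statistics

Estimates are regressed on actual values (actual on the x-axis), with
Pearson r, R² (= r²), RMSE, and mean percentage errors reported *both*
signed (MPE, negative = systematic underestimation) and absolute (MAPE) —
field reports sometimes print signed values under an "absolute" heading,
and keeping the two apart is the only way error tables stay interpretable.
Slope p-values are descriptive output (flagged at p < 0.01); per-group
regressions are independent and no multiplicity correction is applied.

## Synthetic experiments and their sizes

The acceptance experiments (also in `scripts/acceptance.R`) use: 30 dicots
across the full 4–30 cm height range through the complete scene pipeline
(σ = 0.1 cm noise, 2 % ghost points, random true scales 0.5–2) for height;
10 dicots vs 10 monocots with mean 5 % tip loss applied to monocots only
for the leaf-area ordering; 20 rendered layouts at 20 px/cm for the 2D
pipeline; 200 seeded random images for the Otsu-vs-exhaustive identity.
Typical outcomes: height MAPE under 1 % with R² above 0.999; dicot
leaf-area R² above monocot R² with monocot MPE ≈ −3 to −4 % — reproducing
the qualitative dicot-over-monocot accuracy ordering reported for field
reconstructions, where lost end-details on thin curved leaves degrade both
the area estimate and its consistency.

## Numerical choices and known limitations

* Thresholds are closed intervals wherever the rule says "more than".
* All randomness flows through explicit integer seeds
  (`withr::with_seed`); identical configurations yield byte-identical
  outputs, and every pipeline run writes a provenance block (config hash,
  package version, seed).
* The exhaustive-search Otsu is $O(n + b)$ per image; kNN queries use a
  grid-hashed exact search (Rcpp); point-to-mesh distance is brute force
  over triangles, fine for the mesh sizes here.
* The cylindrical height method assumes a roughly vertical stem; strongly
  curved monocot stems are truncated (hence the max-extent fallback and
  the worse monocot height accuracy).
* Synthetic morphotypes are stand-ins with the right size, aspect and
  failure modes, not replicas of any species' leaf geometry.
* 3D colour-based plant/soil segmentation, mesh reconstruction from
  points, stem diameter, leaf counting and biomass models are out of
  scope.
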