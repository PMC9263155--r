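---
title: "Reconstructing volumetric coagulation necrosis from rotated MR thermometry slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing volumetric coagulation necrosis from rotated MR thermometry slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoRecon)
```

## The acquisition model

A microwave-ablation applicator defines a fixed axis in space. A standard
2D gradient-echo slice (256×256 px at 1.0×1.0 mm in-plane, 5 mm thick,
~1.1 s per image) is rotated about that axis in `n` uniform steps of
`180/n` degrees (default `n = 8`). Because every slice plane *contains*
the axis, one slice samples two angular half-planes (`θ` and `θ + 180°`),
so the fan provides `2n = 16` half-planes spaced 22.5°. All package
geometry builds on three conventions:

* world coordinates in mm, right-handed, voxel positions at voxel
  *centers* (the NIfTI convention); the applicator axis is parallel to the
  grid z-axis at in-plane position `(x_c, y_c)`;
* a slice at angle `θ` maps pixel offsets `(u, v)` to
  `(x_c + u·cosθ, y_c + u·sinθ, v)`; `u = 0` lies on a pixel column, so
  every slice shares the axis column exactly;
* cylindrical angles are computed with the standard two-argument
  arctangent of `(y − y_c, x − x_c)` and mapped to `[0, 360)`; a point on
  the axis gets `θ = 0` by convention. (The one-argument fraction form
  sometimes written for this transform is not total; any fixed reading
  only rotates the angular origin, so the standard form is used
  throughout.)

Tissue is declared coagulated by the critical-temperature model: a voxel
is necrotic once its temperature reaches a threshold `τ`, with `τ`
expected in 50–60 °C for bio-protein phantoms, whose pH inhomogeneity
makes the effective threshold vary with direction. Cumulative dose models
(CEM43, Arrhenius) are out of scope by design.

## Thermometry and threshold policies

PRFS thermometry converts a phase-image pair to temperature,

`ΔT = wrap(φ_t − φ_ref) / (2π · γ·1e6 · α·1e−6 · B0 · TE)`,

with defaults `α = −0.01 ppm/°C`, `γ = 42.58 MHz/T`, `B0 = 1.5 T`,
`TE = 3.69 ms` (all configurable; the wrap keeps the difference in
`(−π, π]`, which at these constants is unambiguous up to ±212 °C). Masks
are produced by inclusive thresholding `{T ≥ τ}` inside a 60×60 mm region
of interest around the applicator, followed by largest-connected-component
filtering (8-connected in 2D, 26-connected in 3D — the most permissive
standard choice; equal-size ties resolve to the component containing the
lexicographically smallest pixel, making results order-independent).

Four policies choose `τ` per orientation:

* **global** — one configured value everywhere;
* **median** — the median of the eight per-orientation Dice-optimal
  thresholds, applied everywhere; robust to single unrealistic optima;
* **local** — each orientation keeps its own optimum;
* **ground_truth** — thresholds are bypassed; the input masks are the
  ground-truth segmentation resliced into the acquisition fan (the
  perfect-input condition).

The per-orientation optimum scans `τ` from 0 to 100 °C at 0.5 °C steps
(below the ±1 °C accuracy of the acquisition) and maximizes Dice overlap
against the corresponding resliced ground-truth plane, breaking ties
toward the larger threshold. One consequence of the tie rule worth
documenting: when the reference mask covers everything, every `τ` up to
the image minimum is optimal and the *largest* such `τ` is returned.

The temperature-interpolation baseline supports only the global and median
policies: it estimates necrosis on the reconstructed volume, not on
individual input slices, so per-orientation thresholds and mask input do
not apply to it.

## Outlier rejection

Interventional series occasionally contain single slices with very low
SNR whose thresholded area explodes. Under the assumption that the
necrosis only ever grows, the relative growth
`ΔA = |A_t − A_prev|·100/A_prev` of each orientation's denoised mask area
is compared against the most recent *accepted* frame of the same
orientation; `ΔA > 80%` (strict) flags the slice, which is then excluded
from the current reconstruction but kept in the growth log. Comparing
against the last accepted frame rather than the raw predecessor prevents
a single corrupted frame from also condemning the healthy frame after it.
The 80% default is exposed as a parameter. The geometric backends run
behind this filter; the interpolation baseline runs unfiltered, as
originally conceived, which is exactly what the robustness comparison
measures.

## The four backends

**Temperature interpolation.** A population map is precomputed from
geometry alone: each voxel's cylindrical angle is bracketed by its two
nearest half-planes (wrapping 360→0) and given convex weights. The
weights are assigned so that the *nearer* partner receives the *larger*
weight (`w_near = 1 − Δθ_near/Δθ_pair`); the printed form of this weight
in the source literature assigns the nearer plane the smaller weight,
which would make the reconstruction discontinuous across every acquired
plane, so the labels are swapped here and a voxel exactly on a plane takes
that plane's temperature. `I_w` is a binary inside-ROI indicator (60 mm
cylinder). Partner temperatures are sampled nearest-neighbor in `(r, z)`.
The blended volume is thresholded at the policy's single value and
component-filtered in 3D.

**Delaunay / convex hull.** Necrotic pixels of all accepted masks become
world points (the shared axis column deduplicated; interior pixels may be
dropped — they can never contribute to a convex hull). Bowyer–Watson
insertion maintains a valid Delaunay tetrahedralization: all tetrahedra
whose circumsphere contains the new point are carved out and the cavity
boundary is fanned to the point; super-tetrahedron cells are removed at
the end, and the faces occurring exactly once form the convex hull. A
voxel is necrotic iff its center passes the half-space test against every
hull face (inclusive, tolerance 1e-3 mm). Numerical robustness on
voxel-lattice data (massively cospherical) comes from three measures: a
deterministic ~1e-6-relative jitter (fixed internal seed — a reproducible
symbolic perturbation far below voxel size), randomized insertion order,
and restriction of each insertion cavity to the face-connected component
containing the point, which defuses the enormous circumspheres of
near-degenerate slivers.

**MVEE.** Khachiyan's algorithm on the lifted dual weights solves the
minimum-area enclosing ellipse per axial level (tolerance 1e-4 on the
weight update, ≤1000 iterations, deterministic). The final shape matrix is
rescaled so the farthest point lies exactly on the boundary, making the
enclosure exact while changing the area only at the order of the
tolerance. Minimizing the ellipse area corresponds to *maximizing*
`det(A)` of the shape matrix (area ∝ 1/√det A); a sign-flipped objective
is sometimes printed for this optimization, but "smallest volume" fixes
the intent. Levels with fewer than 3 distinct points, or with collinear
points, are flagged degenerate and left empty. Rasterization marks pixel
centers with quadratic form ≤ 1 (inclusive, 1e-9 slack for round-off).

**Closed splines.** Per level, the outermost necrotic point of each
half-plane (radial maximum per slice row) is a contour vertex — one
sample per angular direction, guaranteeing a simple loop for star-shaped
regions. Vertices are sorted by ascending `θ`; ties resolve by ascending
radius, then input order. A *periodic cubic interpolating B-spline* is
passed through the vertices by solving the cyclic tridiagonal system
`(C_i + 4C_{i+1} + C_{i+2})/6 = V_i` (uniform parameterization), and
evaluated with de Boor's recursion; "closed cubic Bézier curve via de
Boor" conflates two spline families, and the periodic interpolating
B-spline is the only reading that is simultaneously closed, smooth,
interpolating and de Boor-evaluable. The curve is densely sampled (edge
length below half a voxel) and pixels are filled by Sunday's
winding-number test, with pixel centers exactly on an edge counted inside
(consistent inclusivity with the other backends).

## The synthetic phantom simulator

The simulator emulates the *level sets* of an ex vivo bio-protein phantom
ablation, not its physics — every backend consumes thresholded masks, so
only the iso-contours must be realistic:

* **Necrosis**: an ellipsoid centered on the axis with semi-axes
  `(a, c) = (10, 20) mm` at the end of a 900 s treatment (a 2×4 cm zone,
  typical of a 36 W / 15 min MWA), growing as `(t/t_end)^0.5` — monotone,
  never shrinking.
* **Temperature**: `T = T_base + (T_peak − T_base)·exp(−k(θ)·ρ²)` in
  scaled elliptic radius ρ, with `T_base = 20 °C` (room-temperature
  phantom), `T_peak = 90 °C`, and `k(θ)` chosen so that thresholding at
  the direction-dependent threshold `τ(θ)` reproduces the ground-truth
  ellipsoid exactly up to voxelization. `τ(θ)` interpolates the eight
  per-orientation thresholds periodically (period 180°, so both
  half-planes of a slice share one threshold), drawn uniformly from
  50–60 °C under the phantom seed.
* **Noise**: 1 °C inside the ROI (the stated temperature accuracy), 3 °C
  extra outside it (air background).
* **Heat sink**: a PVC-like tube of 7 mm outer diameter (5 mm lumen +
  1 mm wall) running perpendicular to the applicator axis, crossing the
  zone at a configurable in-plane offset and height. The ground truth
  subtracts the cooled sheath (default radius 5 mm around the tube line);
  the temperature model multiplies the excess by a linear ramp that is 1
  at and beyond the cooling radius and 0 inside it (1 mm transition), so
  the thresholded field and the ground truth agree up to one transition
  width. The perpendicular orientation matters: it makes the dent local in
  z, so the convex hull bridges it across slices — the failure mode the
  adaptability comparison quantifies. A tube parallel to the axis would
  instead carve a z-uniform channel that disconnects the outer rim of
  every slice mask, an artifact real phantoms do not show.
* **Outlier slices**: scheduled `(orientation, timestamp)` pairs have
  their noise sd multiplied by 200. At sd ≈ 200 °C the slice is
  temperature garbage of the kind a zero-SNR phase difference produces;
  the thresholded speckle percolates (8-connectivity) and the denoised
  area reliably inflates far beyond 80% of the previous frame. The
  inflation ceiling is bounded by the ROI: with symmetric noise at most
  ~half the ROI can exceed threshold, which is why the default zone size
  leaves ample headroom between the pre-final area (~565 mm²) and that
  ceiling (~1600 mm²).
* Everything is deterministic in the phantom seed; per-slice noise
  streams derive from (seed, timestamp, orientation).

What the simulator does *not* emulate: bioheat physics (no perfusion
term, no diffusion transients), MR artifacts other than iid noise (no
ghosting, B0 drift, motion), partial-volume effects of the 5 mm slice
thickness, sub-lethal transition zones, and the surface irregularity of
manually segmented real necroses. Passing tests therefore demonstrate the
geometric and statistical behavior of the reconstruction algorithms under
controlled conditions, not clinical performance. The last gap is visible
in one comparison: on resliced ground-truth input the convex hull of a
perfectly ellipsoidal phantom is nearly optimal, so the Delaunay backend
scores on par with the per-slice methods here, whereas on real, bumpier
segmentations it trails them.

## Evaluation

Dice similarity `2|A∩B|/(|A|+|B|)` (both-empty = 1 by convention, logged
when triggered), group mean ± the 95% standard-error half-width
(`1.96·sd/√n` by default; a t-quantile variant is available — both
readings of "SEM at 95% confidence" are offered). The a-priori-knowledge
comparison subtracts the known vessel mask from a reconstruction and
reports the removed volume, `|recon ∩ vessel|` in ml, as the
false-positive vessel volume. `runExperiment()` drives phantom × method ×
policy factorials and can include or exclude corrupted phantoms, mirroring
with/without-outlier robustness comparisons. ANOVA and post-hoc testing on
the per-phantom values are deliberately left to standard statistics
packages; the report exposes the raw per-phantom rows.

## Problem sizes and runtime

The defaults reproduce the acquisition conditions (256³ mm volume, 256²
slices). The test-suite and acceptance studies run the same code on
smaller grids chosen to keep a full multi-phantom factorial comfortable on
one CPU: 48³–64³ for unit and cohort tests, 96³ for the perfusion cohort,
and a 128³ noiseless recovery case with a (15, 30) mm zone for the
fine-resolution check. Grid size only changes voxelization granularity;
no algorithm parameter depends on it.

## Known limitations

* The applicator axis must be parallel to the grid z-axis; oblique axes
  and non-uniform angular sampling are out of scope.
* The spline contour rule (radial maximum per half-plane) assumes
  star-shaped level sets; deeply folded shapes would need a boundary-walk
  contour and self-intersection handling.
* The Delaunay backend is intentionally convex — concave deformation is
  precisely what it cannot represent.
* `cmdReconstruct` consumes temperature slice series; phase-pair series
  are supported through `prfsTemperature()`/`synthPhasePair()` in code.
* Real acquisitions deposited in public archives can be evaluated by
  converting each orientation's time series to the slice-series directory
  layout (2D NIfTI + `series.yaml` with angle, timestamp, spacing) and the
  post-treatment segmentation to a NIfTI volume, then running the
  `reconstruct` and `evaluate` subcommands per phantom; the group means of
  the per-phantom Dice values are then directly comparable with published
  per-method accuracies. This path is documented here but is not part of
  the automated suite, which is fully synthetic.
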