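# ThermoRecon

Volumetric reconstruction of thermal-ablation coagulation necrosis from a
sparse fan of 2D MR thermometry slices.

## The problem

During minimally invasive microwave ablation (MWA), clinicians need to know
— live, during the intervention — which tissue has already been destroyed.
MR thermometry with the proton resonance frequency shift (PRFS) method
delivers 2D temperature maps in about a second per slice, but a single
plane cannot show the 3D coagulation zone. One practical acquisition scheme
rotates a standard gradient-echo slice about the ablation applicator's main
axis, so that *n* orientations (typically 8, spaced 180/8 = 22.5°) sample
the volume as 2·n angular half-planes. The task is to reconstruct a full 3D
necrosis map from those sparse rotated slices, robustly against low-SNR
outlier slices and heat-sink effects from nearby vessels.

ThermoRecon implements and compares four reconstruction backends:

* **Temperature interpolation** — the volumetric baseline: each voxel's
  temperature is a convex blend of its two bracketing half-planes,
  `T_i = I_w (w1 T_left + w2 T_right)` with angular-proximity weights
  (`w1 + w2 = 1`), followed by critical-temperature thresholding of the
  reconstructed volume.
* **Delaunay / convex hull** — necrotic voxels from all slices form a 3D
  point cloud; an incremental Bowyer–Watson Delaunay triangulation yields
  the convex hull, whose interior is voxelized.
* **MVEE** — per axial slice perpendicular to the applicator, the
  minimum-volume (minimum-area) enclosing ellipse of the necrotic points is
  fit with Khachiyan's algorithm: minimize the ellipse area subject to
  `(P_i − c)ᵀ A (P_i − c) ≤ 1`, with center/radii/rotation recovered from
  the SVD of `A` (`r_i = 1/√σ_i`).
* **Closed splines** — per axial slice, the outermost necrotic point of
  each angular half-plane is taken as a contour vertex, vertices are sorted
  by cylindrical angle `θ = atan2(y − y_c, x − x_c)`, a *closed periodic
  cubic interpolating B-spline* is passed through them (evaluated with
  de Boor's recursion) and the interior is filled with Sunday's
  winding-number test. This is the only concave backend: vessel dents are
  followed instead of bridged.

Around the backends the package provides PRFS phase-to-temperature
conversion, 60×60 mm ROI handling, connected-component denoising, four
threshold policies (global / median / local / resliced-ground-truth input),
relative-growth outlier rejection (`ΔA = |A_t − A_{t−1}|·100/A_{t−1}`,
flagged when `ΔA > 80%`), a fully synthetic bio-protein phantom simulator
(growing ellipsoidal necrosis, per-orientation coagulation thresholds in
50–60 °C, heat-sink vessel tubes, scheduled low-SNR outlier slices), and a
Dice/SEM evaluation suite. Volumes are exchanged as NIfTI; slice series as
2D NIfTI files with a YAML sidecar.

Intended users: researchers in interventional MR imaging and medical image
analysis who want a self-contained, testable reference implementation of
the four reconstruction strategies and a simulator to stress them.

## Worked example

```r
library(ThermoRecon)

spec <- phantomSpec(gridShape = c(64, 64, 64),
                    vessel = list(center = c(8, 0)),  # heat-sink tube
                    noiseSd = 1, seed = 42)
res <- reconstructPhantom(spec,
                          c("interpolation", "delaunay", "mvee", "splines"),
                          thresholdPolicy("median"))
for (m in names(res))
  cat(sprintf("%-14s DSC %.3f   vessel FP %.3f ml\n",
              m, res[[m]]$dsc, res[[m]]$fpMl))
```

```
delaunay       DSC 0.919   vessel FP 0.270 ml
mvee           DSC 0.930   vessel FP 0.025 ml
splines        DSC 0.908   vessel FP 0.000 ml
interpolation  DSC 0.934   vessel FP 0.000 ml
```

`DSC` is the Dice overlap of the reconstruction with the analytic ground
truth of the phantom; `vessel FP` is the reconstructed volume that falsely
intrudes into the vessel tube (the a-priori-knowledge comparison). The
convex-hull backend bridges the heat-sink dent across slices — largest
false-positive volume — while the concave spline backend and the
temperature interpolation follow it.

A command-line front end covers the same pipeline from the shell:

```sh
ablrecon=$(Rscript -e 'cat(system.file("cli", "ablrecon", package = "ThermoRecon"))')
Rscript "$ablrecon" simulate    --config sim.yaml
Rscript "$ablrecon" reconstruct --config rec.yaml
Rscript "$ablrecon" evaluate    --config ev.yaml
```

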