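---
title: "Methods: prone-to-supine breast deformation and density analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prone-to-supine breast deformation and density analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Ultrasound shear-wave elastography measures breast tissue stiffness as a
shear-wave speed (m/s) with the patient supine; MR imaging measures
volumetric breast density (the fibroglandular-tissue fraction) with the
patient prone. Relating a stiffness measurement to the density of the *same*
tissue region therefore requires deforming the prone MR anatomy into the
supine configuration. `mammodef` implements that full chain: tissue
segmentation on the prone volume, biomechanical prone-to-supine deformation
through an intermediate zero-gravity state, ultrasound-equivalent ROI
placement on the deformed volume, and the cohort-level correlation analysis
between stiffness and whole-breast / local percent density.

Patient image data for the original study are not publicly deposited, so the
package ships a first-class synthetic-data module: image phantoms with known
tissue ground truth, and cohort tables matching the study's printed summary
statistics. Every downstream stage is testable against these.

# Synthetic phantoms

`generate_phantom()` builds a piecewise-constant two-tissue T1-weighted-like
volume: a hemiellipsoidal breast (default semiaxes 50 x 40 x 50 mm,
about 210 cm^3 — a modest breast kept at desk scale; 2 mm isotropic voxels on
a 64 x 48 x 64 grid) attached to a posterior chest slab, with a retroareolar
fibroglandular (FGT) core. The FGT region is an ellipsoidal neighborhood of a
point 35% of the anterior semiaxis in front of the chest wall, thresholded at
the quantile of its ellipsoidal radius that yields the requested percent
density — the construction is therefore exact to one voxel for any target in
[0, 100]%. Fat is bright (200) and FGT dark (80), as on T1-weighted images;
a fixed degree-2 polynomial multiplicative bias field (default +/-20% peak)
and additive Gaussian noise (default SD 12, i.e. 10% of the 120-unit class
contrast) complete the image. The nipple ground truth is the anterior-most
breast-surface point on the mid-sagittal slice.

What the phantom deliberately does **not** emulate: Rician noise statistics,
partial-volume mixing, scattered FGT morphology, skin, or pectoral-muscle
anatomy. A green segmentation test therefore establishes correctness of the
algorithmic chain on smooth two-class anatomy, not clinical-grade accuracy.

# Synthetic cohorts

`sample_cohort()` draws latent (age, breast volume, whole density, local
density, stiffness) from a multivariate normal whose means, SDs and pairwise
correlations default to the study's printed values: stiffness 2.3 +/- 0.8
m/s, breast volume 584.4 +/- 170.4 cm^3, FGT volume 72.7 +/- 31.3 cm^3,
whole density 13.1 +/- 5.8%, ROI depth 1.41 +/- 0.38 cm, r(age, density) =
-0.56, r(age, stiffness) = 0.29, r(volume, stiffness) = -0.14, r(density,
stiffness) = -0.09, r(local density, stiffness) = -0.12.

Three structural choices deserve explanation:

* **FGT volume is derived, not drawn.** The record invariant
  `whole density = 100 fgt / volume` makes FGT the product of two latents.
  Its printed mean then *over-determines* the unprinted volume-density
  correlation: `cov(d, v) = 100 E[fgt] - E[d] E[v]`, giving r = -0.390 with
  the printed means. We use that value (physiologically sensible — larger
  breasts are fattier) rather than an independent default of 0, which would
  misplace the FGT mean by ~4 cm^3.

* **Repeat-noise disattenuation.** Each subject receives 3-5 stiffness
  repeats `s (1 + eps)`, with per-subject noise SD drawn from a gamma
  distribution (shape 2, mean 12.7%) and inflated by the small-sample factor
  `1 + 1/(4k)` so the expected *sample* CV matches the subject's CV. The
  reported stiffness is the repeat with the highest "dense-appearance" score
  (the score is local density plus noise, emulating selection of the
  most-dense-looking ROI; because the score is independent of `eps`, the
  selection is unbiased in stiffness). The observed stiffness then carries
  the repeat noise, so the *latent* stiffness SD is set to
  `sqrt(sd^2 - mean^2 m2)` (with `m2` the closed-form mean-square effective
  CV) and the stiffness row of the correlation matrix is inflated by
  `sd/sd_latent`. The printed mean, SD, correlations and CV are then all
  recovered as *observed* statistics — the module's contract.

* **Clipping.** Stiffness and percent densities are clipped below at 0.1
  (m/s, %); fewer than ~1% of draws are affected and the induced mean shift
  (~0.03 pp for density) is far inside every tolerance. Repeat counts are
  3/4/5 with weights 0.6/0.3/0.1 ("in most patients, three locations").

Remaining unprinted values: age SD 13 y (printed range 24-78 spans ~4 SD),
local density 25 +/- 11% (about twice whole density, as in the two printed
case examples), age-local-density correlation -0.28 (half the age-whole
trend, consistent with the assumed 0.5 whole-local coupling).

# Segmentation

`exclude_chest()` takes foreground voxels above a two-threshold (3-class)
Otsu cut — the three classes being air, dark FGT and bright fat; a plain
2-class Otsu can land *between* the tissue classes and clip FGT — keeps the
largest 6-connected component, and removes the chest (a supplied 3D mask, or
a 2D mid-slice mask propagated slice-by-slice, each slice initialized from
its neighbor). The original template-registration chest segmentation is
deliberately out of scope; phantoms carry chest ground truth.

`bias_correct()` fits a degree-2 polynomial to the log intensity inside the
mask and divides it out. The fit is *trimmed* (three passes dropping
residuals below -2.5 MAD): the smooth field must follow the dominant fat
shading, and an untrimmed least-squares fit chases the dark retroareolar FGT
core — on phantoms this destroyed the fat/FGT bimodality entirely.

`fuzzy_c_means()` is the standard FCM (fuzzifier m = 2, two classes,
tolerance 1e-4 of the intensity range, at most 200 iterations) with centers
initialized deterministically at intensity quantiles; FGT is the darker
winning class by default (`polarity` flag for inverted contrasts). Percent
density is 100 x FGT / breast volume from voxel counts.

# Meshing

`extract_surface()` runs marching *tetrahedra* on the Kuhn 6-tetrahedron
decomposition of each cell — the same isosurface role as marching cubes, but
with no ambiguous cases and a watertight result by construction. The binary
mask is first anti-aliased by two passes of a separable 3-tap box blur so the
isosurface tracks the smooth anatomy instead of the voxel staircase (a
voxelized sphere's area is then within ~1% of 4 pi r^2); if smoothing erases
a tiny mask entirely, the raw mask is used with a warning.

`tetrahedralize()` is the deterministic, dependency-light stand-in for a
Delaunay mesher: a regular lattice of cells (default edge 5 mm) is laid over
the surface, interior cells are kept, and each becomes 6 conforming Kuhn
tetrahedra. Cell selection is *volume-matched*: cells are ranked by a
ray-cast coverage estimate and exactly `round(V_surface / h^3)` are kept, so
the mesh volume equals the surface-enclosed volume up to half a cell and
refinement converges trivially. (A plain "center inside" rule carries a
+3-4% curvature bias at 5 mm on a 20 mm sphere.) Inside tests use parity of
axis-aligned ray crossings with a 2D bucket grid and tilted-direction retries
for edge-grazing hits.

Elements are labeled fat/FGT by majority vote of the voxel classes at the
centroid and vertices, counting only samples inside the breast (so a mask
equal to the breast labels every element FGT); elements with no in-breast
sample default to fat and are reported. The posterior boundary (nodes within
half a lattice edge of the chest plane) is fixed.

Axis convention: +x right, +y anterior (away from the chest), +z superior;
prone gravity is +y, supine gravity -y; all directions configurable.

# FEM solver

The solver is total Lagrangian explicit dynamics (TLED) with dynamic
relaxation: linear tetrahedra with precomputed reference shape-function
gradients, a compressible neo-Hookean material
`Psi = mu/2 (J^{-2/3} I1 - 3) + K/2 (J - 1)^2`, lumped mass, central
difference integration with mass-proportional damping, and gravity ramped
over the first 2000 steps. Convergence requires both the maximum nodal
velocity below 1e-6 m/s and the maximum free-node residual below 1e-4 of the
total gravity load; exceeding 2e5 steps is an error carrying the residual
history. Element inversion (J <= 0) aborts with the element id. Meshes are
in mm; mechanics run in SI units internally.

Parameter interpretation: the study prints only "bulk moduli" 3400 Pa (fat)
and 50,000 Pa (FGT). We take these literally as bulk moduli K, with a
configurable Poisson ratio (default 0.45) and
`mu = 3 K (1 - 2 nu) / (2 (1 + nu))`. This is documented prominently because
the cited material source may intend Young's moduli: under the literal
reading, K_fat is only ~10x the gravity-scale stress rho g L (~400 Pa), so
the tissue is *not* numerically near-incompressible — under prone gravity the
phantom's total volume dilates by ~2.2-2.5% even at nu = 0.49, slightly above
the 2% near-incompressibility check carried in the acceptance suite, which we
leave failing rather than reinterpret the printed values. Unprinted
constants: tissue density 1000 kg/m^3, g = 9.81 m/s^2, time step 0.4 of the
critical estimate (minimum element altitude over dilatational wave speed),
damping at the critical value of a lowest-mode estimate
`pi sqrt(E_min/rho) / L` along the gravity axis.

Verification: tip displacement of a hanging column under self-weight within
5% of `rho g L^2 / (2E)`; displacement scaling inverse to moduli in the
linear limit; zero force/displacement for zero gravity; exact frame
equivariance under 90-degree rotations; stress against finite differences of
the energy at 1e-6.

# Gravity pipeline

`estimate_zero_gravity()` inverts the prone gravity load by fixed-point
iteration: simulate prone gravity from the current rest candidate, correct
the candidate by the (relaxed) mismatch to the observed prone nodes, stop
when the simulated prone shape matches within 0.5 mm (cap 20 iterations,
step halving after three consecutive residual increases). On phantoms the
iteration contracts strongly (two iterations at alpha = 1).

`load_supine_until_depth()` interprets the study's stopping rule — iterate
until the deformed MR breast depth equals the ultrasound breast depth — as a
*target-matching* condition, implemented as bisection on the supine gravity
load factor lambda in [0, 1], each step a fully converged static solve.
Breast depth is operationalized as the chest-plane-to-skin distance along the
anterior axis within a 6 mm sagittal slab around the nipple, matching supine
US probe geometry (the paper never defines "depth"). Depth is monotone
non-increasing in lambda, so bisection terminates within 0.05 cm of any
reachable target; a target below the full-gravity depth returns lambda = 1
with a warning rather than extrapolating beyond physical loading.

`warp_labels()` maps every output voxel center through the deformed mesh
(containing-tet search with a bucket grid, barycentric interpolation back to
the prone configuration, nearest-neighbor label sampling). Voxels inside the
mesh whose rounded preimage lands just outside the voxel mask take the
nearest labeled 6-neighbor — the mesh and the voxel mask disagree on a thin
boundary shell by construction, and an in-mesh voxel is tissue by definition.
The warp conserves the FGT fraction to well under 3 percentage points and
the breast volume to ~2% of the deformed mesh volume at the default 5 mm
resolution.

# ROI density and statistics

`place_roi()` reproduces the elastography window on the sagittal slice
through the nipple: top edge at the configured depth below the skin along
the anterior axis, laterally centered on the nipple line; the window
defaults to 1.0 x 0.5 cm (the study does not print its size). Local percent
density is FGT area over *whole box* area, including any non-breast voxels,
exactly as the study defines it. The 2D (single-slice) variant is the
default because the study speaks of areas; sagittal was chosen since the
supine sweep geometry is not stated.

`cohort_report()` emits mean/SD/range summaries, the five Pearson
correlations with the study's band rule — none < 0.3, weak [0.3, 0.5),
moderate [0.5, 0.7), strong >= 0.7, applied to |r| since the study discusses
r = -0.56 as a clear (moderate) trend — and the per-subject CV analysis
(sample SD over mean, in percent, with <10% / 10-20% / >20% bins). No
multiple-testing correction is applied, as in the study.

# Numerical choices and degenerate inputs

* FCM requires at least c distinct intensities; constant input errors.
* Distances below 1e-12 of the range in FCM are floored to avoid 0/0;
  affected points get (numerically) crisp membership.
* Empty masks, all-zero images, open surfaces, flat surfaces, out-of-grid
  ROIs and sub-minimal repeat counts raise errors naming the condition.
* `nearest_psd()` clips eigenvalues at 1e-8 and rescales to unit diagonal;
  PSD inputs are returned unchanged.
* Seeds: every stochastic step (phantom noise, cohort draws, pipeline
  subjects) consumes an explicit integer seed; identical seeds give
  bit-identical outputs.

# Known limitations

* The lattice mesh has a staircase boundary (no boundary-conforming
  elements); surface quantities inherit ~1 cell of geometric noise.
* No skin/shell elements, no contact with the chest wall, no circumferential
  stretching — the supine depth change on the wide-based phantom is only a
  few percent of the rest depth, so depth targets far below the rest depth
  clamp at lambda = 1.
* The pipeline's per-subject stiffness values are attached from the cohort
  model (imaging phantoms carry no elastography physics); pipeline
  correlations are smoke-level, not reproductions.
* Linear tetrahedra lock volumetrically as nu approaches 0.5; nu = 0.49 is
  the practical ceiling at these mesh sizes.
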