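---
title: "erythroshape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{erythroshape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the simulator does and
does not emulate, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The phenotyping problem

Red blood cells deform along a reversible continuum — the
stomatocyte–discocyte–echinocyte (SDE) sequence — and additionally take
distinct pathological shapes (trilobal knizocytes, irregularly spiculated
acanthocytes, damaged keratocytes, multilobate young cells, fixation
clusters). The package maps each 3D-imaged cell to (i) one of seven
mutually exclusive classes and (ii), for SDE cells, a continuous score on
[−1, +1] whose anchors are the seven canonical SDE shapes spaced 1/3
apart: spherocyte −1, stomatocyte II −2/3, stomatocyte I −1/3, discocyte
0, echinocyte I +1/3, echinocyte II +2/3, echinocyte III +1. Half the
anchor spacing, printed at two decimals, is the matching tolerance:
±0.17 (`sde_half_interval()`).

## 2. Preprocessing chain

`crop → interpolate → binarize → isosurface`, each a documented function.

* **Cropping** (`crop_cells`). Cells are connected components of the
  thresholded maximum-intensity projection; components touching the
  lateral border or supported by fewer than `min_cell_voxels` thresholded
  voxels are discarded; each survivor yields a 100 px × 100 px substack.
* **Isotropic interpolation** (`interpolate_isotropic`). Linear
  interpolation along z down to the lateral pitch; the new plane count is
  `floor(n_planes · z_nm / xy_nm)` — 68 planes at 300 nm over a 110 nm
  lateral pitch become 185.
* **Binarization** (`binarize`). Foreground = intensity ≥
  `threshold_fraction` × per-crop maximum; the largest 6-connected
  component is kept and interior cavities are filled so the membrane
  shell becomes a solid body. *Default 0.2, not 0.5*: with an axially
  elongated confocal blur, laterally facing membrane integrates ≈
  σ_z/σ_xy ≈ 2× brighter than axially facing membrane, and an axially
  facing patch that falls midway between 300 nm planes is undersampled to
  ≈ 0.64 of its peak. A fraction near 0.5 of the *global* maximum
  therefore provably cuts holes into the dimmest shell regions, the
  outside flood-fill leaks through them, and the recovered cell collapses.
  0.2 keeps every canonical shape watertight while sitting roughly eight
  noise standard deviations above background. An absolute-threshold mode
  (`threshold_absolute`) is provided for calibrated real data.
* **Isosurface** (`extract_isosurface`). A marching isosurface at level
  0.5 over the zero-padded binary volume, built on the Freudenthal
  6-tetrahedra decomposition of each grid cube — the marching-cubes
  family, chosen in its tetrahedral variant because it is watertight by
  construction and needs no 256-case lookup table. Vertices are scaled to
  micrometres and the bounding-box center is moved to the origin, which
  makes downstream analysis translation invariant.
* **Ridge refinement** (default on, `compensate = FALSE` restores the
  literal chain). Thresholding a blurred membrane shell at a fraction f
  of its peak places the recovered surface a distance σ·√(2·ln(1/f))
  *outside* the membrane per axis — 100–250 nm at confocal blur, which
  alone inflates a discocyte's volume by ~15–20%. Each marching-cubes
  vertex is therefore moved inward along its normal to the local maximum
  (ridge) of the interpolated intensity, i.e. to the membrane center,
  with parabolic sub-voxel refinement. The volume round trip
  (rasterize → preprocess) then closes within ~1% instead of ~15%.
* **Taubin smoothing** (default 15 λ/μ passes, `smooth_iterations = 0`
  disables). Marching surfaces carry voxel-scale staircase roughness that
  a smooth reference mesh does not have; the roughness leaks spurious
  high-frequency band energy into the descriptor and was the largest
  source of clean-vs-recovered descriptor discrepancy (relative L2 ~0.3,
  reduced to ~0.1 by smoothing, against ~0.015 rotation jitter). The λ/μ
  pair acts as a pass-band filter and preserves enclosed volume to
  ~0.5%, unlike plain Laplacian shrinkage.

## 3. The rotation-invariant descriptor

The cell is voxelized onto a 64³ grid (`voxelize_mesh`): by default an
*antialiased surface shell* (a Gaussian of distance to the membrane,
σ = 1 voxel, peak 1) — the membrane-as-isosurface reading of the data —
with an exact parity-filled *solid* mode as an alternative. Around the
cube center, 32 concentric spheres of radii 1..32 voxels are sampled by
trilinear interpolation on a Gauss–Legendre × equispaced-φ quadrature
grid, and each spherical function is decomposed into real orthonormal
spherical harmonics up to degree 15 (16 frequencies). The quadrature is
exact for band-limited functions: Gauss–Legendre in cos θ with 24 nodes
integrates every product of two degree-≤15 associated Legendre functions
of equal order exactly, and 48 equispaced φ samples are exact up to
azimuthal order 30.

Per radius the feature block is (a₁, a₂, a₃, ‖f₁‖, ‖f₃‖, ‖f₄‖, …,
‖f₁₅‖): degrees 0 and 2 are folded into the three sorted eigenvalues of
the quadratic form f₀+f₂ = a₁x²+a₂y²+a₃z² on the unit sphere
(`euclid_f0_f2`; the 6×6 map from harmonic coefficients to the form is
derived numerically from the package's own basis, so it cannot drift out
of sign convention), and the remaining 14 degrees {1, 3, 4, …, 15}
contribute band energies. 32 × (3 + 14) = 544 features, flattened
radius-major and min–max normalized to [0, 1] per vector (per-vector
rather than per-dataset, because inference must work one cell at a time).

Design choices worth stating:

* **Centering.** The bounding-box center guarantees translation
  invariance but is *not* rotation covariant; anchoring the sampling
  spheres there breaks rotation invariance badly for asymmetric cells
  (relative L2 discrepancy up to ~1.0 for a multilobate cell). The
  descriptor therefore re-centers each mesh on its volume centroid
  (center of mass) before voxelization — the standard choice for this
  descriptor family — while meshes as artifacts keep the bounding-box
  convention. With centroid centering and the smooth shell, 20 random
  rotations of every canonical shape stay within relative L2 distance
  0.05 (the only residual symmetry breaker is voxel-grid aliasing).
* **Scale.** Default `fixed_physical` (0.2 µm per voxel, a 12.8 µm
  field): absolute cell size is diagnostic and should reach the
  classifier. `fit_to_grid` (bounding sphere to 90% of the grid radius)
  is available for size-free retrieval-style use.
* **Eigenvalues, not axis coefficients.** (a₁,a₂,a₃) are reported sorted;
  raw axis-aligned coefficients would depend on orientation.

## 4. Dataset assembly

Measured spectra are split 80/20 stratified by shape class *before* any
augmentation, so no interpolated sample ever mixes information across the
train/validation boundary (`split_before_augmentation`, verified by a
parent-id leakage test). Augmentation is linear interpolation of spectrum
pairs with uniform weight followed by re-normalization: within each
stage-1 class up to 2000 samples per class (`augment_classification`),
and for the regressor between pairs from the same or adjacent SDE classes
with the target score interpolated by the same weight
(`augment_regression`). The trained "unknown" slot is synthesized from
cross-class mixtures (weights 0.3–0.7), emulating ambiguous in-between
shapes; at inference the 75% confidence threshold additionally routes
low-confidence cells to unknown. Both mechanisms — a trained catch-all
slot and threshold-based rejection — are therefore active; a 6-class mode
without the trained slot is a config switch.

## 5. The dual-stage network

Single-hidden-layer perceptrons in base R matrix algebra, trained by Adam
(10⁻³, 0.9/0.999) on shuffled batches of 100, fully seeded:

| | stage 1 (classifier) | stage 2 (regressor) |
|---|---|---|
| architecture | 544 → 54 ReLU → 7 softmax | 544 → 544 ReLU → 1 tanh |
| loss | crossentropy | mean squared error |
| epochs | 100 | 40 |
| output | class probabilities; < 75% ⇒ unknown | score in [−1, 1] |

Both stages are trained from multiple random starts (100 in the full
protocol; tests use 3) and the model with the lowest final validation
loss is kept (`multi_restart_select`; stage-1 ties break by validation
accuracy). The tanh output head guarantees the printed [−1, 1] range by
construction; its output layer is initialized 20× smaller than the He
default because a saturated tanh has a vanishing (1 − out²) gradient
factor and can freeze training permanently — with the small start the
pre-activations stay in the linear region until the loss surface pulls
them out (verified across seeds in the test suite). A linear-plus-clip
head is available by config.

## 6. The simulator: its world and its limits

Every canonical shape is a star-shaped radial function r(θ, φ) evaluated
on a fixed subdivided-icosahedron grid (2562 vertices), which makes the
shared parameterization for remeshing and morphing exact by construction.
The discocyte uses the classic biconcave thickness polynomial
T(ρ) = √(1−(2ρ/D)²)(c₀ + c₂(2ρ/D)² + c₄(2ρ/D)⁴) with defaults
c₀ = 0.81, c₂ = 7.83, c₄ = −4.39 µm at D = 7.82 µm (center ≈ 0.81 µm,
rim ≈ 2.5 µm, volume ≈ 93 fl). Stomatocytes are oblate bodies with one
polar Gaussian cup (depth separates type I from II); echinocytes add
Gaussian spikes at Fibonacci-lattice directions to a biconcave (type I)
or ovoid (II, III) base, type III carrying 30 spikes to satisfy the
">25 spikes" criterion; knizocytes get a 3-fold cos(3φ) modulation;
acanthocytes few (7) amplitude- and width-jittered spicules at seeded
random directions; keratocyte and multilobate are labeled stand-ins (a
notched body with two horns; four broad lobes) because the literature
defines them only loosely; a cell cluster is the union of two overlapping
spheres. Dataset generation jitters diameter (5% sd) and geometry
parameters (8% sd) and applies uniform random rotations, all through one
seeded generator.

Morphing remeshes both meshes onto the shared grid by ray casting from
the origin (star-shape assumption; violations raise a morph-failure
error naming the mesh) and interpolates grid points linearly; the
ground-truth score of a morph is the same linear interpolation of the
endpoint scores. One caution discovered while testing: the enclosed
volume of such a radial interpolation is *not* bounded between the
endpoint volumes (a thin rim averaging against a round body can dip below
both); the true bound is the dual Brunn–Minkowski inequality
V(t)^{1/3} ≤ (1−t)V(0)^{1/3} + tV(1)^{1/3}, which is what the tests
assert.

Synthetic acquisition (`rasterize_to_stack`) splats the membrane surface
as anisotropic Gaussians — blur default σ = (80, 80, 160) nm. The lateral
value matches a confocal-class PSF; the axial value is the smallest that
keeps axially facing membrane patches lying *between* 300 nm planes above
threshold (at σ_z much below half the plane spacing the patch vanishes
from every sampled plane and the shell leaks). Additive Gaussian noise
(sd 0.05 of the shell peak) is clipped at zero. The simulator does *not*
emulate: diffraction side lobes or a realistic 3D PSF shape, photon
(Poisson) noise, bleaching, refractive-index distortions along z,
touching cells requiring watershed splitting, or internal structure of
reticulocytes. A green end-to-end test therefore establishes that the
*pipeline* is correct and self-consistent at realistic geometry, blur,
anisotropy and noise — not that the classifier would transfer to any
particular microscope without retraining on its data.

## 7. Numerical choices and degenerate inputs

* Quadrature: Gauss–Legendre nodes from the Golub–Welsch eigenvalue
  method; associated Legendre by the stable (l−m) upward recursion, exact
  in double precision to degree 15.
* Min–max normalization of a constant vector returns all zeros with a
  warning (the 0/0 case).
* Binary volumes are zero-padded by one voxel before isosurfacing so
  border-touching foreground still closes.
* The ±0.17 matching half-interval is used exactly as printed (not 1/6):
  `round(spacing/2, 2)`.
* CI₀.₉₅ of a sample's scores is the central 95% interval of the per-cell
  score distribution (inverse-ECDF quantiles, which makes reports
  invariant under duplicating a sample), not a standard error of μ.
* Model serialization writes weights as 17-significant-digit strings so a
  save/load round trip reproduces predictions bit-exactly.
* All randomness flows through explicit integer seeds; the pipeline fans
  its global seed out to stages by fixed documented offsets, and
  re-running a configuration reproduces every results table byte for
  byte.

## 8. Known limitations

* Real-microscope generalization is untested by necessity (no public
  data); the absolute-threshold binarization mode and the descriptor's
  `fit_to_grid` scale mode are the knobs most likely to need adjustment
  on real stacks.
* The spike counter is tuned for bump-like protrusions at least ~0.05 µm
  prominent on the icosphere grid; sub-resolution crenellation (mild
  echinocyte I texture) is deliberately not counted.
* Keratocyte and multilobate geometries are stand-ins; their
  classification accuracy on synthetic data should not be read as a
  statement about real damaged cells.
* Training is single-threaded CPU; the full 100-restart protocol is
  hours-scale, which is why tests and the default pipeline use 3
  restarts.
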