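---
title: "Measuring cellular strain energy in 3D gels: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cellular strain energy in 3D gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `tfm3d`, the parameters
that matter, the design decisions where more than one defensible choice
existed, and what the synthetic validation suite does — and does not — show
about real data.

# The measurement model

A cell embedded in a biopolymer gel contracts its surroundings. If the gel
behaves as an isotropic linear elastic continuum on the scale of interest,
the elastic energy stored in the matrix is a scalar measure of the cell's
total contractility. The measurement chain is:

1. Two z-stacks of fluorescent marker beads: the *deformed* state (cell
   under tension) and the *relaxed* state (after pharmacological disruption
   of the actin cytoskeleton, which is the force-free reference).
2. Per-bead 3D displacements between the two stacks.
3. A tetrahedral finite-element mesh on the relaxed bead positions
   (Delaunay); nodal displacements are the measured bead displacements.
4. Per-element strain energy from constant-strain linear tetrahedra, with
   two noise defenses: geometric exclusion of flat elements and subtraction
   of the expected noise energy.
5. Integration to a total strain energy, plus second-moment anisotropy
   descriptors of the energy distribution.

## Continuum assumptions

The gel is treated as homogeneous, isotropic, and linearly elastic. For
reconstituted collagen at 2.4 mg/ml this holds on scales larger than about
ten pore sizes and for strains up to roughly 5%; beyond that, strain
stiffening makes the linear model underestimate the stored energy. The
cell volume itself is included in the integration domain with matrix
properties — the cell occupies only a few elements, so the error is small
compared to the noise defenses it avoids.

## Elasticity formulation

Each Delaunay tetrahedron is a 4-node constant-strain element. With node
coordinates in µm, the stiffness is `K = V · BᵀC B`, where `B` holds the
shape-function gradients and `C` is the isotropic elasticity matrix built
from the shear modulus `G` and the first Lamé parameter
`λ = 2Gν/(1 − 2ν)`. The element energy is the quadratic form
`U = ½ uᵀK u`. Internal units are Pa·µm³ (= 10⁻⁶ pJ), so the unit identity
`U[pJ] = w[Pa] · V[µm³] · 10⁻⁶` is exact by construction.

`K` is symmetric positive semi-definite with a six-dimensional null space
(three translations, three linearized rotations); finite rotations of angle
θ leak energy only at order θ⁴. Because strain is constant per element, the
formulation is *exact* for affine displacement fields — this is the
strongest available oracle and the test suite checks it to numerical
precision against the closed form
`w = ½λ tr(ε)² + G Σ εᵢⱼ²`.

# Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| shear modulus G | 118 | Pa | reference collagen gel at 1 Hz |
| Poisson ratio ν | 0.35 | — | reference collagen gel |
| voxel pitch | 0.645, 0.645, 2.0 | µm | 2 µm optical sections, 10× effective magnification |
| subvolume | 4.5 × 4.5 × 14 | µm | matching window around each bead; elongated in z to compensate the coarser axial sampling |
| search radius | 10 | µm | larger than cell-induced displacements away from the cell; bounded for speed |
| pre-smoothing σ | 0.7, 0.7, 1.5 | µm | about one voxel per axis; suppresses interpolation bias (below) |
| noise σ | 0.022, 0.022, 0.130 | µm | displacement accuracy used for the energy baseline |
| qₘᵢₙ | 0.5 | — | element shape-factor threshold |
| mean bead spacing | 24 | µm | reference bead density; sets the spatial resolution of the strain field |

# Numerical choices

## Sub-voxel tracking

The matcher minimizes the mean-subtracted SSD between the reference
subvolume and the tri-linearly interpolated target. Three choices matter:

* **Optimizer.** Coarse integer-voxel grid search over the search radius,
  then a 3×3×3 pattern search with successive step halving down to ~10⁻⁶
  voxel. The SSD surface of a blob image is smooth at the voxel scale, so
  this is robust without derivatives. A bead whose optimum lands on the
  search boundary, or whose subvolume leaves either stack, is flagged lost
  rather than silently dropped.
* **Symmetric interpolation.** The candidate shift is split as ∓s/2 between
  the two stacks, so both windows experience the same interpolation
  smoothing at the optimum.
* **Band-limiting.** Tri-linear interpolation of an under-sampled blob
  (PSF σ ≈ 0.6 voxel laterally) produces a systematic sub-voxel bias
  toward integer shifts ("peak locking"). Pre-smoothing both stacks with a
  Gaussian of about one voxel per axis removes most of it: on noise-free
  synthetic shifts the RMS error drops from ≈55 nm to ≈15 nm laterally and
  from ≈115 nm to ≈60 nm axially, inside the 22/130 nm accuracies assumed
  by the noise model. The cost is a slightly wider effective PSF, which is
  harmless at 24 µm bead spacing.
* **Mean subtraction** of both windows makes the match insensitive to
  uniform bleaching between acquisitions.

## Delaunay tessellation

No 3D Delaunay implementation ships with the packages this library builds
on, so the tessellation is an incremental Bowyer–Watson construction in
compiled code: points are located by orientation-guided walking, the
conflict cavity is grown by circumsphere tests, and the cavity is re-meshed
around the new point. Degenerate inputs (exactly cospherical points, e.g.
grid corners) can make the floating-point cavity inconsistent; the cavity
is therefore validated (every boundary edge on exactly two faces) before
any mutation, and on failure the insertion retries with a deterministic
µ-scale jitter of the working coordinates. The element indices returned
always refer to the caller's exact coordinates. Validation: exact hull
volume conservation on known hulls and brute-force empty-circumsphere
checks on random instances.

## Shape factor and noise defenses

The shape factor `q = 36√2 · V / Σ lᵢ³` is normalized so a regular
tetrahedron scores exactly 1 (the constant is forced by
`V = a³/(6√2)` and `Σl³ = 6a³`) and flat elements score 0; it is invariant
under rotation, translation, uniform scaling and vertex permutation.
Elements with q < 0.5 are excluded (q = 0.5 exactly is kept — the
exclusion is a strict inequality), and their densities are filled from the
nearest valid element centroid, with the fill provenance recorded.

Strain energy is quadratic in displacement, so zero-mean displacement
noise `n` with per-axis SDs σ biases each element by
`E[½ nᵀK n] = ½ Σᵢ Kᵢᵢ σᵢ²` (independent noise per node and axis). This
baseline is subtracted per element. Corrected energies may then be
negative; they are deliberately retained unfloored in totals so the
estimator stays unbiased (validated by pure-noise simulations whose mean
corrected total is statistically indistinguishable from zero), but floored
at zero for density visualization and for anisotropy weights, which
require non-negative mass.

## Integration and time-lapse maps

The total strain energy is the cumulative sum of corrected element
energies whose centroids lie within growing spheres around the cell; the
value at the largest radius is the plateau. Monotonicity is not enforced —
corrected energies can be negative. Time-lapse relative-change maps
rasterize both density fields (floored) onto a common 5 µm grid by
point-in-tetrahedron lookup and report `(w₂ − w₁)/max(w₁, floor)` with a
floor of 1% of the first frame's maximum density; the floor prevents
blow-up where the reference density vanishes.

## Anisotropy and summaries

Cell shape is outlined as a 2D polygon at the sharpest z-plane (Tenengrad
focus measure: sum of squared Sobel gradients; ties break to the lowest
z). The polygon is rasterized at the lateral pixel size and the index is
the eigenvalue ratio of the centered second-moment matrix of mask pixels.
Energy anisotropy uses element centroids weighted by floored density ×
element volume — volume weighting makes the tensor independent of how the
mesh happens to subdivide a region. Per-cell scalars are summarized as
geometric mean ± geometric SE because strain energies and anisotropy
indices follow log-normal distributions.

# The synthetic test bed

The generator emulates: beads at the reference ~24 µm mean spacing
(hard-sphere rejection sampling), displaced by analytic linear-elastic
fields, rendered as anisotropic Gaussian blobs (σ = 0.4, 0.4, 1.5 µm,
approximating a 1 µm bead under a low-NA air objective) at voxel centers,
with optional Poisson or Gaussian noise. Three displacement models:

* **Affine** `u = (R − I + ε)(x − x₀) + t` — the exactness oracle.
* **Kelvin point force** `uᵢ = Fⱼ/(16πG(1−ν)r)·[(3−4ν)δᵢⱼ + rᵢrⱼ/r²]` —
  an equilibrium solution (verified by finite-difference stress
  divergence), the building block for localized sources.
* **Contractile dipole** — two opposing Kelvin forces emulating a spindle
  cell. The default scene is an 80 × 30 µm bead-free capsule ("cell
  body") with 15 nN pole forces 50 µm apart in a 240³ µm³ box; the force
  was chosen so the peak gel strain at the cell surface is ≈5%, the upper
  end of the linear regime. The scene manifest stores the exact per-bead
  displacements and the analytic continuum energy of the ground-truth
  field, integrated by Gauss–Legendre quadrature over a spherical shell
  and by a midpoint grid over the remaining gel volume around the capsule
  (the point forces inside the cell are singular, so the energy is only
  defined over the gel domain).

## What recovery against ground truth shows

With exact (noise-free) nodal displacements, the recovered total energy of
the default dipole scene is 57–77% of the analytic continuum energy across
scene seeds, never exceeding it, and the seed-averaged recovery grows with
bead density. The deficit has two distinct causes, measured separately by
the validation suite:

* *Cavity smoothing*: no beads exist inside the cell, so elements spanning
  it interpolate across the steepest part of the field. This is the
  dominant, physically expected underestimation — the same mechanism
  operates in real assays.
* *The quality filter*: on noise-free data, excluding q < 0.5 elements and
  filling their densities from neighbors discards real energy (recovery
  rises from ≈0.69 to ≈0.87 of the analytic value when the filter is
  disabled). On real, noisy data the filter pays for itself by removing
  elements whose spurious energy the baseline cannot reliably cancel.

Two caveats sharpen what passing tests mean. First, in regions the bead
density resolves (field length scale ≳ 2–3 bead spacings) and with exact
nodal sampling of an equilibrium field, the finite-element interpolant
slightly *over*estimates the continuum energy on a matched domain (by
5–10% at 24 µm spacing, shrinking with refinement) — the interpolation
error energy is positive. Net underestimation is a statement about
localized cellular fields with a bead-free cell body, not a property of
linear interpolation per se. Second, the acceptance check on the default
scene asks for recovery within 30% of the continuum energy; the measured
mean over the fixed validation seeds is ≈0.69, i.e. right at that
boundary, and the assertion is kept at its stated bound rather than
adjusted — a sub-percent shortfall there reflects the genuine
discretization deficit of a 24 µm bead spacing around a point-force cell,
not an implementation defect.

## What the synthetic suite does not show

Rendered scenes are ideal: Gaussian PSF, no aberrations, no fiber texture,
no bead drift or bleaching, and a gel that is exactly linear and
homogeneous. Real collagen adds strain stiffening (systematic
underestimation of high-strain regions), local matrix remodeling by the
cell, and non-Gaussian imaging artifacts. Accuracy figures from the
synthetic protocol are therefore upper bounds on real-data performance,
and the absolute energies of real cells inherit the uncertainty of the
measured G and ν.

# Problem sizes

The test suite and the reference-quantity script run at deliberate desk
scale: 100-shift tracking accuracy protocols on 31 × 31 × 17-voxel stacks,
~1000-bead scenes (≈6300 elements) for energy recovery, 10⁵-draw Monte
Carlo checks of the noise baseline, 20-repeat pure-noise simulations, and
10⁴-sample invasion profiles. These sizes were chosen so each statistical
check has enough power to be meaningful while the whole suite stays
interactive; the pipeline itself handles full-size stacks (hundreds of
megabytes, ~10⁴ beads) in a few minutes on one core.

# Known limitations

* Linear elasticity only; no strain stiffening or viscoelasticity.
* Infinite-medium analytic models; boundary effects are ignored, valid for
  cells several field decay lengths away from gel surfaces.
* No full inverse traction reconstruction — the method deliberately
  reports strain energy and its distribution, which are robust to noise
  and matrix non-linearity in ways surface-traction maps are not.
* Time-lapse series are handled as successive pairs; no particle linking
  with appearance/disappearance models.
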