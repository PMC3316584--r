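# tfm3d — strain-energy traction microscopy in 3D biopolymer gels

Cells invading a three-dimensional extracellular matrix pull on it, and the
work they expend is stored as elastic strain energy in the gel around them.
`tfm3d` measures that energy — a robust scalar readout of cellular
contractility — from pairs of fluorescence z-stacks of marker beads embedded
in a collagen gel: one stack in the contracted state, one after the cell is
pharmacologically relaxed (e.g. with cytochalasin D), so that the relaxed
stack defines the force-free reference configuration.

The package targets experimentalists running 3D traction assays on a
standard motorized fluorescence microscope, and methods developers who need
a fully synthetic, ground-truth-controlled test bed for such pipelines.

## Method

1. **Bead localization and tracking.** Beads are detected in the relaxed
   stack by intensity thresholding and connected-component centroids. Each
   bead's displacement is measured by cutting a 4.5 × 4.5 × 14 µm subvolume
   around it and shifting it against the deformed stack until the sum of
   squared intensity differences (SSD) is minimal, with tri-linear
   interpolation providing sub-voxel resolution. Both stacks are Gaussian
   band-limited first and the shift is split symmetrically between them,
   which suppresses interpolation bias; at 0.645 µm lateral pixels and 2 µm
   z-sections the tracker reaches an RMS accuracy of about 15 nm laterally
   and 60 nm axially on synthetic sub-voxel shifts (within the 22 / 130 nm
   accuracy of the reference implementation of this assay).
2. **Tessellation.** The relaxed bead positions become the nodes of linear
   (constant-strain) tetrahedral finite elements via 3D Delaunay
   tessellation.
3. **Element quality filtering.** Flat "sliver" elements amplify
   displacement noise into spurious energy. Each element is scored with the
   shape factor

   q = 36√2 · V / Σᵢ lᵢ³,

   the normalized ratio of element volume to the sum of its six cubed edge
   lengths: q = 1 for a regular tetrahedron, q = 0 for a degenerate flat
   element. Elements with q < 0.5 are excluded and their energy densities
   filled from the nearest valid element.
4. **Strain energy.** With isotropic linear elasticity (shear modulus
   G = 118 Pa, Poisson ratio ν = 0.35 for the reference collagen gel), each
   element's stiffness is K = V·BᵀCB and its strain energy U = ½ uᵀK u from
   the nodal displacements u. Because energy is quadratic in displacement,
   zero-mean measurement noise biases it upward; the expected spurious
   energy E[½ nᵀK n] = ½ Σᵢ Kᵢᵢ σᵢ² is subtracted per element. The total
   strain energy is the integral of the corrected energy density over a
   large volume around the cell (cell volume included).
5. **Anisotropy and invasion.** Second-moment eigenvalue ratios
   (λ_max/λ_min) quantify cell-shape anisotropy (2D contours) and the
   anisotropy of the strain-energy-density distribution (3D); invasion
   assays are summarized as the cumulative probability of finding a cell
   below a given depth. Per-cell statistics are summarized by geometric
   mean ± geometric SE, appropriate for their log-normal distribution.

A synthetic-scene generator provides ground truth for every stage: beads at
the reference ~24 µm mean spacing, displaced by analytic elastic fields
(point-force/Kelvin, contractile dipole with a bead-free cell capsule, or
affine), rendered as Gaussian blobs with optional noise.

## Worked example

A contractile dipole (an 80 × 30 µm spindle-shaped "cell" pulling with
15 nN at each pole) in a 240³ µm³ gel with beads at 24 µm spacing:

```r
library(tfm3d)

scene <- dipoleScene(seed = 1)     # ground truth: positions + displacements
mesh  <- tessellate(scene@positions)
field <- assembleField(mesh, scene@manifest$displacements,
                       material = scene@material,
                       noise = NoiseModel(c(0, 0, 0)))   # noise-free scene
energy <- totalEnergy(field, center = scene@params$center,
                      radii = seq(24, 96, by = 8))
energy$plateau_pJ                        # 0.00283
scene@manifest$analytic_gel_energy_pJ    # 0.0041
energyAnisotropy(field)                  # index 2.81
```

which prints, along the way:

```
TetMesh: 1000 nodes, 6273 elements (2271 valid after quality filter)
StrainEnergyField: 6273 elements (2271 computed, 4002 filled)
  total corrected energy 0.001938 pJ, peak density 0.02371 Pa
AnisotropyResult: index 2.807 (eigenvalues 4613000, 1799000, 1644000)
```

The recovered total (0.00283 pJ) sits below the analytic continuum energy
of the ground-truth field (0.0041 pJ): sampling the displacement field only
at bead positions smooths away sub-bead-spacing strain variation — most of
it across the bead-free cell body — so the estimator underestimates the
true strain energy, and converges toward it as bead density grows. The
energy distribution around this elongated contractile source is strongly
anisotropic (index 2.8 versus 1 for an isotropic distribution).

For image-based runs, `runPipeline()` (or the `inst/cli/tfm3d` script's
`track`, `energy` and `pipeline` subcommands) goes from two TIFF stacks to
a JSON report with the total energy, its convergence over integration
radius, anisotropy, and full provenance.

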