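Package: tfm3d
Title: Strain-Energy Traction Microscopy in 3D Biopolymer Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cellular contractility in three-dimensional
    biopolymer gels from paired fluorescence z-stacks of embedded marker
    beads. Beads are localized in 3D and tracked between the contracted and
    the drug-relaxed state of the gel by sub-voxel subvolume matching with
    tri-linear interpolation. The relaxed bead positions are tessellated
    into linear tetrahedral finite elements; from the nodal displacements
    and the gel's isotropic linear elasticity the per-element strain energy
    and strain energy density are computed, flat noise-amplifying elements
    are excluded by a tetrahedron shape-quality factor, and the expected
    spurious energy from displacement noise is subtracted. Scalar
    contractility (total strain energy), second-moment anisotropy indices
    of cell shape and of the strain energy density distribution, and
    invasion-depth profiles for 3D invasion assays are derived. A synthetic
    scene generator (analytic point-force, contractile-dipole and affine
    displacement fields rendered as Gaussian beads) provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    pracma,
    tiff,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
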