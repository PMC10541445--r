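Package: spiOrient
Title: Orientation-Recovery Quality in X-Ray Single-Particle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how solvent
    (water-layer) scattering and radiation damage degrade orientation
    recovery in X-ray free-electron-laser single-particle imaging.
    Provides an Ewald-sphere diffraction forward model for hydrated,
    optionally damaged particles, photon-sparse Poisson pattern
    generation, an expand-maximize-compress (EMC) reconstruction of the
    3D reciprocal-space intensity with a beta/num_div annealing
    schedule, 600-cell based quadrature sampling of SO(3), and two
    reconstruction-quality metrics: the per-shell R-factor and the
    orientation-disconcurrence metric on the symmetry quotient of
    SO(3).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, MathematicalBiology
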