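Package: mreit
Title: Simulation and Harmonic Bz Reconstruction for Magnetic Resonance
    Electrical Impedance Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for magnetic resonance electrical impedance tomography
    (MREIT): synthetic conductivity phantoms with a two-dimensional finite
    element forward solve and Biot-Savart simulation of the current-induced
    magnetic flux density Bz, synthesis of complex MR image pairs and k-space
    data, extraction of Bz from measured phase (phase division, Goldstein
    branch-cut unwrapping, slice-continuity verification), ramp-preserving
    denoising by structure-tensor nonlinear diffusion, automatic detection and
    harmonic inpainting of MR signal-void regions, pixel-conforming
    triangulation of the imaging domain with electrode markers, and one-pass
    harmonic Bz reconstruction of scaled cross-sectional conductivity images,
    globally or on a local polygonal region.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    RNifti,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
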