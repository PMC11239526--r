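Package: ptir
Title: Permittivity Tensor Imaging: Vectorial Forward Models and Inverse
    Reconstruction for Label-Free Polarization Microscopy
Version: 0.1.0
Authors@R:
    person("ptir", "developers", email = "ptir@example.org", role = c("aut", "cre"))
Description: Simulates and reconstructs the uniaxial permittivity tensor of
    weakly scattering specimens imaged with oblique partially coherent
    illumination and polarization-resolved detection. Implements the uniaxial
    tensor algebra and its scattering-potential decomposition, a single
    scattering (vector Born) simulator with a dyadic Green's tensor, the
    linearized multi-channel transfer-function model, Stokes polarimetry with
    instrument-matrix calibration and background correction, a per-frequency
    Tikhonov inverse solver with dual optic-sign property extraction and
    optic-sign probability estimation, synthetic phantoms with exact ground
    truth, and post-reconstruction metrology (PSF width from beads, structure
    tensor orientation, orientation histograms, multi-scale coarse graining,
    projected retardance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
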