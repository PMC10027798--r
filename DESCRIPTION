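Package: tandemspect
Title: Multi-Isotope Quantitative SPECT Simulation and Single-Time-Point
    Dosimetry for Tandem Lu-177/Ac-225 Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom and synthetic-patient simulation of low-count
    dual-isotope SPECT acquisitions for tandem Lu-177/Ac-225 PSMA-targeted
    radionuclide therapy, together with quantitative MLEM/OSEM image
    reconstruction (CT-based attenuation correction, triple/dual
    energy-window scatter correction, distance-dependent collimator-detector
    response including septal-penetration star artifacts), cross-isotope
    image-quality harmonization, phantom figures of merit (recovery
    coefficients, signal-to-noise ratios), and single-time-point voxel
    dosimetry (two-point effective half-life fitting, cross-nuclide
    half-life conversion, time-integrated activity maps, voxel S-value
    kernels, CT-density and RBE weighting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
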