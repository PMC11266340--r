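Package: muracam
Title: Coded-Aperture Gamma Camera Simulation, Reconstruction and
    Resolution Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for near-field coded-aperture imaging with a compact
    gamma camera: generation of MURA (modified uniformly redundant array)
    mask patterns and their decoding arrays, rasterization of
    distance-dependent point-spread functions, forward simulation of
    detector images with mask transmission and Poisson counting noise,
    planar and z-stack reconstruction by MURA decoding, an extended 3D
    maximum-likelihood expectation-maximization (3D-MLEM) reconstructor
    with per-slice sensitivity normalization and a transmission-aware
    forward model, and a semi-automatic axial/lateral resolution
    assessment based on fitting an offset Gaussian to the
    contrast-to-noise-ratio profile along the optical axis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    graphics,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
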