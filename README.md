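# muracam

Simulation, reconstruction and resolution assessment for a compact
near-field gamma camera with a MURA coded-aperture collimator.

## The problem

Handheld gamma cameras are used intraoperatively — for instance to locate
radioactively marked sentinel lymph nodes — and coded apertures are an
attractive collimation technique for them: hundreds of tiny holes arranged
as a modified uniformly redundant array (MURA) harvest far more photons
than a single pinhole, and because a point source at distance *z* casts a
mask shadow magnified by

```
M(z) = 1 + b / z        (b = detector-to-mask distance)
```

the *depth* of a source is encoded in a single 2D exposure. Reconstructing
the same detector image at a series of assumed distances produces an image
stack in which the source comes into focus at its true depth. How sharply it
does — the **axial resolution** — is what this package measures, for the two
standard reconstructors:

* **MURA decoding** — circular convolution of the central detector window
  with the signed decoding array, magnified to the in-focus plane
  (milliseconds per slice);
* **extended 3D-MLEM** — iterative maximum-likelihood reconstruction of all
  slices jointly, with a per-slice sensitivity map `n_z = h_z ⋆ 1` that
  accounts for a mask smaller than the detector, and a forward model
  `F(f_z, h_z) = (1 − t)(f_z * h_z) + t Σ f_z` that accounts for the ~46 %
  of 59.5 keV photons transmitted straight through the 0.11 mm tungsten
  mask (seconds per slice, but markedly sharper in depth).

The axial resolution is quantified by a reproducible, semi-automatic
procedure: every placement of a source-sized circular region of interest is
sampled on each slice, the contrast-to-noise ratio
`CNR = (S̄ − B̄)/σ̄_B` is traced along *z*, an offset Gaussian
`α + (β − α) exp(−(z − γ)²/2δ²)` is fitted, and the resolution is reported
as `FWHM = 2√(2 ln 2) δ ≈ 2.35 δ` with the fit uncertainty.

The default `camera_geometry()` describes a 256 × 256 pixel, 14.08 mm
Timepix-class detector 20 mm behind a rank-31 no-two-holes-touching MURA
mask (0.08 mm round holes, 2 × 2 mosaic, 9.92 mm side).

## A worked example

```r
library(muracam)
g  <- camera_geometry()

# a point source 30 mm in front of the mask, ~1e6 detected quanta
img <- simulate_detector_image(source_scene(z = 30, intensity = 1e6),
                               g, seed = 7, noisy = TRUE)

# fast planar reconstruction by MURA decoding at the true depth
rec <- mura_decode(img, g, z = 30)
rec
#> reconstructed slice at z = 30.0 mm, 150 x 150 px

# the full axial assessment for both methods
a <- assess_axial(img, g, "mura", truth_z = 30)
a
#> MURA axial resolution (raw detector image)
#>   source distance: 30.0 mm; fitted peak gamma = 30.62 mm
#>   axial FWHM = 8.79 +/- 0.32 mm
#>   stack: 61 slices of 150 px; ROI diameter 13 px (19044 placements)

b <- assess_axial(img, g, "mlem", truth_z = 30)   # ~3 min: 55 slices x 40 iterations
b
#> MLEM axial resolution (raw detector image)
#>   source distance: 30.0 mm; fitted peak gamma = 30.00 mm
#>   axial FWHM = 1.90 +/- 0.03 mm
#>   stack: 55 slices of 256 px; ROI diameter 8 px (62001 placements)

plot(b)          # CNR profile with its fitted offset Gaussian
summary(b$fit)   # alpha, beta, gamma, delta with standard errors
```

Read the numbers as: the decoded stack comes into focus over an ~9 mm band
around the true depth, while the iterative reconstruction pins the source
down to ~2 mm — the same several-fold advantage the camera shows on
measured data, at the cost of orders of magnitude more computation.

`decode_stack()`, `reconstruct_3d()`, `preprocess_detector()`,
`assess_lateral()`, `read_detector_image()` / `write_detector_image()` and
`read_geometry_config()` cover the rest of the pipeline;
`inst/scripts/muracam-cli.R` wraps it for shell use
(`simulate` / `decode` / `mlem` / `assess` / `report`). The measured
21-image dataset of the physical camera can be cataloged with
`fetch_dataset()` once downloaded.

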