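#' Describe a scene of point-like gamma sources
#'
#' @param x,y lateral source positions in mm (0 = optical axis)
#' @param z source-to-mask distances in mm (> 0)
#' @param intensity expected number of detected quanta per source
#' @param source_fwhm_mm physical full width at half maximum of the
#'   (near-point) source, rendered as a Gaussian blob on the source plane;
#'   the default 0.65 mm matches a sealed 241-Am check source whose active
#'   spot was measured at that width
#' @return an object of class `source_scene`
#' @export
source_scene <- function(x = 0, y = 0, z = 30, intensity = 1e6,
                         source_fwhm_mm = 0.65) {
  n <- max(length(x), length(y), length(z), length(intensity))
  s <- data.frame(x = rep_len(x, n), y = rep_len(y, n),
                  z = rep_len(z, n), intensity = rep_len(intensity, n))
  if (any(s$z <= 0)) stop("all source distances z must be > 0")
  if (any(s$intensity < 0)) stop("source intensities must be >= 0")
  structure(list(sources = s, source_fwhm_mm = source_fwhm_mm),
            class = "source_scene")
}

#' Detector image container
#'
#' Light wrapper around a square non-negative pixel matrix with provenance
#' metadata (measured or simulated, ground-truth source positions for
#' simulations, preprocessing flag, random seed).
#'
#' @param pixels square non-negative numeric matrix
#' @param meta named list of provenance metadata
#' @return an object of class `detector_image`
#' @export
detector_image <- function(pixels, meta = list(provenance = "unknown")) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stop("detector image must be a square matrix")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    bad <- which(!is.finite(pixels) | pixels < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("detector image has a negative or non-finite entry at row %d, col %d",
                 bad[1], bad[2]))
  }
  structure(list(pixels = pixels, meta = meta), class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("detector image %d x %d px (%s)\n",
              nrow(x$pixels), ncol(x$pixels),
              x$meta$provenance %||% "unknown"))
  cat(sprintf("  total counts %.4g, max %.4g\n", sum(x$pixels), max(x$pixels)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a detector image of a point-source scene
#'
#' Each source is rendered as a Gaussian blob of the scene's physical FWHM on
#' a source-plane grid aligned with the detector pixels, forward-projected
#' through the mask with the NTHT point-spread function at its distance (the
#' physical mask casts NTHT shadows) and the transmission background of
#' the camera, then summed over sources. The point-spread function is
#' normalized to unit integral inside the projection so that `intensity` is
#' the expected number of detected quanta and the transmission fraction `t`
#' partitions them between mask pattern and uniform background. With
#' `noisy = TRUE` each pixel is Poisson-sampled using the given seed.
#'
#' Note the projective inversion: a source displaced laterally by `+d` mm
#' shifts its shadow by `-d * b / z` mm on the detector.
#'
#' @param scene a [source_scene()]
#' @param geometry a [camera_geometry()]
#' @param seed integer seed for the Poisson sampling
#' @param noisy logical; add Poisson counting noise?
#' @param pattern optional precomputed [mura_mask()] (must match the geometry)
#' @param psfs optional named list of precomputed NTHT `psf_image`s keyed by
#'   `as.character(z)`, to avoid re-rasterization in repeated calls
#' @param supersample supersampling factor passed to [rasterize_psf()]
#' @return a [detector_image()] with ground truth recorded in `meta`
#' @export
simulate_detector_image <- function(scene, geometry, seed = 1L, noisy = TRUE,
                                    pattern = NULL, psfs = NULL,
                                    supersample = 8L) {
  stopifnot(inherits(scene, "source_scene"),
            inherits(geometry, "camera_geometry"))
  if (is.null(pattern)) pattern <- mura_mask(geometry$rank)
  n <- geometry$detector_pixels
  cc <- n %/% 2L + 1L
  t <- geometry$transmission_t
  img <- matrix(0, n, n)

  for (k in seq_len(nrow(scene$sources))) {
    src <- scene$sources[k, ]
    fov_k <- fov(geometry, src$z, "pinhole")
    if (abs(src$x) > fov_k / 2 || abs(src$y) > fov_k / 2) {
      stop(sprintf("source %d at (%.1f, %.1f) mm lies outside the %.1f mm field of view at z = %.1f mm",
                   k, src$x, src$y, fov_k, src$z))
    }
    # source-plane pixel footprint matching the detector grid at this z
    px_mm <- geometry$pixel_pitch_mm * src$z / geometry$b_mm
    sigma_px <- scene$source_fwhm_mm / (2 * sqrt(2 * log(2))) / px_mm
    # projective inversion: +x source displacement moves the shadow to -x
    ux <- cc - src$x / px_mm
    uy <- cc - src$y / px_mm
    g1x <- exp(-((seq_len(n) - ux)^2) / (2 * sigma_px^2))
    g1y <- exp(-((seq_len(n) - uy)^2) / (2 * sigma_px^2))
    blob <- outer(g1x, g1y)
    blob <- blob / sum(blob) * src$intensity

    key <- as.character(src$z)
    h <- if (!is.null(psfs) && !is.null(psfs[[key]])) {
      psfs[[key]]
    } else {
      rasterize_psf(geometry, pattern, src$z, mode = "NTHT",
                    supersample = supersample)
    }
    hn <- h$pixels / sum(h$pixels)
    img <- img + forward_project(blob, hn, t)
  }

  if (noisy) {
    set.seed(as.integer(seed))
    img <- matrix(as.numeric(stats::rpois(length(img), lambda = img)), n, n)
  }
  detector_image(img, meta = list(
    provenance = "simulated",
    truth = scene$sources,
    source_fwhm_mm = scene$source_fwhm_mm,
    noisy = noisy,
    seed = if (noisy) as.integer(seed) else NA_integer_,
    preprocessed = FALSE
  ))
}
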