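#' Camera geometry
#'
#' Bundle of all physical constants of the coded-aperture gamma camera:
#' detector dimensions, mask rank and cell pitch, detector-to-mask distance
#' `b`, source energy and the mask transmission fraction `t`. Defaults
#' describe a 256x256 pixel, 14.08 mm Timepix-class detector behind a rank-31
#' no-two-holes-touching (NTHT) MURA mask (0.08 mm holes in 0.11 mm tungsten)
#' mounted 20 mm in front of the sensor.
#'
#' The mask is the basic rank-`r` MURA pattern, expanded to NTHT (holes in
#' every other cell) and duplicated in a plain 2x2 arrangement, so its
#' physical side is `2 * 2 * rank * cell_pitch` (9.92 mm for the default).
#'
#' @param detector_side_mm sensitive detector side length in mm
#' @param detector_pixels number of pixels per detector side
#' @param b_mm detector-to-mask distance in mm
#' @param rank prime rank of the MURA pattern
#' @param cell_pitch_mm pitch of the NTHT cell grid in mm
#' @param hole_diameter_mm diameter of the round mask holes in mm
#' @param mask_thickness_mm mask sheet thickness in mm
#' @param energy_kev source photon energy in keV
#' @param transmission_t fraction of photons transmitted through the closed
#'   mask material (uniform background weight in the forward model)
#' @return an object of class `camera_geometry`
#' @examples
#' g <- camera_geometry()
#' magnification(g, 30)
#' @export
camera_geometry <- function(detector_side_mm = 14.08,
                            detector_pixels = 256L,
                            b_mm = 20,
                            rank = 31L,
                            cell_pitch_mm = 0.08,
                            hole_diameter_mm = 0.08,
                            mask_thickness_mm = 0.11,
                            energy_kev = 59.5,
                            transmission_t = 0.46) {
  stopifnot(detector_side_mm > 0, detector_pixels >= 1,
            b_mm > 0, cell_pitch_mm > 0, hole_diameter_mm > 0,
            mask_thickness_mm >= 0, energy_kev > 0)
  if (!is_prime(rank)) {
    stop("mask rank must be a prime number, got ", rank)
  }
  if (transmission_t < 0 || transmission_t > 1) {
    stop("transmission_t must lie in [0, 1], got ", transmission_t)
  }
  g <- structure(list(
    detector_side_mm  = detector_side_mm,
    detector_pixels   = as.integer(detector_pixels),
    pixel_pitch_mm    = detector_side_mm / detector_pixels,
    b_mm              = b_mm,
    rank              = as.integer(rank),
    cell_pitch_mm     = cell_pitch_mm,
    hole_diameter_mm  = hole_diameter_mm,
    mask_thickness_mm = mask_thickness_mm,
    # NTHT pattern doubled to a 2x2 mosaic: 2 * 2 * rank cells per side
    mask_side_mm      = 4 * rank * cell_pitch_mm,
    energy_kev        = energy_kev,
    transmission_t    = transmission_t
  ), class = "camera_geometry")
  g
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat("Coded-aperture camera geometry\n")
  cat(sprintf("  detector: %d x %d px, %.2f x %.2f mm^2 (pitch %.4f mm)\n",
              x$detector_pixels, x$detector_pixels,
              x$detector_side_mm, x$detector_side_mm, x$pixel_pitch_mm))
  cat(sprintf("  mask: rank-%d NTHT MURA, 2x2 mosaic, side %.2f mm\n",
              x$rank, x$mask_side_mm))
  cat(sprintf("  cell pitch %.3f mm, hole diameter %.3f mm, thickness %.3f mm\n",
              x$cell_pitch_mm, x$hole_diameter_mm, x$mask_thickness_mm))
  cat(sprintf("  detector-to-mask distance b = %.1f mm\n", x$b_mm))
  cat(sprintf("  source energy %.1f keV, mask transmission t = %.2f\n",
              x$energy_kev, x$transmission_t))
  invisible(x)
}

#' Read camera geometry from a YAML config file
#'
#' The file must use exactly the keys `detector_side_mm`, `detector_pixels`,
#' `b_mm`, `rank`, `cell_pitch_mm`, `hole_diameter_mm`, `mask_thickness_mm`,
#' `energy_kev`, `transmission_t` (any subset; missing keys fall back to the
#' defaults of [camera_geometry()]). Unknown keys are rejected.
#'
#' @param path path to a YAML file
#' @return a `camera_geometry` object
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("detector_side_mm", "detector_pixels", "b_mm", "rank",
               "cell_pitch_mm", "hole_diameter_mm", "mask_thickness_mm",
               "energy_kev", "transmission_t")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown geometry config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(camera_geometry, cfg)
}

#' Shadow magnification factor
#'
#' A point source at distance `z` in front of the mask projects the mask
#' pattern onto the detector enlarged by `M = 1 + b/z`, where `b` is the
#' detector-to-mask distance. `M` decreases strictly with `z` and tends to 1
#' for a source at infinity.
#'
#' @param geometry a [camera_geometry()]
#' @param z source-to-mask distance in mm (> 0); may be a vector
#' @return dimensionless magnification factor(s)
#' @export
magnification <- function(geometry, z) {
  stopifnot(inherits(geometry, "camera_geometry"))
  if (any(z <= 0)) stop("source-to-mask distance z must be > 0")
  1 + geometry$b_mm / z
}

#' Field of view at a given distance
#'
#' For the convolution-based reconstructor the field of view equals that of a
#' single pinhole, `detector_side * z / b`. For MURA decoding only one basic
#' mask period is used, so the field of view is taken as the basic pattern's
#' physical side scaled to the object plane, `basic_side * z / b`. The MURA
#' convention is not unique in the literature; the formula used is recorded in
#' the result's `"method"` attribute.
#'
#' @param geometry a [camera_geometry()]
#' @param z source-to-mask distance in mm (> 0)
#' @param method `"pinhole"` or `"mura"`
#' @return field of view in mm at the source plane
#' @export
fov <- function(geometry, z, method = c("pinhole", "mura")) {
  stopifnot(inherits(geometry, "camera_geometry"))
  method <- match.arg(method)
  if (any(z <= 0)) stop("source-to-mask distance z must be > 0")
  side <- switch(method,
    pinhole = geometry$detector_side_mm,
    mura    = basic_side_mm(geometry)
  )
  out <- side * z / geometry$b_mm
  attr(out, "method") <- method
  out
}

# physical side of one basic MURA period (a quarter of the 2x2 mosaic)
basic_side_mm <- function(geometry) {
  geometry$mask_side_mm / 2
}

is_prime <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) return(FALSE)
  if (n < 4L) return(TRUE)
  if (n %% 2L == 0L) return(FALSE)
  k <- 3L
  while (k * k <= n) {
    if (n %% k == 0L) return(FALSE)
    k <- k + 2L
  }
  TRUE
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
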