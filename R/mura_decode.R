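#' Minimum distance at which MURA decoding is possible
#'
#' The central part (one full basic mask period projected at magnification
#' `M(z)`) must fit on the detector; this bounds the decodable range from
#' below at `z_min = b * s / (D - s)` with `s` the basic pattern's physical
#' side and `D` the detector side (about 10.9 mm for the default camera).
#'
#' @param geometry a [camera_geometry()]
#' @return minimum decodable source-to-mask distance in mm
#' @export
min_decodable_z <- function(geometry) {
  s <- basic_side_mm(geometry)
  d <- geometry$detector_side_mm
  if (s >= d) stop("basic mask period larger than the detector; not decodable at any distance")
  geometry$b_mm * s / (d - s)
}

#' Central part of a detector image
#'
#' Extracts the centered square window onto which one entire basic mask
#' period (a quarter of the 2x2 mosaic) is projected at magnification
#' `M(z)`. Its side is `round(basic_side * M(z) / pixel_pitch)` pixels
#' (round half away from zero), so reconstructed image sizes depend on the
#' source-to-mask distance.
#'
#' @param geometry a [camera_geometry()]
#' @param image a [detector_image()] or detector-sized matrix
#' @param z assumed source-to-mask distance in mm
#' @return the window as a matrix, with attributes `side_px` and `offset`
#'   (rows/cols dropped before the window)
#' @export
central_part <- function(geometry, image, z) {
  if (length(z) != 1L || z <= 0) stop("source-to-mask distance z must be > 0")
  p <- if (inherits(image, "detector_image")) image$pixels else image
  n <- geometry$detector_pixels
  stopifnot(all(dim(p) == n))
  side <- central_part_side(geometry, z)
  if (side > n) {
    stop(sprintf(paste0("central part (%d px) exceeds the %d px detector at z = %.1f mm; ",
                        "MURA decoding needs z >= %.1f mm for this camera"),
                 side, n, z, min_decodable_z(geometry)))
  }
  off <- (n - side) %/% 2L
  w <- p[(off + 1L):(off + side), (off + 1L):(off + side)]
  attr(w, "side_px") <- side
  attr(w, "offset") <- off
  w
}

central_part_side <- function(geometry, z) {
  m <- magnification(geometry, z)
  as.integer(round_half_away(basic_side_mm(geometry) * m / geometry$pixel_pitch_mm))
}

#' Reconstruct one in-focus plane by MURA decoding
#'
#' Extracts the central part of the detector image at the magnification of
#' the assumed distance `z` and circularly convolves it (frequency domain)
#' with the signed decoding array resampled by nearest-neighbour to the same
#' pixel grid. Decoded values may be negative; they are not clipped.
#'
#' @param image a [detector_image()] or detector-sized matrix
#' @param geometry a [camera_geometry()]
#' @param z assumed source-to-mask distance in mm
#' @param pattern optional precomputed [mura_mask()]
#' @param resample decoder upsampling: `"nearest"` (default; preserves the
#'   +/-1 balance) or `"bilinear"`
#' @return an object of class `recon_slice`: list with `pixels`, `z`,
#'   `side_px`
#' @export
mura_decode <- function(image, geometry, z, pattern = NULL,
                        resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  if (is.null(pattern)) pattern <- mura_mask(geometry$rank)
  w <- central_part(geometry, image, z)
  s <- attr(w, "side_px")
  d <- resample_decoder(pattern$decoding, s, resample)
  rec <- circular_xcorr(unclass_attr(w), d)
  structure(list(pixels = rec, z = z, side_px = s), class = "recon_slice")
}

# upsampling of the signed basic decoding array to an s x s pixel grid;
# nearest-neighbour preserves the +/-1 balance within rounding of cell edges
resample_decoder <- function(g, s, method = "nearest") {
  if (method == "bilinear") return(bilinear_resize(g, s))
  r <- nrow(g)
  idx <- floor((seq_len(s) - 0.5) * r / s) + 1L
  idx[idx > r] <- r
  g[idx, idx, drop = FALSE]
}

unclass_attr <- function(w) {
  attr(w, "side_px") <- NULL
  attr(w, "offset") <- NULL
  w
}

#' @export
print.recon_slice <- function(x, ...) {
  cat(sprintf("reconstructed slice at z = %.1f mm, %d x %d px\n",
              x$z, x$side_px, x$side_px))
  invisible(x)
}

#' Decode an image stack over a grid of distances
#'
#' Runs [mura_decode()] at every `z` of the grid. Distances below the minimum
#' decodable bound are collected (attribute `undecodable_z`, with a warning)
#' rather than aborting the stack. With `resize = TRUE` all slices are
#' bilinearly interpolated to the pixel size of the reference slice — the
#' slice at the grid point closest to `reference_z` (by default the assumed
#' source distance should be passed; otherwise the grid median is used) — so
#' that region-of-interest positions are comparable across the stack.
#'
#' @param image a [detector_image()] or detector-sized matrix
#' @param geometry a [camera_geometry()]
#' @param z_grid increasing vector of distances in mm
#' @param resize logical; resize all slices to the reference slice's size?
#' @param reference_z distance whose reconstruction size is the common size
#' @param pattern optional precomputed [mura_mask()]
#' @return an [image_stack()]
#' @export
decode_stack <- function(image, geometry, z_grid, resize = TRUE,
                         reference_z = stats::median(z_grid), pattern = NULL) {
  if (is.null(pattern)) pattern <- mura_mask(geometry$rank)
  n <- geometry$detector_pixels
  ok <- central_part_sides_ok(geometry, z_grid, n)
  if (!any(ok)) {
    stop(sprintf("no distance in the grid is decodable; minimum decodable z is %.1f mm",
                 min_decodable_z(geometry)))
  }
  if (any(!ok)) {
    warning(sprintf("dropping %d undecodable distance(s) below %.1f mm: %s",
                    sum(!ok), min_decodable_z(geometry),
                    paste(z_grid[!ok], collapse = ", ")))
  }
  zs <- z_grid[ok]
  slices <- lapply(zs, function(z) mura_decode(image, geometry, z, pattern))
  resized <- FALSE
  if (resize && length(zs) > 1L) {
    ref <- which.min(abs(zs - reference_z))
    target <- slices[[ref]]$side_px
    slices <- lapply(slices, function(sl) {
      sl$pixels <- bilinear_resize(sl$pixels, target)
      sl$side_px <- target
      sl
    })
    resized <- TRUE
  }
  image_stack(slices, method = "mura", resized = resized,
              undecodable_z = z_grid[!ok])
}

central_part_sides_ok <- function(geometry, z_grid, n) {
  vapply(z_grid, function(z) central_part_side(geometry, z) <= n, logical(1))
}

#' Image stack container
#'
#' An ordered set of reconstructions of one detector image at successive
#' distances.
#'
#' @param slices list of `recon_slice` objects with strictly increasing `z`
#' @param method reconstruction method tag (`"mura"` or `"mlem"`)
#' @param resized logical; were slices interpolated to a common size?
#' @param undecodable_z distances that could not be reconstructed
#' @param diagnostics optional per-iteration diagnostics (MLEM)
#' @return an object of class `image_stack`
#' @export
image_stack <- function(slices, method, resized = FALSE,
                        undecodable_z = numeric(0), diagnostics = NULL) {
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (is.unsorted(z, strictly = TRUE)) {
    stop("slice distances must be strictly increasing")
  }
  structure(list(z = z, slices = slices, method = method,
                 step = if (length(z) > 1L) stats::median(diff(z)) else NA_real_,
                 resized = resized, undecodable_z = undecodable_z,
                 diagnostics = diagnostics),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image stack (%s): %d slices, z = %.1f .. %.1f mm (step %.2f mm)%s\n",
              x$method, length(x$z), min(x$z), max(x$z), x$step,
              if (x$resized) ", resized" else ""))
  if (length(x$undecodable_z)) {
    cat("  undecodable z:", paste(x$undecodable_z, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.image_stack <- function(x, z = x$z[which.max(vapply(x$slices, function(s) max(s$pixels), numeric(1)))], ...) {
  i <- which.min(abs(x$z - z))
  sl <- x$slices[[i]]
  graphics::image(sl$pixels, asp = 1, axes = FALSE, useRaster = TRUE,
                  main = sprintf("%s reconstruction at z = %.1f mm", x$method, sl$z), ...)
  invisible(x)
}
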