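#' Rasterize the mask point-spread function at a source distance
#'
#' Projects the 2x2 mask mosaic, magnified by `M(z) = 1 + b/z`, onto the
#' detector pixel grid, centered on the detector. Each pixel value is the
#' fraction of the pixel covered by open mask area, estimated by `supersample`
#' x `supersample` point sampling per pixel, so values lie in `[0, 1]`.
#'
#' Two hole conventions are supported: `"NTHT"` renders the physical mask —
#' round holes of `hole_diameter_mm` in every other cell of the fine cell grid
#' — while `"THT"` (two-holes-touching) renders contiguous square holes that
#' fill whole cells of the basic pattern at doubled cell pitch. The THT form
#' is the one used as the MLEM point-spread function, which avoids the
#' periodic background structure that the NTHT form induces.
#'
#' @param geometry a [camera_geometry()]
#' @param pattern a [mura_mask()] bundle (rank must match the geometry)
#' @param z source-to-mask distance in mm (> 0)
#' @param mode `"THT"` or `"NTHT"`
#' @param supersample samples per pixel side (default 8)
#' @return an object of class `psf_image`: list with `pixels` (detector-sized
#'   matrix), `z`, `mode`, `magnification`
#' @export
rasterize_psf <- function(geometry, pattern, z, mode = c("THT", "NTHT"),
                          supersample = 8L) {
  stopifnot(inherits(geometry, "camera_geometry"),
            inherits(pattern, "mask_pattern"))
  mode <- match.arg(mode)
  if (length(z) != 1L || z <= 0) stop("source-to-mask distance z must be > 0")
  if (pattern$rank != geometry$rank) {
    stop("mask pattern rank (", pattern$rank,
         ") does not match geometry rank (", geometry$rank, ")")
  }
  m <- magnification(geometry, z)
  if (geometry$mask_side_mm * m < geometry$pixel_pitch_mm) {
    stop("magnified mask pattern is smaller than one detector pixel")
  }
  n <- geometry$detector_pixels
  f <- as.integer(supersample)
  stopifnot(f >= 1L)

  # supersample coordinates (mm from detector center), projected to the mask
  # plane by 1/M (centered point source, mask center over detector center)
  xs <- ((seq_len(n * f) - 0.5) * (geometry$pixel_pitch_mm / f) -
           geometry$detector_side_mm / 2) / m
  half <- geometry$mask_side_mm / 2

  if (mode == "THT") {
    # square holes filling whole basic-pattern cells at doubled pitch
    pitch <- 2 * geometry$cell_pitch_mm
    grid <- pattern$mosaic_tht
    ci <- floor((xs + half) / pitch) + 1
    ok <- ci >= 1 & ci <= nrow(grid)
    ci[!ok] <- 1L
    v <- grid[ci, ci, drop = FALSE]
    v[!ok, ] <- 0L
    v[, !ok] <- 0L
    pix <- block_mean(v, f)
  } else {
    # round holes of hole_diameter in every other cell of the fine grid
    pitch <- geometry$cell_pitch_mm
    grid <- pattern$mosaic
    ci <- floor((xs + half) / pitch) + 1
    ok <- ci >= 1 & ci <= nrow(grid)
    cii <- ci
    cii[!ok] <- 1L
    open <- grid[cii, cii, drop = FALSE]
    open[!ok, ] <- 0L
    open[, !ok] <- 0L
    # distance from the cell center, separable in x and y
    centers <- -half + (ci - 0.5) * pitch
    d <- xs - centers
    r2 <- (geometry$hole_diameter_mm / 2)^2
    inside <- outer(d^2, d^2, "+") <= r2
    v <- open * inside
    pix <- block_mean(v, f)
  }

  structure(list(pixels = pix, z = z, mode = mode, magnification = m,
                 supersample = f),
            class = "psf_image")
}

#' @export
print.psf_image <- function(x, ...) {
  cat(sprintf("PSF image (%s) at z = %.1f mm, M = %.3f\n",
              x$mode, x$z, x$magnification))
  cat(sprintf("  %d x %d px, total open-area integral %.1f px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}
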