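# rescale a slice to [0, 1]; the CNR is invariant under per-slice affine
# rescaling, and unit scale keeps the exact ROI moment sums well conditioned
norm01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' CNR profile of an image stack
#'
#' Computes the contrast-to-noise ratio of every slice of a stack with a
#' frozen set of regions of interest: all ROI placements are sampled on the
#' in-focus slice, the signal ROI is the highest-mean ROI in the inner 50 %
#' of the image area, ROIs overlapping it are discarded, all others are
#' background; signal and background positions are then kept fixed for every
#' slice of the stack. Slices must share one pixel size (resize MURA stacks
#' first).
#'
#' @param stack an [image_stack()]
#' @param diameter ROI diameter in px (see [roi_diameter()])
#' @param in_focus_z distance of the in-focus slice (nearest slice is used)
#' @param sigma_b background-noise estimator: `"roi_mean"` (default) averages
#'   the per-ROI standard deviations; `"pooled"` pools the per-ROI variances
#'   of all background ROIs
#' @return list with `z`, `cnr`, `signal` (frozen signal ROI), `diameter`,
#'   `n_roi` (number of ROI placements per slice)
#' @export
stack_cnr_profile <- function(stack, diameter, in_focus_z,
                              sigma_b = c("roi_mean", "pooled")) {
  sigma_b <- match.arg(sigma_b)
  stopifnot(inherits(stack, "image_stack"))
  sides <- vapply(stack$slices, function(s) s$side_px, numeric(1))
  if (length(unique(sides)) != 1L) {
    stop("stack slices have differing pixel sizes; decode with resize = TRUE")
  }
  i0 <- which.min(abs(stack$z - in_focus_z))
  focus <- norm01(stack$slices[[i0]]$pixels)
  tab <- sample_rois(focus, diameter)
  sig <- select_signal_roi(tab)
  bg <- sig$background

  profile <- vapply(seq_along(stack$z), function(i) {
    maps <- roi_maps(norm01(stack$slices[[i]]$pixels), diameter)
    means <- as.vector(maps$mean)
    sds <- as.vector(maps$sd)
    if (sigma_b == "pooled") {
      s <- sqrt(mean(sds[bg]^2))
      if (s == 0) stop("degenerate background: pooled standard deviation is 0")
      (means[sig$index] - mean(means[bg])) / s
    } else {
      cnr(means[sig$index], means[bg], sds[bg])
    }
  }, numeric(1))

  list(z = stack$z, cnr = profile, signal = sig[c("row", "col", "index")],
       diameter = diameter, n_roi = nrow(tab))
}

# ghost-source heuristic: count distinct local maxima above half the global
# maximum whose centers lie outside the inner 50% of the image area
detect_ghosts <- function(slice_px) {
  side <- nrow(slice_px)
  thr <- 0.5 * max(slice_px)
  if (thr <= 0) return(FALSE)
  half <- side / sqrt(2) / 2
  c0 <- (side + 1) / 2
  hits <- which(slice_px >= thr, arr.ind = TRUE)
  outer_hits <- hits[abs(hits[, 1] - c0) > half | abs(hits[, 2] - c0) > half, ,
                     drop = FALSE]
  if (nrow(outer_hits) == 0L) return(FALSE)
  # cluster by rounding to a coarse grid; >= 2 separated clusters flag ghosts
  key <- unique(paste(round(outer_hits[, 1] / 8), round(outer_hits[, 2] / 8)))
  length(key) >= 2L
}

#' Measure the axial resolution of one detector image
#'
#' Implements the semi-automatic assessment procedure: (1) if the true source
#' distance is unknown, reconstruct over a broad coarse grid (5–100 mm in
#' 5 mm steps) and locate the source at the slice with the highest CNR;
#' (2) reconstruct a fine stack in 0.5 mm steps around the located distance;
#' (3) sample all ROI placements, freeze the signal/background set found on
#' the in-focus slice, compute the CNR profile along z; (4) fit the offset
#' Gaussian and report `FWHM = 2 sqrt(2 ln 2) delta` with its fit
#' uncertainty.
#'
#' MURA stacks are resized by bilinear interpolation to the in-focus slice's
#' image size; 3D-MLEM stacks keep the fixed detector size. The default fine
#' half-widths (15 mm for MURA decoding, 13.5 mm for 3D-MLEM, clipped to the
#' decodable range) give stack sizes of the order 55–61 slices.
#'
#' @param image a [detector_image()]
#' @param geometry a [camera_geometry()]
#' @param method `"mura"` or `"mlem"`
#' @param truth_z true source-to-mask distance in mm if known; when supplied
#'   the coarse localization stage is skipped and the in-focus slice is the
#'   slice at the true distance
#' @param preprocess apply [preprocess_detector()] first?
#' @param fine_step fine stack spacing in mm (default 0.5)
#' @param fine_halfwidth half-width of the fine z-window in mm
#' @param coarse_grid distances for the coarse localization stage
#' @param iterations 3D-MLEM iteration count (default 40)
#' @param pattern,psfs,supersample forwarded to the reconstructors
#' @return an object of class `resolution_result`
#' @export
assess_axial <- function(image, geometry, method = c("mura", "mlem"),
                         truth_z = NULL, preprocess = FALSE,
                         fine_step = 0.5,
                         fine_halfwidth = if (method == "mura") 15 else 13.5,
                         coarse_grid = seq(5, 100, by = 5),
                         iterations = 40L, pattern = NULL, psfs = NULL,
                         supersample = 8L) {
  method <- match.arg(method)
  stopifnot(inherits(image, "detector_image"))
  if (is.null(pattern)) pattern <- mura_mask(geometry$rank)
  preprocessing <- if (preprocess) "preprocessed" else "raw"
  if (preprocess) image <- preprocess_detector(image)

  z_loc <- if (!is.null(truth_z)) {
    truth_z
  } else {
    coarse_localize(image, geometry, method, coarse_grid, iterations,
                    pattern, psfs, supersample)
  }

  zmin_ok <- if (method == "mura") min_decodable_z(geometry) + 1e-6 else fine_step
  z_lo <- max(z_loc - fine_halfwidth, zmin_ok)
  z_hi <- z_loc + fine_halfwidth
  # grid aligned so that z_loc is a grid point
  z_grid <- sort(unique(c(rev(seq(z_loc, z_lo, by = -fine_step)),
                          seq(z_loc, z_hi, by = fine_step))))

  stack <- if (method == "mura") {
    suppressWarnings(decode_stack(image, geometry, z_grid, resize = TRUE,
                                  reference_z = z_loc, pattern = pattern))
  } else {
    reconstruct_3d(image, geometry, z_grid, iterations = iterations,
                   pattern = pattern, psfs = psfs, supersample = supersample)
  }

  i0 <- which.min(abs(stack$z - z_loc))
  side <- stack$slices[[i0]]$side_px
  d <- roi_diameter(geometry, z_loc,
                    method = if (method == "mura") "mura" else "pinhole",
                    image_side_px = side,
                    source_fwhm_mm = image$meta$source_fwhm_mm %||% 0.65)
  prof <- stack_cnr_profile(stack, d, z_loc)
  fit <- fit_cnr_profile(prof$z, prof$cnr)
  ghost <- detect_ghosts(norm01(stack$slices[[i0]]$pixels))

  structure(list(
    method = method, preprocessing = preprocessing,
    source_z_mm = z_loc, truth_z_mm = truth_z,
    axial_fwhm_mm = fit$fwhm_mm, axial_fwhm_sd_mm = fit$fwhm_sd_mm,
    gamma_mm = fit$coefficients[["gamma"]],
    fit = fit, roi_diameter_px = d, n_roi = prof$n_roi,
    n_slices = length(stack$z), image_side_px = side,
    ghost_flag = ghost, stack = stack, in_focus_index = i0
  ), class = "resolution_result")
}

coarse_localize <- function(image, geometry, method, coarse_grid, iterations,
                            pattern, psfs, supersample) {
  if (method == "mura") {
    ok <- central_part_sides_ok(geometry, coarse_grid, geometry$detector_pixels)
    coarse_grid <- coarse_grid[ok]
    if (!length(coarse_grid)) stop("no decodable distance in the coarse grid")
    stack <- suppressWarnings(decode_stack(image, geometry, coarse_grid,
                                           resize = FALSE, pattern = pattern))
  } else {
    stack <- reconstruct_3d(image, geometry, coarse_grid,
                            iterations = iterations, pattern = pattern,
                            psfs = psfs, supersample = supersample)
  }
  # signal search re-run per coarse slice, each with its own ROI size
  best <- vapply(seq_along(stack$z), function(i) {
    sl <- stack$slices[[i]]
    d <- roi_diameter(geometry, sl$z,
                      method = if (method == "mura") "mura" else "pinhole",
                      image_side_px = sl$side_px)
    tab <- sample_rois(norm01(sl$pixels), d)
    sig <- select_signal_roi(tab)
    cnr(tab$mean[sig$index], tab$mean[sig$background], tab$sd[sig$background])
  }, numeric(1))
  stack$z[which.max(best)]
}

#' Measure the lateral resolution from an in-focus slice
#'
#' Takes the slice profile along the row with the highest pixel intensity,
#' fits a Gaussian with offset, and converts the FWHM from pixels to mm via
#' the field of view of the reconstruction.
#'
#' @param in_focus a `recon_slice` or square matrix (in-focus reconstruction)
#' @param fov_mm field of view of the reconstruction in mm (see [fov()])
#' @return lateral FWHM in mm, with attributes `fwhm_px`, `row`, `fit`
#' @export
assess_lateral <- function(in_focus, fov_mm) {
  px <- if (inherits(in_focus, "recon_slice")) in_focus$pixels else in_focus
  side <- nrow(px)
  peak <- which(px == max(px), arr.ind = TRUE)[1, ]
  prof <- px[peak[1], ]
  fit <- fit_cnr_profile(seq_len(side), prof)   # same offset-Gaussian model
  fwhm_px <- fit$fwhm_mm                        # here in pixel units
  out <- fwhm_px * fov_mm / side
  attr(out, "fwhm_px") <- fwhm_px
  attr(out, "row") <- unname(peak[1])
  attr(out, "fit") <- fit
  out
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("%s axial resolution (%s detector image)\n",
              toupper(x$method), x$preprocessing))
  cat(sprintf("  source distance: %.1f mm; fitted peak gamma = %.2f mm\n",
              x$source_z_mm, x$gamma_mm))
  cat(sprintf("  axial FWHM = %.2f +/- %.2f mm\n",
              x$axial_fwhm_mm, x$axial_fwhm_sd_mm))
  cat(sprintf("  stack: %d slices of %d px; ROI diameter %d px (%d placements)\n",
              x$n_slices, x$image_side_px, x$roi_diameter_px, x$n_roi))
  if (isTRUE(x$ghost_flag)) cat("  note: ghost sources detected near the image border\n")
  invisible(x)
}

#' @export
plot.resolution_result <- function(x, ...) {
  plot(x$fit, main = sprintf("%s CNR profile, source at %.1f mm",
                             toupper(x$method), x$source_z_mm), ...)
  invisible(x)
}

#' @export
fwhm.resolution_result <- function(object, ...) object$axial_fwhm_mm
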