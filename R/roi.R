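#' Region-of-interest diameter for a resolution measurement
#'
#' Converts the physical source FWHM to pixels at the field of view of the
#' true source distance and rounds to the nearest integer (at least 1 px).
#'
#' @param geometry a [camera_geometry()]
#' @param z true source-to-mask distance in mm
#' @param method FOV convention, `"mura"` or `"pinhole"` (see [fov()])
#' @param image_side_px side of the reconstructed image in pixels
#' @param source_fwhm_mm physical source FWHM in mm
#' @return integer ROI diameter in pixels
#' @export
roi_diameter <- function(geometry, z, method = c("pinhole", "mura"),
                         image_side_px = geometry$detector_pixels,
                         source_fwhm_mm = 0.65) {
  method <- match.arg(method)
  if (z <= 0) stop("source-to-mask distance z must be > 0")
  px_mm <- as.numeric(fov(geometry, z, method)) / image_side_px
  d <- as.integer(round_half_away(source_fwhm_mm / px_mm))
  if (d < 1L) {
    warning("ROI diameter rounded to 0 px; clamping to 1 px")
    d <- 1L
  }
  d
}

# pixel offsets (0-based, within the d x d bounding box) of a circular ROI:
# pixels whose centers fall within the disc of the given diameter centered on
# the bounding-box center
disc_offsets <- function(diameter) {
  c0 <- (diameter + 1) / 2
  ij <- expand.grid(i = seq_len(diameter), j = seq_len(diameter))
  keep <- (ij$i - c0)^2 + (ij$j - c0)^2 <= (diameter / 2)^2
  ij[keep, , drop = FALSE]
}

# dense maps of ROI mean and (sample) standard deviation over every
# fully-contained placement: exact shift-accumulate over disc offsets,
# avoiding the cancellation error of FFT-based moments
roi_maps <- function(img, diameter) {
  side <- nrow(img)
  stopifnot(ncol(img) == side, diameter >= 1, diameter <= side)
  off <- disc_offsets(diameter)
  npix <- nrow(off)
  m <- side - diameter + 1L
  s1 <- matrix(0, m, m)
  s2 <- matrix(0, m, m)
  img2 <- img * img
  for (k in seq_len(npix)) {
    ri <- off$i[k]:(off$i[k] + m - 1L)
    ci <- off$j[k]:(off$j[k] + m - 1L)
    s1 <- s1 + img[ri, ci]
    s2 <- s2 + img2[ri, ci]
  }
  mean_map <- s1 / npix
  var_map <- (s2 - s1 * s1 / npix) / max(npix - 1L, 1L)
  var_map[var_map < 0] <- 0
  list(mean = mean_map, sd = sqrt(var_map), npix = npix, m = m,
       diameter = diameter, side = side)
}

#' Sample all circular region-of-interest placements of an image
#'
#' Every fully-contained position of a circular ROI of the given diameter is
#' sampled on the integer pixel grid (dense sliding placement, stride 1 px),
#' giving `(side - diameter + 1)^2` placements. For each ROI the center, the
#' mean intensity and the sample standard deviation are returned.
#'
#' @param image square matrix (one reconstructed slice)
#' @param diameter ROI diameter in pixels
#' @return an object of class `roi_table`: a data frame with columns
#'   `row`, `col` (ROI center, possibly half-integer for even diameters),
#'   `mean`, `sd`; attributes `diameter`, `image_side_px`, `npix`
#' @export
sample_rois <- function(image, diameter) {
  maps <- roi_maps(image, diameter)
  c0 <- (diameter - 1) / 2
  centers <- seq_len(maps$m) + c0
  tab <- data.frame(
    row = rep(centers, times = maps$m),
    col = rep(centers, each = maps$m),
    mean = as.vector(maps$mean),
    sd = as.vector(maps$sd)
  )
  structure(tab, class = c("roi_table", "data.frame"),
            diameter = diameter, image_side_px = maps$side, npix = maps$npix)
}

#' Select the signal ROI on the in-focus slice
#'
#' Picks the ROI with the highest mean intensity among those whose center
#' lies in the inner 50 % of the image area — the centered square of side
#' `image_side / sqrt(2)` — to avoid locking onto ghost sources along the
#' image border. Exact ties are broken deterministically (lowest row, then
#' lowest column) with a warning. ROIs overlapping the signal (center
#' distance < diameter) are flagged as excluded; the rest form the background
#' set.
#'
#' @param table a `roi_table` from [sample_rois()]
#' @param inner `"area"` restricts to half the image *area* (side/sqrt(2));
#'   `"side"` restricts to half the side length
#' @return list with `row`, `col`, `mean`, `sd`, `index` of the signal ROI
#'   and logical vector `background` marking non-overlapping ROIs
#' @export
select_signal_roi <- function(table, inner = c("area", "side")) {
  inner <- match.arg(inner)
  side <- attr(table, "image_side_px")
  d <- attr(table, "diameter")
  half_side <- if (inner == "area") side / sqrt(2) else side / 2
  c0 <- (side + 1) / 2
  cand <- abs(table$row - c0) <= half_side / 2 &
          abs(table$col - c0) <= half_side / 2
  if (!any(cand)) stop("no ROI center lies within the inner region of the image")
  best <- max(table$mean[cand])
  hits <- which(cand & table$mean == best)
  if (length(hits) > 1L) {
    warning("multiple ROIs tie for the highest mean; picking lowest row, then column")
    ord <- order(table$row[hits], table$col[hits])
    hits <- hits[ord]
  }
  i <- hits[1L]
  dist2 <- (table$row - table$row[i])^2 + (table$col - table$col[i])^2
  background <- dist2 >= d^2          # center distance >= diameter: disjoint discs
  background[i] <- FALSE
  list(row = table$row[i], col = table$col[i], mean = table$mean[i],
       sd = table$sd[i], index = i, background = background)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (S - B) / sigma_B`, where `B` is the mean of the background ROI
#' means and `sigma_B` the mean of the background ROI standard deviations.
#'
#' @param signal_mean mean intensity of the signal ROI
#' @param background_means vector of background ROI mean intensities
#' @param background_stds vector of background ROI standard deviations
#' @return dimensionless CNR
#' @export
cnr <- function(signal_mean, background_means, background_stds) {
  if (length(background_means) < 1L) stop("at least one background ROI is required")
  sb <- mean(background_stds)
  if (sb == 0) stop("degenerate background: mean background standard deviation is 0")
  (signal_mean - mean(background_means)) / sb
}
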