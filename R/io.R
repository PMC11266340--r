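#' Read a detector image from disk
#'
#' Text images are whitespace-delimited floats, row-major, one detector row
#' per line; TIFF images are single-page 32-bit float. The matrix must be
#' square and non-negative.
#'
#' @param path file path
#' @param format `"text"` or `"tiff"`; guessed from the extension by default
#' @return a [detector_image()] with provenance metadata
#' @export
read_detector_image <- function(path, format = c("auto", "text", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tiff") {
    px <- tiff::readTIFF(path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    scale_file <- paste0(path, ".scale")
    if (file.exists(scale_file)) {
      px <- px * as.numeric(readLines(scale_file, n = 1L))
    }
    px <- matrix(as.numeric(px), nrow = nrow(px))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (anyNA(v)) stop(sprintf("malformed detector image %s: non-numeric token on line %d", path, i))
      v
    })
    len <- lengths(rows)
    if (length(unique(len)) != 1L) {
      stop(sprintf("malformed detector image %s: ragged rows (line %d has %d values, line 1 has %d)",
                   path, which(len != len[1])[1], len[len != len[1]][1], len[1]))
    }
    px <- do.call(rbind, rows)
  }
  if (nrow(px) != ncol(px)) {
    stop(sprintf("detector image must be square; %s is %d x %d",
                 path, nrow(px), ncol(px)))
  }
  detector_image(px, meta = list(provenance = "measured", path = path,
                                 preprocessed = FALSE))
}

#' Write a detector image to disk
#'
#' The text format round-trips bit-identically (`%.17g` per value); TIFF is
#' written as single-page 32-bit float and is therefore lossy for doubles.
#'
#' @param image a [detector_image()] or matrix
#' @param path output file path
#' @param format `"text"` or `"tiff"`; guessed from the extension by default
#' @export
write_detector_image <- function(image, path, format = c("auto", "text", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  }
  px <- if (inherits(image, "detector_image")) image$pixels else image
  if (format == "tiff") {
    # TIFF float samples are clamped to [0,1]; counts are stored normalized,
    # with the scale factor in a sidecar "<path>.scale" file
    scale <- max(px, 1e-300)
    tiff::writeTIFF(px / scale, path, bits.per.sample = 32L)
    writeLines(sprintf("%.17g", scale), paste0(path, ".scale"))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(px))) {
      writeLines(paste(sprintf("%.17g", px[i, ]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write an image stack as multi-page TIFF plus a sidecar table
#'
#' Each slice is min-max normalized to `[0, 1]` (TIFF float convention); the
#' sidecar tab-separated table records `z`, `side_px`, and the original
#' `min`/`max` per slice so absolute values can be restored.
#'
#' @param stack an [image_stack()]
#' @param path output TIFF path; the sidecar is `<path>.tsv`
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$slices, function(s) norm01(s$pixels))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  info <- data.frame(
    z = stack$z,
    side_px = vapply(stack$slices, function(s) s$side_px, numeric(1)),
    min = vapply(stack$slices, function(s) min(s$pixels), numeric(1)),
    max = vapply(stack$slices, function(s) max(s$pixels), numeric(1))
  )
  utils::write.table(info, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Catalog the deposited set of measured detector images
#'
#' The measured dataset consists of 21 detector images of a point-like
#' source at 12–20 mm in 2 mm steps and 25–100 mm in 5 mm steps, in raw and
#' preprocessed variants. Given a local directory, files are discovered by
#' parsing the source-to-mask distance from their names (first integer
#' followed by an optional "mm"); given a URL the archive must first be
#' downloaded manually (no network access is assumed). Missing distances are
#' reported in the error.
#'
#' @param path local directory containing the image files
#' @param pattern filename regex for image files
#' @return data frame with columns `z_mm`, `variant` (`raw`/`preprocessed`),
#'   `path`, `md5`
#' @export
fetch_dataset <- function(path, pattern = "\\.(txt|tsv|tif|tiff)$") {
  expected <- dataset_distances()
  if (grepl("^https?://", path)) {
    stop("network download is not performed automatically; download the ",
         "deposited archive manually and pass its local directory")
  }
  if (!dir.exists(path)) stop("dataset directory not found: ", path)
  files <- list.files(path, pattern = pattern, full.names = TRUE,
                      recursive = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("no image files found under ", path)
  z <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\s*mm.*", "\\1",
                                       basename(files))))
  bad <- !is.finite(z)
  z[bad] <- suppressWarnings(as.numeric(sub("\\D*(\\d+).*", "\\1",
                                            basename(files)[bad])))
  variant <- ifelse(grepl("preproc|smooth|filtered", basename(files),
                          ignore.case = TRUE), "preprocessed", "raw")
  cat_df <- data.frame(z_mm = z, variant = variant, path = files,
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  cat_df <- cat_df[is.finite(cat_df$z_mm) & cat_df$z_mm %in% expected, ]
  missing <- setdiff(expected, unique(cat_df$z_mm))
  if (length(missing)) {
    stop("dataset incomplete; missing source-to-mask distance(s) [mm]: ",
         paste(missing, collapse = ", "))
  }
  cat_df[order(cat_df$z_mm, cat_df$variant), ]
}

#' The 21 source-to-mask distances of the measured dataset
#' @return numeric vector in mm
#' @export
dataset_distances <- function() {
  c(seq(12, 20, by = 2), seq(25, 100, by = 5))
}
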