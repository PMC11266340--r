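#' Preprocess a raw detector image
#'
#' Outlier handling followed by smoothing: pixels with values strictly below
#' the 1st or strictly above the 99th percentile of the image are replaced by
#' the median of their 3x3 neighborhood (truncated at the borders), then the
#' image is smoothed with a Gaussian of sigma 1 pixel (reflected boundaries).
#' By construction at most ~2 % of the pixels are touched by the outlier
#' rule; a constant image passes through unchanged.
#'
#' @param raw a [detector_image()] or non-negative square matrix
#' @return a [detector_image()] with `meta$preprocessed = TRUE`
#' @export
preprocess_detector <- function(raw) {
  is_di <- inherits(raw, "detector_image")
  x <- if (is_di) raw$pixels else raw
  stopifnot(is.matrix(x), all(x >= 0))
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  out <- which(x < q[1] | x > q[2])
  if (length(out)) {
    n <- nrow(x)
    m <- ncol(x)
    repl <- x
    rc <- arrayInd(out, dim(x))
    for (k in seq_along(out)) {
      i <- rc[k, 1]; j <- rc[k, 2]
      nb <- x[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(m, j + 1)]
      repl[i, j] <- stats::median(nb)
    }
    x <- repl
  }
  x <- gaussian_smooth(x, sigma = 1)
  x[x < 0] <- 0
  meta <- if (is_di) raw$meta else list(provenance = "unknown")
  meta$preprocessed <- TRUE
  detector_image(x, meta)
}
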