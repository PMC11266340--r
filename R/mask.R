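#' Basic MURA aperture pattern
#'
#' Generates the rank-`r` modified uniformly redundant array by the standard
#' quadratic-residue construction: cell `(i, j)` (0-based) is open iff
#' `i != 0` and (`j == 0` or the quadratic-residue characters of `i` and `j`
#' modulo the prime rank are equal). Row `i = 0` is entirely closed and the
#' pattern has exactly `(rank^2 - 1) / 2` open cells.
#'
#' @param rank prime rank of the array
#' @return a `rank` x `rank` binary (0/1) integer matrix
#' @examples
#' sum(mura_basic(31)) # 480 open cells
#' @export
mura_basic <- function(rank) {
  rank <- as.integer(rank)
  if (!is_prime(rank)) {
    stop("MURA patterns exist only for prime rank; got ", rank)
  }
  qr <- quadratic_residues(rank)
  chr <- rep(-1L, rank)          # chr[i+1] = +1 if i is a QR mod rank
  chr[qr + 1L] <- 1L
  a <- matrix(0L, rank, rank)
  for (i in seq_len(rank - 1L)) { # i = 1 .. rank-1 (0-based), row 0 closed
    a[i + 1L, 1L] <- 1L           # column j = 0 open for i != 0
    open <- chr[i + 1L] == chr[2:rank]
    a[i + 1L, 1L + which(open)] <- 1L
  }
  a
}

quadratic_residues <- function(p) {
  sort(unique((seq_len(p - 1L)^2) %% p))
}

#' Expand a basic pattern to its no-two-holes-touching (NTHT) form
#'
#' Each cell of the input is placed on a grid of doubled side with one empty
#' cell between any two holes: cell `(2i, 2j)` (0-based) of the output copies
#' cell `(i, j)` of the input, all other cells are closed. The open-cell count
#' is preserved.
#'
#' @param basic binary matrix
#' @return binary matrix of doubled side
#' @export
expand_ntht <- function(basic) {
  check_binary(basic)
  n <- nrow(basic)
  m <- ncol(basic)
  out <- matrix(0L, 2L * n, 2L * m)
  out[seq(1L, 2L * n, by = 2L), seq(1L, 2L * m, by = 2L)] <- as.integer(basic)
  out
}

#' Tile a pattern into a plain 2x2 mosaic
#'
#' Duplicates the pattern in a 2x2 arrangement, quadrupling the open-cell
#' count. For the default rank-31 NTHT pattern this yields 124 x 124 cells,
#' i.e. a 9.92 mm mask at 0.08 mm cell pitch.
#'
#' @param pattern square binary matrix
#' @return binary matrix of doubled side
#' @export
tile_mosaic <- function(pattern) {
  check_binary(pattern)
  if (nrow(pattern) != ncol(pattern)) stop("pattern must be square")
  rbind(cbind(pattern, pattern), cbind(pattern, pattern))
}

#' MURA decoding array
#'
#' The signed (+1/-1) inverse filter of a basic MURA pattern:
#' `G = 2A - 1` with the `(0,0)` element forced to +1. Circular
#' cross-correlation of the 2x2-tiled basic pattern with this array is a
#' delta function up to a constant offset (perfectly flat sidelobes).
#'
#' @param basic a basic MURA pattern as returned by [mura_basic()]
#' @return signed integer matrix of the same dimensions with entries +1/-1
#' @export
decoding_array <- function(basic) {
  check_binary(basic)
  g <- 2L * as.integer(basic) - 1L
  dim(g) <- dim(basic)
  g[1L, 1L] <- 1L
  g
}

#' Full mask pattern bundle
#'
#' Convenience constructor assembling the basic pattern, its NTHT expansion,
#' the 2x2 mosaic of the NTHT pattern (the physical mask), the
#' two-holes-touching (THT) mosaic used for the MLEM point-spread function,
#' and the signed decoding array.
#'
#' @param rank prime rank (default 31)
#' @return an object of class `mask_pattern` with elements `rank`, `basic`,
#'   `ntht`, `mosaic` (2x2 tiling of `ntht`), `mosaic_tht` (2x2 tiling of
#'   `basic`, holes filling whole cells at doubled pitch) and `decoding`
#' @export
mura_mask <- function(rank = 31L) {
  basic <- mura_basic(rank)
  ntht <- expand_ntht(basic)
  structure(list(
    rank       = as.integer(rank),
    basic      = basic,
    ntht       = ntht,
    mosaic     = tile_mosaic(ntht),
    mosaic_tht = tile_mosaic(basic),
    decoding   = decoding_array(basic)
  ), class = "mask_pattern")
}

#' @export
print.mask_pattern <- function(x, ...) {
  cat(sprintf("rank-%d MURA mask pattern\n", x$rank))
  cat(sprintf("  basic: %dx%d, %d open cells\n",
              nrow(x$basic), ncol(x$basic), sum(x$basic)))
  cat(sprintf("  NTHT: %dx%d; 2x2 mosaic: %dx%d cells\n",
              nrow(x$ntht), ncol(x$ntht), nrow(x$mosaic), ncol(x$mosaic)))
  invisible(x)
}

#' Circular 2D cross-correlation
#'
#' `r[di, dj] = sum_{u,v} a[u + di, v + dj] * b[u, v]` with periodic indexing;
#' lag `(0, 0)` is stored at `r[1, 1]`. Both arguments must have identical
#' dimensions. Computed in the frequency domain.
#'
#' @param a,b numeric matrices of identical dimensions
#' @return matrix of correlation values over all lags
#' @export
circular_xcorr <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  r <- fft(fft(a) * Conj(fft(b)), inverse = TRUE) / length(a)
  Re(r)
}

#' Write a binary or signed pattern as a plain-text matrix
#'
#' One row per line, entries separated by single spaces.
#'
#' @param pattern integer/numeric matrix
#' @param path output file path
#' @export
write_pattern_txt <- function(pattern, path) {
  write.table(pattern, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binary pattern as a single-page TIFF image
#'
#' Open cells map to white (1), closed cells to black (0).
#'
#' @param pattern binary 0/1 matrix
#' @param path output file path
#' @export
write_pattern_tiff <- function(pattern, path) {
  check_binary(pattern)
  tiff::writeTIFF(pattern + 0, path, bits.per.sample = 8L)
  invisible(path)
}

check_binary <- function(x) {
  if (!is.matrix(x) || !all(x %in% c(0L, 1L))) {
    stop("pattern must be a binary 0/1 matrix")
  }
  invisible(TRUE)
}
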