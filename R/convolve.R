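# Internal frequency-domain convolution machinery.
#
# All linear convolutions/correlations used by the forward model and MLEM are
# computed on a zero-padded grid of side >= 2N - 1 (next power of two) so that
# no unintended circular wrap-around occurs; the result is cropped back to the
# N x N detector grid with the kernel's reference pixel at cc = N/2 + 1.

pad_size <- function(n) {
  p <- 1L
  while (p < 2L * n - 1L) p <- p * 2L
  p
}

zero_pad <- function(x, p) {
  out <- matrix(0, p, p)
  out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  out
}

# FFT of a zero-padded kernel, for reuse across many filtering calls
kernel_fft <- function(h, p = pad_size(nrow(h))) {
  fft(zero_pad(h, p))
}

# Linear convolution out[i,j] = sum_kl x[k,l] * h[i-k+cc, j-l+cc], cropped to
# the N x N grid (kernel center at cc = N/2 + 1). H is kernel_fft(h).
lin_conv2 <- function(x, H, n = nrow(x)) {
  p <- nrow(H)
  y <- Re(fft(fft(zero_pad(x, p)) * H, inverse = TRUE)) / (p * p)
  cc <- n %/% 2L + 1L
  y[cc:(cc + n - 1L), cc:(cc + n - 1L)]
}

# Linear cross-correlation out[i,j] = sum_uv h[u,v] * x[u+i-cc, v+j-cc],
# cropped to the N x N grid.
lin_corr2 <- function(x, H, n = nrow(x)) {
  p <- nrow(H)
  y <- Re(fft(fft(zero_pad(x, p)) * Conj(H), inverse = TRUE)) / (p * p)
  cc <- n %/% 2L + 1L
  idx <- ((seq_len(n) - cc) %% p) + 1L
  y[idx, idx]
}

# Paired real FFT: one complex transform yields the spectra of two real
# matrices (halves the transform count in the MLEM inner loop).
fft2_pair <- function(a, b) {
  z <- fft(a + (0+1i) * b)
  p <- nrow(a)
  idx <- c(1L, p:2L)             # index of -k (mod p)
  zr <- Conj(z[idx, idx, drop = FALSE])
  list(A = (z + zr) / 2, B = (z - zr) / (0+2i))
}

# Paired inverse FFT: A and B are spectra of real matrices; returns both
# inverse transforms from a single complex inverse FFT.
ifft2_pair <- function(A, B) {
  z <- fft(A + (0+1i) * B, inverse = TRUE) / length(A)
  list(a = Re(z), b = Im(z))
}

# Mean over 8x8 (or f x f) pixel blocks; used by the PSF rasterizer.
block_mean <- function(x, f) {
  n <- nrow(x) %/% f
  stopifnot(nrow(x) == n * f, ncol(x) == n * f)
  a <- array(x, c(f, n, n * f))
  b <- colSums(a) / f            # n x (n*f)
  c2 <- array(t(b), c(f, n, n))
  t(colSums(c2) / f)             # n x n, rows back in place
}

# Separable Gaussian smoothing with reflected boundaries.
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {     # filter along columns
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))  # reflect
    ext <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k)) {
      out <- out + k[s] * ext[(s - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(x))))
}

# Bilinear resize of a square image to side `n_out`, preserving the physical
# extent (pixel-center convention), via pracma::interp2.
bilinear_resize <- function(x, n_out) {
  n_in <- nrow(x)
  if (n_out == n_in) return(x)
  # target pixel centers mapped into source pixel coordinates
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  # out[i, j] interpolates x at (row src[i], col src[j]); pracma::interp2
  # takes Z as length(y) x length(x), so rows are yp. expand.grid varies its
  # first factor fastest, matching column-major fill of the result.
  grid <- expand.grid(yp = src, xp = src)
  v <- pracma::interp2(x = seq_len(n_in), y = seq_len(n_in), Z = x,
                       xp = grid$xp, yp = grid$yp, method = "linear")
  matrix(v, n_out, n_out)
}
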