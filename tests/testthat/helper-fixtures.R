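# Shared fixtures: one default camera and mask bundle per test run, plus a
# small helper to simulate centered point-source images.

default_geometry <- camera_geometry()
default_mask <- mura_mask(31)

simulate_centered <- function(z, intensity = 1e6, noisy = FALSE, seed = 1L,
                              geometry = default_geometry,
                              pattern = default_mask) {
  simulate_detector_image(source_scene(z = z, intensity = intensity),
                          geometry, seed = seed, noisy = noisy,
                          pattern = pattern)
}

# brute-force quadratic residues mod p (independent of the generator)
brute_qr <- function(p) sort(unique((seq_len(p - 1)^2) %% p))

# brute-force circular cross-correlation by explicit looping over all lags
brute_circ_xcorr <- function(a, b) {
  n <- nrow(a)
  m <- ncol(a)
  out <- matrix(0, n, m)
  for (di in 0:(n - 1)) {
    for (dj in 0:(m - 1)) {
      as <- a[((seq_len(n) - 1 + di) %% n) + 1, ((seq_len(m) - 1 + dj) %% m) + 1]
      out[di + 1, dj + 1] <- sum(as * b)
    }
  }
  out
}
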