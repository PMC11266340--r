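test_that("normalization map is the correlation of ones with the PSF", {
  n <- 64
  g <- camera_geometry(detector_pixels = n)
  # impulse PSF at the center -> sensitivity 1 everywhere
  h <- matrix(0, n, n)
  h[n / 2 + 1, n / 2 + 1] <- 1
  nm <- normalization_map(h)
  expect_equal(nm, matrix(1, n, n), tolerance = 1e-10)
  # extended PSF: center = sum(h) when support fits; corners smaller
  h2 <- matrix(0, n, n)
  h2[25:40, 25:40] <- runif(16 * 16)
  nm2 <- normalization_map(h2)
  expect_equal(nm2[n / 2 + 1, n / 2 + 1], sum(h2), tolerance = 1e-8)
  expect_lt(nm2[1, 1], nm2[n / 2 + 1, n / 2 + 1])
  expect_error(normalization_map(matrix(0, n, n)), "all-zero")
})

test_that("single-slice noiseless MLEM converges with monotone likelihood", {
  g <- default_geometry
  n <- g$detector_pixels
  cc <- n / 2 + 1
  h <- rasterize_psf(g, default_mask, 30, "THT")
  hn <- h$pixels / sum(h$pixels)
  f <- matrix(0, n, n)
  f[cc, cc] <- 1e5
  p <- forward_project(f, hn, 0)
  st <- mlem_init(p, g, 30, t = 0, pattern = default_mask,
                  psfs = list("30" = h))
  for (k in 1:40) {
    st <- mlem_iterate(st)
    expect_true(all(st$slices[[1]] >= 0))   # non-negativity every iteration
  }
  ll <- st$loglik
  expect_true(all(diff(ll) >= -abs(ll[-length(ll)]) * 1e-8))
  # mass concentrates onto the impulse
  fr <- st$slices[[1]]
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(cc, cc))
  expect_gt(sum(fr[(cc - 1):(cc + 1), (cc - 1):(cc + 1)]) / sum(fr), 0.95)
})

test_that("MLEM is stationary at an exact fixed point", {
  g <- default_geometry
  h <- rasterize_psf(g, default_mask, 30, "THT")
  hn <- h$pixels / sum(h$pixels)
  set.seed(5)
  n <- g$detector_pixels
  f <- matrix(runif(n * n, 0.5, 2), n, n)
  p <- forward_project(f, hn, 0.46)
  st <- mlem_init(p, g, 30, t = 0.46, pattern = default_mask,
                  psfs = list("30" = h))
  st$slices[[1]] <- f
  st$forwards <- muracam:::slice_forwards(st)
  st2 <- mlem_iterate(st)
  rel <- abs(st2$slices[[1]] - f) / pmax(f, 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("zero iterations return the initialization unchanged", {
  g <- default_geometry
  img <- simulate_centered(30)
  st <- reconstruct_3d(img, g, c(25, 30, 35), iterations = 0,
                       pattern = default_mask)
  expect_equal(length(st$z), 3L)
  # uniform start: every slice is constant
  for (s in st$slices) expect_equal(diff(range(s$pixels)), 0)
})

test_that("3D-MLEM localizes a noiseless source in depth", {
  g <- default_geometry
  img <- simulate_centered(30)
  st <- reconstruct_3d(img, g, seq(15, 45, by = 5), iterations = 40,
                       pattern = default_mask)
  expect_true(all(vapply(st$slices, function(s) all(s$pixels >= 0), logical(1))))
  mx <- vapply(st$slices, function(s) max(s$pixels), numeric(1))
  expect_equal(st$z[which.max(mx)], 30)
  # output keeps the fixed detector size
  expect_true(all(vapply(st$slices, function(s) s$side_px, numeric(1)) == 256))
  # the likelihood improved over the run
  expect_gt(utils::tail(st$diagnostics$loglik, 1), st$diagnostics$loglik[1])
})

test_that("count consistency holds after convergence on noiseless input", {
  # data generated by the reconstruction model itself (THT PSF, shadow fully
  # inside the detector at z = 60), so the forward projection can represent
  # the measurement exactly
  g <- default_geometry
  n <- g$detector_pixels
  h <- rasterize_psf(g, default_mask, 60, "THT")
  hn <- h$pixels / sum(h$pixels)
  cc <- n / 2 + 1
  f <- matrix(0, n, n)
  f[(cc - 2):(cc + 2), (cc - 2):(cc + 2)] <- 2e4
  p <- forward_project(f, hn, 0.46)
  st0 <- mlem_init(p, g, 60, pattern = default_mask, psfs = list("60" = h))
  # the total transiently overshoots by a few percent (the backprojection has
  # no transmission adjoint) and decays back as the iteration converges
  for (k in 1:200) st0 <- mlem_iterate(st0)
  tot_fw <- sum(Reduce(`+`, st0$forwards))
  expect_equal(tot_fw, sum(p), tolerance = 0.01)
})

test_that("MLEM background is far more uniform than MURA decoding's", {
  g <- default_geometry
  img <- simulate_centered(50, noisy = TRUE, seed = 9)
  # MURA reconstruction at the true plane, normalized to [0, 1]
  rm_ <- mura_decode(img, g, 50, default_mask)
  st <- reconstruct_3d(img, g, seq(45, 55, by = 5), iterations = 40,
                       pattern = default_mask)
  ml <- st$slices[[which.min(abs(st$z - 50))]]
  sig_b <- function(px, d) {
    tab <- sample_rois(muracam:::norm01(px), d)
    sig <- suppressWarnings(select_signal_roi(tab))
    mean(tab$sd[sig$background])
  }
  s_mura <- sig_b(rm_$pixels, roi_diameter(g, 50, "mura", rm_$side_px))
  s_mlem <- sig_b(ml$pixels, roi_diameter(g, 50, "pinhole", 256))
  # qualitative ordering: MLEM background noise at least an order of
  # magnitude below MURA decoding's on the same normalized task (the gap is
  # far larger on long-exposure measured data)
  expect_gt(s_mura / s_mlem, 10)
})

test_that("the un-extended normalization mislocalizes the source in depth", {
  g <- default_geometry
  img <- simulate_centered(30)
  zg <- seq(20, 45, by = 5)
  ext <- reconstruct_3d(img, g, zg, iterations = 15, pattern = default_mask,
                        normalization = "extended")
  ori <- reconstruct_3d(img, g, zg, iterations = 15, pattern = default_mask,
                        normalization = "original")
  peak_z <- function(st) st$z[which.max(vapply(st$slices, function(s)
    max(s$pixels), numeric(1)))]
  expect_equal(peak_z(ext), 30)
  # without the sensitivity map the stack maximum lands on a wrong plane
  expect_gt(abs(peak_z(ori) - 30), 4.9)
})
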