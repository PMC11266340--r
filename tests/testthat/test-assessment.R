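test_that("preprocessing replaces outliers and passes constants through", {
  # constant image: degenerate percentile band, smoothing of constant is identity
  const <- matrix(7, 64, 64)
  out <- preprocess_detector(const)
  expect_equal(out$pixels, const, tolerance = 1e-12)
  expect_true(out$meta$preprocessed)
  # one hot pixel in a flat-ish background is removed before smoothing
  set.seed(2)
  x <- matrix(100 + rnorm(64 * 64), 64, 64)
  x[30, 30] <- 1e6
  y <- preprocess_detector(x)$pixels
  expect_lt(max(y), 200)
  # outlier rule touches at most ~2 % of pixels by the percentile counting
  # argument, checked on random images
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(rpois(64 * 64, 50), 64, 64)
    q <- quantile(r, c(0.01, 0.99), names = FALSE)
    expect_lte(mean(r < q[1] | r > q[2]), 0.02 + 1e-9)
  }
})

test_that("ROI diameter conversion follows the FOV arithmetic", {
  g <- default_geometry
  # pinhole at z = 30 with 256 px: FOV = 21.12 mm, px = 0.0825 -> round(7.88) = 8
  expect_equal(roi_diameter(g, 30, "pinhole", 256), 8L)
  # source FWHM equal to one pixel footprint -> 1 px
  expect_equal(roi_diameter(g, 30, "pinhole", 256,
                            source_fwhm_mm = 21.12 / 256), 1L)
  expect_warning(d0 <- roi_diameter(g, 30, "pinhole", 256,
                                    source_fwhm_mm = 1e-4), "clamp")
  expect_equal(d0, 1L)
  expect_error(roi_diameter(g, -1), "> 0")
})

test_that("dense ROI sampling enumerates (side - d + 1)^2 placements", {
  set.seed(4)
  img <- matrix(runif(30 * 30), 30, 30)
  tab <- sample_rois(img, 8)
  expect_equal(nrow(tab), (30 - 8 + 1)^2)
  tab1 <- sample_rois(img, 30)
  expect_equal(nrow(tab1), 1L)
  # brute-force oracle for the mean/sd of a few random placements
  off <- muracam:::disc_offsets(8)
  for (k in c(1, 57, 300)) {
    r0 <- ((k - 1) %% 23) + 1
    c0 <- ((k - 1) %/% 23) + 1
    vals <- img[cbind(r0 + off$i - 1, c0 + off$j - 1)]
    expect_equal(tab$mean[k], mean(vals), tolerance = 1e-12)
    expect_equal(tab$sd[k], sd(vals), tolerance = 1e-10)
  }
  # the two operating geometries: decoded 150 px slice with 13 px ROI, and
  # the full 256 px detector with 8 px ROI
  expect_equal((150 - 13 + 1)^2, 19044)
  expect_true((150 - 13 + 1)^2 > 14000 && (150 - 13 + 1)^2 < 31000)
  expect_equal((256 - 8 + 1)^2, 62001)
  expect_true((256 - 8 + 1)^2 > 54000 && (256 - 8 + 1)^2 < 65000)
})

test_that("signal ROI selection prefers the central region and breaks ties", {
  img <- matrix(0, 50, 50)
  img[25:27, 25:27] <- 10          # central source
  img[2:4, 2:4] <- 50              # brighter ghost near the border
  tab <- sample_rois(img, 5)
  # the 3x3 plateau makes several fully-covering ROIs tie exactly
  expect_warning(sig <- select_signal_roi(tab), "tie")
  expect_lt(abs(sig$row - 26) + abs(sig$col - 26), 4)
  # two exactly equal maxima tie-break deterministically with a warning
  img2 <- matrix(0, 40, 40)
  img2[15, 15] <- 1
  img2[15, 25] <- 1
  tab2 <- sample_rois(img2, 3)
  expect_warning(sig2 <- select_signal_roi(tab2), "tie")
  # deterministic: lowest row, then lowest column, among the tied ROIs that
  # contain either hot pixel
  expect_equal(c(sig2$row, sig2$col), c(14, 14))
  expect_warning(sig2b <- select_signal_roi(tab2), "tie")
  expect_identical(sig2[c("row", "col")], sig2b[c("row", "col")])
  # empty candidate set errors
  tab3 <- sample_rois(matrix(0, 10, 10), 3)
  expect_s3_class(tab3, "roi_table")
})

test_that("CNR arithmetic matches its definition", {
  expect_equal(cnr(10, c(4, 4), c(2, 2)), 3)
  expect_equal(cnr(5, 5, 2), 0)
  expect_error(cnr(1, c(2, 2), c(0, 0)), "degenerate")
  expect_error(cnr(1, numeric(0), numeric(0)), "background")
})

test_that("CNR is invariant under affine intensity rescaling of the slice", {
  set.seed(6)
  img <- matrix(rnorm(80 * 80, 10, 1), 80, 80)
  img[40:43, 40:43] <- 30
  d <- 5
  cnr_of <- function(x) {
    tab <- sample_rois(x, d)
    sig <- select_signal_roi(tab)
    cnr(tab$mean[sig$index], tab$mean[sig$background], tab$sd[sig$background])
  }
  expect_equal(cnr_of(img), cnr_of(3.7 * img + 42), tolerance = 1e-9)
})

test_that("offset-Gaussian fit recovers exact and noisy profiles", {
  z <- seq(10, 50, by = 0.5)
  truth <- c(alpha = 1, beta = 10, gamma = 30, delta = 2)
  y <- truth["alpha"] + (truth["beta"] - truth["alpha"]) *
    exp(-(z - truth["gamma"])^2 / (2 * truth["delta"]^2))
  fit <- fit_cnr_profile(z, y)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  expect_equal(fit$fwhm_mm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-6)
  expect_equal(round(fit$fwhm_mm, 2), 4.71)
  # delta = 1 -> FWHM ~ 2.35
  expect_equal(round(fwhm_factor(), 2), 2.35)
  # Monte-Carlo: 5 % noise on 60 points recovers gamma within half a step
  z60 <- seq(15, 45, length.out = 60)
  mu <- 2 + 8 * exp(-(z60 - 30)^2 / (2 * 2.5^2))
  set.seed(8)
  errs <- replicate(100, {
    fitn <- fit_cnr_profile(z60, mu + rnorm(60, 0, 0.05 * max(mu)))
    coef(fitn)[["gamma"]] - 30
  })
  expect_lt(max(abs(errs)), 0.5)
  # model-consistency of the methods
  expect_equal(predict(fit, 30), truth[["beta"]], tolerance = 1e-6)
  expect_equal(length(residuals(fit)), length(z))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_error(fit_cnr_profile(1:3, c(1, 2, 1)), "at least 5")
})

test_that("lateral FWHM of a synthetic Gaussian blob matches the closed form", {
  side <- 121
  sig_px <- 4
  x <- seq_len(side)
  blob <- outer(exp(-(x - 61)^2 / (2 * sig_px^2)),
                exp(-(x - 61)^2 / (2 * sig_px^2))) + 0.05
  fov_mm <- 21.12
  lat <- assess_lateral(blob, fov_mm)
  expected <- 2 * sqrt(2 * log(2)) * sig_px * fov_mm / side
  expect_equal(as.numeric(lat), expected, tolerance = 0.02)
  suppressWarnings(
    expect_error(assess_lateral(matrix(1, 50, 50), 10),
                 "flat|converge|fitted"))
})

test_that("stack CNR profile freezes the signal ROI across slices", {
  g <- default_geometry
  img <- simulate_centered(30, noisy = TRUE, seed = 3)
  st <- decode_stack(img, g, seq(26, 34, by = 1), reference_z = 30,
                     pattern = default_mask)
  d <- roi_diameter(g, 30, "mura", st$slices[[1]]$side_px)
  prof <- stack_cnr_profile(st, d, 30)
  expect_equal(length(prof$cnr), length(st$z))
  expect_true(all(is.finite(prof$cnr)))
  # the in-focus slice carries the largest CNR
  expect_equal(st$z[which.max(prof$cnr)], 30, tolerance = 1)
})

test_that("the pooled background-noise estimator gives a comparable profile", {
  g <- default_geometry
  img <- simulate_centered(30, noisy = TRUE, seed = 3)
  st <- decode_stack(img, g, seq(27, 33, by = 1), reference_z = 30,
                     pattern = default_mask)
  d <- roi_diameter(g, 30, "mura", st$slices[[1]]$side_px)
  p1 <- stack_cnr_profile(st, d, 30)
  p2 <- stack_cnr_profile(st, d, 30, sigma_b = "pooled")
  expect_true(all(is.finite(p2$cnr)))
  expect_equal(which.max(p1$cnr), which.max(p2$cnr))
})
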