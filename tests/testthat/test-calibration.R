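# Unit calibration: background subtraction, peak detection, PSF fitting,
# and derivation of the unit from trimmed fit distributions.

test_that("background subtraction removes a constant offset", {
  const <- fluor_image(matrix(10, 32, 32))
  out <- subtract_background(const)
  expect_true(all(out$pixels == 0))
  expect_equal(out$background, 10)

  zero <- fluor_image(matrix(0, 32, 32))
  expect_true(all(subtract_background(zero)$pixels == 0))

  expect_error(subtract_background(const, matrix(TRUE, 32, 32)),
               "entire image")
})

test_that("background subtraction leaves spot-free pixels at zero", {
  r <- sparse_scene(n_spots = 10L, seed = 3)
  out <- scene_signal(r)
  # pixels far from every spot must be exactly zero
  far <- matrix(TRUE, nrow(out$pixels), ncol(out$pixels))
  for (i in seq_len(nrow(r$scene$spot_positions))) {
    pos <- r$scene$spot_positions[i, ]
    rr <- pmax(1, round(pos[1]) - 9):pmin(nrow(far), round(pos[1]) + 9)
    cc <- pmax(1, round(pos[2]) - 9):pmin(ncol(far), round(pos[2]) + 9)
    far[rr, cc] <- FALSE
  }
  expect_true(all(out$pixels[far] < 1e-6))
})

test_that("detect_peaks finds isolated spots and nothing on a flat image", {
  flat <- fluor_image(matrix(0, 64, 64))
  expect_identical(nrow(detect_peaks(flat)), 0L)
  expect_error(detect_peaks(flat, min_separation_px = 0), "positive")

  one <- row_of_units(1, 0)
  pk <- detect_peaks(one$image)
  expect_identical(nrow(pk), 1L)
  expect_lt(sqrt(sum((c(pk$row, pk$col) - one$positions[1, ])^2)), 0.5)

  two <- row_of_units(2, spacing = 15)     # 10 sigma apart
  expect_identical(nrow(detect_peaks(two$image)), 2L)
})

test_that("detection on sparse scenes is complete with no false positives", {
  for (seed in 1:3) {
    r <- sparse_scene(n_spots = 20L, seed = seed)
    pk <- detect_peaks(scene_signal(r))
    truth <- r$scene$spot_positions
    d <- sqrt(outer(pk$row, truth[, 1], "-")^2 +
              outer(pk$col, truth[, 2], "-")^2)
    matched <- apply(d, 2, min) <= 1
    expect_gte(mean(matched), 0.95)
    expect_true(all(apply(d, 1, min) <= 1))  # zero false positives
  }
})

test_that("fit_psf is exact on a noise-free Gaussian window", {
  one <- row_of_units(1, 0, amp = 100, sigma = 1.5)
  pk <- detect_peaks(one$image)
  fit <- fit_psf(one$image, pk[1, ])
  expect_true(fit$accepted)
  expect_equal(fit$fit_amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$fit_sigma, 1.5, tolerance = 1e-6)
  expect_equal(fit$fit_background, 0, tolerance = 1e-6)
  expect_lt(fit$fit_rss, 1e-10)
})

test_that("fit_psf flags flat windows and rejects off-image windows", {
  flat <- fluor_image(matrix(0, 32, 32))
  cand <- data.frame(row = 16, col = 16, peak_value = 0,
                     fit_amplitude = NA, fit_sigma = NA,
                     fit_background = NA, fit_rss = NA, accepted = FALSE)
  expect_false(fit_psf(flat, cand)$accepted)
  cand$row <- 2
  expect_error(fit_psf(flat, cand), "beyond the image")
})

test_that("fit_psf recovers the amplitude within 5% under read noise", {
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    img <- matrix(0, 21, 21)
    img <- fishpol:::add_gaussian(img, 11, 11, 100, 1.5)
    img <- pmax(img + matrix(rnorm(21 * 21, sd = 1), 21, 21), 0)
    cand <- data.frame(row = 11, col = 11, peak_value = img[11, 11],
                       fit_amplitude = NA, fit_sigma = NA,
                       fit_background = NA, fit_rss = NA, accepted = FALSE)
    fit <- fit_psf(fluor_image(img), cand)
    abs(fit$fit_amplitude - 100) / 100
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("derive_unit returns the degenerate distribution unchanged", {
  cand <- data.frame(row = 1, col = 1, peak_value = 100,
                     fit_amplitude = rep(100, 100),
                     fit_sigma = rep(1.5, 100),
                     fit_background = 0, fit_rss = 0, accepted = TRUE)
  u <- derive_unit(cand)
  expect_equal(u$amplitude, 100)
  expect_equal(u$sigma, 1.5)
  expect_equal(u$integrated_intensity, 2 * pi * 100 * 2.25)
  expect_identical(u$n_support, 100L)
  expect_identical(u$trim_fraction_applied, 0)
})

test_that("derive_unit trims the upper mode of a contaminated distribution", {
  set.seed(1)
  cand <- data.frame(row = 1, col = 1, peak_value = 1,
                     fit_amplitude = c(rnorm(90, 100, 5), rnorm(10, 300, 5)),
                     fit_sigma = rnorm(100, 1.5, 0.05),
                     fit_background = 0, fit_rss = 0, accepted = TRUE)
  u <- derive_unit(cand)
  expect_equal(u$amplitude, 100, tolerance = 0.05)
  expect_gt(u$trim_fraction_applied, 0.05)
})

test_that("derive_unit is idempotent on its surviving candidate set", {
  set.seed(2)
  cand <- data.frame(row = 1, col = 1, peak_value = 1,
                     fit_amplitude = c(rnorm(90, 100, 5), rnorm(10, 300, 5)),
                     fit_sigma = rnorm(100, 1.5, 0.05),
                     fit_background = 0, fit_rss = 0, accepted = TRUE)
  u1 <- derive_unit(cand)
  # rebuild the surviving set: the n_support smallest amplitudes
  keep <- order(cand$fit_amplitude)[seq_len(u1$n_support)]
  u2 <- derive_unit(cand[keep, ])
  expect_equal(u2$amplitude, u1$amplitude, tolerance = 1e-12)
  expect_equal(u2$sigma, u1$sigma, tolerance = 1e-12)
})

test_that("derive_unit fails loudly without enough support", {
  expect_error(derive_unit(fishpol:::empty_candidates()),
               "insufficient isolated spots")
  few <- data.frame(row = 1, col = 1, peak_value = 1,
                    fit_amplitude = rep(100, 5), fit_sigma = rep(1.5, 5),
                    fit_background = 0, fit_rss = 0, accepted = TRUE)
  expect_error(derive_unit(few), "insufficient isolated spots")
})

test_that("calibration on a synthetic scene recovers the generator unit", {
  r <- sparse_scene(n_spots = 40L, seed = 3)
  u <- calibrate_unit(r$mrna, r$scene$cell_mask)
  truth <- 2 * pi * r$scene$params$unit_amplitude *
    r$scene$params$unit_sigma^2
  expect_equal(u$integrated_intensity, truth, tolerance = 0.05)
  expect_gte(u$n_support, 10)
})
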