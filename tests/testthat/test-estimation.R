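# Count estimation: linear estimator, greedy stochastic reconstruction,
# simulated estimate, average image.

test_that("linear estimate is self-consistent for rendered units", {
  one <- row_of_units(1, 0)
  whole <- matrix(TRUE, 64, 64)
  expect_equal(linear_estimate(one$image, whole, one$unit), 1,
               tolerance = 0.02)

  seven <- row_of_units(7, spacing = 8)
  expect_equal(linear_estimate(seven$image, whole, seven$unit), 7,
               tolerance = 0.1 / 7)

  # background-only region
  corner <- matrix(FALSE, 64, 64); corner[1:8, 1:8] <- TRUE
  expect_equal(linear_estimate(seven$image, corner, seven$unit), 0,
               tolerance = 1e-6)

  bad_unit <- list(integrated_intensity = 0)
  expect_error(linear_estimate(one$image, whole, bad_unit), "positive")
  expect_error(linear_estimate(one$image, matrix(FALSE, 64, 64), one$unit),
               "no pixels")
})

test_that("linear estimates are additive over an exact-cover partition", {
  r <- sparse_scene(n_spots = 15L, seed = 5)
  img <- scene_signal(r)
  unit <- scene_unit(r$scene)
  rois <- scene_roi_pair(r$scene)
  shape <- dim(img$pixels)
  m <- roi_pair_masks(rois, shape,
                      cell_mask = matrix(TRUE, shape[1], shape[2]))
  whole <- linear_estimate(img, matrix(TRUE, shape[1], shape[2]), unit)
  parts <- linear_estimate(img, m$anterior, unit) +
    linear_estimate(img, m$posterior, unit)
  expect_equal(parts, whole, tolerance = 1e-6)
  # conservation: whole-cell count equals the true spot count
  expect_equal(whole, 15, tolerance = 0.03)
})

test_that("reconstruction of a single unit converges in one step", {
  one <- row_of_units(1, 0)
  tr <- reconstruct(one$image, one$unit, seed = 1)
  expect_identical(tr$final_count, 1L)
  expect_lt(sqrt(sum((tr$placements[1, ] - one$positions[1, ])^2)), 1)
  expect_true(tr$converged)
})

test_that("reconstruction of a flat image places nothing", {
  flat <- fluor_image(matrix(0, 64, 64))
  tr <- reconstruct(flat, unit_model(100, 1.5), seed = 1)
  expect_identical(tr$final_count, 0L)
})

test_that("reconstruction is deterministic at zero jitter", {
  five <- row_of_units(5, spacing = 6)
  t1 <- reconstruct(five$image, five$unit, seed = 1, jitter_px = 0)
  t2 <- reconstruct(five$image, five$unit, seed = 99, jitter_px = 0)
  expect_identical(t1$placements, t2$placements)
  expect_identical(t1$final_count, 5L)
})

test_that("overlapping spots are counted within one unit (median over seeds)", {
  dense <- row_of_units(10, spacing = 3, sigma = 1.5)  # centres 2 sigma apart
  counts <- vapply(1:25, function(s)
    reconstruct(dense$image, dense$unit, seed = s)$final_count, 0L)
  expect_lte(abs(median(counts) - 10), 1)
})

test_that("every accepted placement strictly decreases the SSD", {
  for (seed in 1:5) {
    r <- render_scene(cohort_params(seed = seed, n_spots = 30L))
    tr <- reconstruct(scene_signal(r), scene_unit(r$scene), seed = seed)
    ssd <- c(tr$ssd_initial, tr$ssd_after_each)
    expect_true(all(diff(ssd) < 0))
    expect_identical(tr$final_count, length(tr$ssd_after_each))
  }
})

test_that("reconstruction rejects a mask narrower than the unit", {
  img <- fluor_image(matrix(1, 32, 32))
  tiny <- matrix(FALSE, 32, 32); tiny[16, 16] <- TRUE
  expect_error(reconstruct(img, unit_model(100, 3), mask = tiny),
               "wider than the reconstruction mask")
})

test_that("simulated estimate agrees with the linear estimate when sparse", {
  r <- sparse_scene(n_spots = 20L, seed = 7)
  img <- scene_signal(r)
  unit <- scene_unit(r$scene)
  est <- simulated_estimate(img, matrix(TRUE, nrow(img$pixels),
                                        ncol(img$pixels)),
                            unit, n_reps = 5, master_seed = 2)
  expect_lte(abs(est$sim_count_mean - est$linear_count),
             max(1, 0.05 * est$linear_count))
  # single repetition has zero spread by definition
  est1 <- simulated_estimate(img, matrix(TRUE, nrow(img$pixels),
                                         ncol(img$pixels)),
                             unit, n_reps = 1, master_seed = 3)
  expect_identical(est1$sim_count_sd, 0)
  expect_error(simulated_estimate(img, matrix(TRUE, 2, 2), unit, n_reps = 0),
               "n_reps")
})

test_that("per-ROI simulated counts recover an asymmetric ground truth", {
  p <- scene_params(image_shape = c(96L, 96L), cell_axes = c(30, 15),
                    n_spots = 40L, enrichment = 0.75, seed = 13,
                    background = 10)
  r <- render_scene(p)
  img <- scene_signal(r)
  est <- simulated_estimate(img, scene_roi_pair(r$scene),
                            scene_unit(r$scene), n_reps = 10,
                            master_seed = 4)
  truth <- c(anterior = r$scene$true_anterior_count,
             posterior = r$scene$true_posterior_count)
  for (roi in c("anterior", "posterior"))
    expect_lte(abs(est$sim_count_mean[est$roi_id == roi] - truth[roi]), 2)
})

test_that("average image conserves the reconstructed unit content", {
  one <- row_of_units(1, 0)
  tr <- reconstruct(one$image, one$unit, seed = 1)
  avg1 <- average_image(list(tr), c(64L, 64L), one$unit)
  direct <- fishpol:::add_gaussian(matrix(0, 64, 64),
                                   tr$placements[1, 1], tr$placements[1, 2],
                                   one$unit$amplitude, one$unit$sigma)
  expect_equal(avg1$pixels, direct, tolerance = 1e-12)

  # identical traces average to any single rendering
  avg3 <- average_image(list(tr, tr, tr), c(64L, 64L), one$unit)
  expect_equal(avg3$pixels, avg1$pixels, tolerance = 1e-12)

  dense <- row_of_units(10, spacing = 3)
  traces <- lapply(1:25, function(s)
    reconstruct(dense$image, dense$unit, seed = s))
  avg <- average_image(traces, c(64L, 64L), dense$unit)
  n_avg <- sum(avg$pixels) / dense$unit$integrated_intensity
  expect_lte(abs(n_avg - 10), 1)

  bad <- reconstruct(fluor_image(matrix(0, 32, 32)), dense$unit, seed = 1)
  expect_error(average_image(list(tr, bad), c(64L, 64L), dense$unit),
               "shape mismatch")
})
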