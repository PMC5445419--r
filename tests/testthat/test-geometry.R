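# Cell geometry: equivalent-ellipse axes, eccentricity, nucleus-centred
# bisection, posterior intensity fractions.

test_that("fit_cell_axes recovers ellipse semi-axes from area moments", {
  poly <- ellipse_polygon(c(60, 60), a = 20, b = 10, angle = 0.7, n = 256L)
  ax <- fit_cell_axes(poly)
  expect_equal(ax$a, 20, tolerance = 0.01)
  expect_equal(ax$b, 10, tolerance = 0.01)
  # orientation recovered modulo pi
  expect_equal(abs(cos(ax$orientation - 0.7)), 1, tolerance = 1e-3)

  circ <- ellipse_polygon(c(30, 30), 10, 10, n = 256L)
  axc <- fit_cell_axes(circ)
  expect_equal(axc$a / axc$b, 1, tolerance = 0.005)

  square <- cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))
  axs <- fit_cell_axes(square)
  expect_equal(axs$a, axs$b, tolerance = 1e-9)

  expect_error(fit_cell_axes(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("eccentricity matches the closed form and is monotone in b/a", {
  expect_identical(eccentricity(10, 10), 0)
  expect_identical(eccentricity(10, 0), 1)
  expect_equal(eccentricity(2, 1), sqrt(3) / 2)
  expect_error(eccentricity(1, 2), "a >= b")
  expect_error(eccentricity(0, 0), "positive")
  ratios <- seq(0.05, 1, by = 0.05)
  eps <- eccentricity(rep(1, length(ratios)), ratios)
  expect_true(all(diff(eps) < 0))
  expect_true(all(eps >= 0 & eps <= 1))
})

test_that("bisection splits a symmetric ellipse into equal halves", {
  poly <- ellipse_polygon(c(50, 50), 20, 10, n = 256L)
  rois <- bisect_cell(poly, c(50, 50), c(50, 110))
  a_ant <- polygon_area(rois$anterior)
  a_post <- polygon_area(rois$posterior)
  expect_equal(a_ant, a_post, tolerance = 1e-6)
  expect_equal(a_ant + a_post, polygon_area(poly), tolerance = 1e-9)
})

test_that("flipping the aggregation point swaps labels, not polygons", {
  poly <- ellipse_polygon(c(50, 50), 20, 10, n = 128L)
  r1 <- bisect_cell(poly, c(50, 52), c(50, 110))
  r2 <- bisect_cell(poly, c(50, 52), c(50, -10))
  expect_equal(r1$anterior, r2$posterior, tolerance = 1e-12)
  expect_equal(r1$posterior, r2$anterior, tolerance = 1e-12)
})

test_that("a nucleus offset toward the aggregate shrinks the anterior half", {
  poly <- ellipse_polygon(c(50, 50), 20, 10, n = 256L)
  rois <- bisect_cell(poly, c(50, 52), c(50, 110))
  expect_lt(polygon_area(rois$anterior), polygon_area(rois$posterior))
  expect_equal(polygon_area(rois$anterior) + polygon_area(rois$posterior),
               polygon_area(poly), tolerance = 1e-9)
})

test_that("bisection rejects degenerate anchors", {
  poly <- ellipse_polygon(c(50, 50), 20, 10, n = 64L)
  expect_error(bisect_cell(poly, c(50, 90), c(50, 110)),
               "inside the cell polygon")
  expect_error(bisect_cell(poly, c(50, 50), c(50, 50)), "coincides")
})

test_that("ROI-pair masks partition the cell mask exactly", {
  poly <- ellipse_polygon(c(40, 40), 22, 12, angle = 0.4, n = 128L)
  rois <- bisect_cell(poly, c(40, 40), c(40 + 22 * sin(0.4), 40 + 22 * cos(0.4)))
  cellmask <- polygon_mask(poly, c(80L, 80L))
  m <- roi_pair_masks(rois, c(80L, 80L), cell_mask = cellmask)
  expect_false(any(m$anterior & m$posterior))
  expect_identical(m$anterior | m$posterior, cellmask)
})

test_that("posterior intensity fraction behaves on uniform and one-sided signal", {
  # centre between pixel centres so the cut line carries no pixel ties
  poly <- ellipse_polygon(c(32.5, 32.5), 20, 10, n = 256L)
  rois <- bisect_cell(poly, c(32.5, 32.5), c(32.5, 60))
  cellmask <- polygon_mask(poly, c(64L, 64L))
  m <- roi_pair_masks(rois, c(64L, 64L), cell_mask = cellmask)

  unif <- matrix(0, 64, 64); unif[cellmask] <- 7
  f <- posterior_intensity_fraction(fluor_image(unif), m)
  expect_equal(f, sum(m$posterior) / sum(cellmask), tolerance = 1e-12)
  expect_equal(f, 0.5, tolerance = 1e-6)

  onesided <- matrix(0, 64, 64); onesided[m$posterior] <- 3
  expect_identical(posterior_intensity_fraction(fluor_image(onesided), m), 1)

  expect_warning(
    f0 <- posterior_intensity_fraction(fluor_image(matrix(0, 64, 64)), m),
    "zero")
  expect_identical(f0, 0.5)
})

test_that("the protein channel fraction matches the generator setting", {
  p <- scene_params(protein_posterior_fraction = 0.7, n_spots = 0L, seed = 2)
  r <- render_scene(p)
  protein <- subtract_background(r$protein, r$scene$cell_mask)
  rois <- scene_roi_pair(r$scene)
  m <- roi_pair_masks(rois, dim(protein$pixels),
                      cell_mask = r$scene$cell_mask)
  expect_equal(posterior_intensity_fraction(protein, m), 0.7,
               tolerance = 0.01)
})

test_that("manually supplied anterior/posterior polygons take precedence", {
  poly <- ellipse_polygon(c(50, 50), 20, 10, n = 64L)
  auto <- bisect_cell(poly, c(50, 50), c(50, 110))
  cell <- list(cell_id = "c1", cell = poly, nucleus = c(50, 50),
               aggregation_center = c(50, 110),
               anterior = auto$anterior, posterior = auto$posterior)
  manual <- cell_roi_pair(cell)
  expect_identical(manual$anterior, cell$anterior)
  expect_identical(manual$posterior, cell$posterior)
  # without the halves it falls back to programmatic bisection
  cell$anterior <- NULL; cell$posterior <- NULL
  expect_equal(cell_roi_pair(cell)$anterior, auto$anterior,
               tolerance = 1e-12)
})
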