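# Shared fixtures: all synthetic, built in code at test time.

# A quiet noise-free scene with well-separated spots (>= `sep_sigma` PSF
# widths apart), suitable for photometric oracles.
sparse_scene <- function(n_spots = 25L, seed = 1L, sep_sigma = 6,
                         sigma = 1.5, shape = c(160L, 160L),
                         axes = c(55, 30)) {
  render_scene(scene_params(
    image_shape = shape, cell_axes = axes, n_spots = n_spots,
    unit_sigma = sigma, min_spot_separation = sep_sigma * sigma,
    background = 10, seed = seed))
}

# Ground-truth unit of a scene's generator.
scene_unit <- function(scene) {
  unit_model(scene$params$unit_amplitude, scene$params$unit_sigma)
}

# Background-subtracted mRNA channel of a rendered scene.
scene_signal <- function(rendered) {
  subtract_background(rendered$mrna, rendered$scene$cell_mask)
}

# Small-image parameters for cohort-level statistics (kept small so
# replicated cohorts stay fast).
cohort_params <- function(seed, n_spots = 40L, ...) {
  scene_params(image_shape = c(64L, 64L), cell_axes = c(20, 10),
               n_spots = n_spots, unit_sigma = 1.2, background = 5,
               seed = seed, ...)
}

# An image containing `n` unit PSFs placed in a row `spacing` px apart.
row_of_units <- function(n, spacing, amp = 100, sigma = 1.5,
                         shape = c(64L, 64L)) {
  img <- matrix(0, shape[1L], shape[2L])
  start <- (shape[2L] - (n - 1) * spacing) / 2
  pos <- cbind(rep(shape[1L] / 2, n), start + spacing * (seq_len(n) - 1))
  for (i in seq_len(n))
    img <- fishpol:::add_gaussian(img, pos[i, 1L], pos[i, 2L], amp, sigma)
  list(image = fluor_image(img), positions = pos,
       unit = unit_model(amp, sigma))
}
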