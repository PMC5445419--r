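# Synthetic FISH scene generator.
#
# Renders FISH-like images with known ground truth: diffraction-limited
# spots as 2D isotropic Gaussians of a common PSF over a low constant
# background, placed inside an elliptical cell with a tunable posterior
# enrichment, plus a matching "protein" channel whose within-cell intensity
# is split between the two halves at a tunable posterior fraction.

#' Parameters of a synthetic FISH scene
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param cell_axes `c(a, b)` semi-major and semi-minor axes in pixels,
#'   `a >= b > 0`.
#' @param cell_center `(row, col)` centre of the cell ellipse; defaults to
#'   the image centre.
#' @param polarity_axis_angle orientation of the anterior direction in
#'   radians (0 = along increasing column).
#' @param nucleus_offset displacement of the nucleus centroid from the cell
#'   centre, in pixels along the polarity axis (positive = toward the
#'   anterior).
#' @param n_spots number of mRNA spots, `>= 0`.
#' @param enrichment posterior spot fraction `f` in `[0, 1]`; `0.5` means
#'   spatially uniform placement.
#' @param unit_amplitude peak intensity of one unit PSF.
#' @param unit_sigma Gaussian PSF width in pixels, `> 0`.
#' @param background constant background intensity, `>= 0`.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param poisson_noise logical; apply Poisson noise to background + signal.
#' @param protein_posterior_fraction fraction of total protein-channel
#'   intensity in the posterior half, in `[0, 1]`.
#' @param protein_mean_intensity mean within-cell protein intensity above
#'   background.
#' @param border_margin_sigma spots are rejected and resampled if closer
#'   than this many PSF sigmas to the image border (keeps photometric
#'   invariants exact); set to 0 to disable.
#' @param min_spot_separation minimum pairwise distance between spot centres
#'   in pixels (0 = no constraint); useful for generating sparse scenes.
#' @param seed integer seed; the scene is fully reproducible from it.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(128L, 128L),
                         cell_axes = c(40, 20),
                         cell_center = NULL,
                         polarity_axis_angle = 0,
                         nucleus_offset = 0,
                         n_spots = 50L,
                         enrichment = 0.5,
                         unit_amplitude = 100,
                         unit_sigma = 1.5,
                         background = 10,
                         read_noise_sd = 0,
                         poisson_noise = FALSE,
                         protein_posterior_fraction = 0.5,
                         protein_mean_intensity = 50,
                         border_margin_sigma = 3,
                         min_spot_separation = 0,
                         seed = 1L) {
  if (is.null(cell_center))
    cell_center <- (image_shape + 1) / 2
  p <- list(image_shape = as.integer(image_shape), cell_axes = cell_axes,
            cell_center = cell_center,
            polarity_axis_angle = polarity_axis_angle,
            nucleus_offset = nucleus_offset, n_spots = as.integer(n_spots),
            enrichment = enrichment, unit_amplitude = unit_amplitude,
            unit_sigma = unit_sigma, background = background,
            read_noise_sd = read_noise_sd,
            poisson_noise = isTRUE(poisson_noise),
            protein_posterior_fraction = protein_posterior_fraction,
            protein_mean_intensity = protein_mean_intensity,
            border_margin_sigma = border_margin_sigma,
            min_spot_separation = min_spot_separation,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  a <- p$cell_axes[1L]; b <- p$cell_axes[2L]
  if (!(a >= b && b > 0)) stop("cell_axes must satisfy a >= b > 0")
  if (p$n_spots < 0L) stop("n_spots must be >= 0")
  if (p$enrichment < 0 || p$enrichment > 1)
    stop("enrichment must be in [0, 1]")
  if (p$protein_posterior_fraction < 0 || p$protein_posterior_fraction > 1)
    stop("protein_posterior_fraction must be in [0, 1]")
  if (p$unit_sigma <= 0) stop("unit_sigma must be > 0")
  if (p$background < 0 || p$read_noise_sd < 0)
    stop("background and read_noise_sd must be >= 0")
  u <- axis_direction(p$polarity_axis_angle)
  v <- c(-u[2L], u[1L])
  ext <- c(sqrt((a * u[1L])^2 + (b * v[1L])^2),
           sqrt((a * u[2L])^2 + (b * v[2L])^2))
  lo <- p$cell_center - ext
  hi <- p$cell_center + ext
  if (any(lo < 0.5) || any(hi > p$image_shape + 0.5))
    stop("cell ellipse exceeds the image bounds")
  invisible(p)
}

# Logical mask of pixels whose centres lie inside the cell ellipse.
ellipse_mask <- function(shape, center, a, b, angle) {
  rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dr <- rows - center[1L]; dc <- cols - center[2L]
  u <- axis_direction(angle)
  xa <- dr * u[1L] + dc * u[2L]           # along major axis
  xb <- -dr * u[2L] + dc * u[1L]          # along minor axis
  (xa / a)^2 + (xb / b)^2 <= 1
}

# Add an isotropic Gaussian of amplitude `amp`, width `sigma` at subpixel
# position (r0, c0) to matrix `img` (evaluated at pixel centres, over a
# +-5 sigma window). Returns the updated matrix.
add_gaussian <- function(img, r0, c0, amp, sigma) {
  w <- ceiling(5 * sigma)
  ri <- max(1L, floor(r0 - w)):min(nrow(img), ceiling(r0 + w))
  ci <- max(1L, floor(c0 - w)):min(ncol(img), ceiling(c0 + w))
  if (!length(ri) || !length(ci)) return(img)
  g <- exp(-(ri - r0)^2 / (2 * sigma^2)) %o% exp(-(ci - c0)^2 / (2 * sigma^2))
  img[ri, ci] <- img[ri, ci] + amp * g
  img
}

# Uniform sample inside the cell ellipse, restricted to one half-plane side
# of the nucleus line and away from the image border.
sample_spot <- function(p, side, nucleus, u, existing) {
  a <- p$cell_axes[1L]; b <- p$cell_axes[2L]
  margin <- p$border_margin_sigma * p$unit_sigma
  v <- c(-u[2L], u[1L])
  for (i in 1:20000) {
    r <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    xa <- a * r * cos(th); xb <- b * r * sin(th)
    pt <- p$cell_center + xa * u + xb * v
    d <- (pt[1L] - nucleus[1L]) * u[1L] + (pt[2L] - nucleus[2L]) * u[2L]
    if (side == "posterior" && d >= 0) next
    if (side == "anterior" && d < 0) next
    if (margin > 0 &&
        (pt[1L] < 1 + margin || pt[1L] > p$image_shape[1L] - margin ||
         pt[2L] < 1 + margin || pt[2L] > p$image_shape[2L] - margin)) next
    if (p$min_spot_separation > 0 && nrow(existing) > 0) {
      dd <- sqrt((existing[, 1L] - pt[1L])^2 + (existing[, 2L] - pt[2L])^2)
      if (any(dd < p$min_spot_separation)) next
    }
    return(pt)
  }
  stop("could not place a spot satisfying the constraints after 20000 attempts")
}

#' Render a synthetic FISH scene
#'
#' Draws spot positions inside the cell mask (posterior with probability
#' `enrichment`, uniform within the chosen half), renders the mRNA channel as
#' background + a sum of unit Gaussians (+ optional noise), and renders a
#' protein channel whose within-cell intensity is split between the halves at
#' `protein_posterior_fraction`. Fully reproducible from `params$seed`.
#'
#' @param params a [scene_params()] object.
#' @return A list with components `scene` (class `fish_scene`: ground truth
#'   positions, half labels, counts, geometry), `mrna` and `protein`
#'   ([fluor_image()] objects).
#' @export
render_scene <- function(params) {
  p <- validate_scene_params(params)
  set.seed(p$seed)
  shape <- p$image_shape
  a <- p$cell_axes[1L]; b <- p$cell_axes[2L]
  u <- axis_direction(p$polarity_axis_angle)
  nucleus <- p$cell_center + p$nucleus_offset * u
  aggregation <- p$cell_center + 3 * a * u
  cellmask <- ellipse_mask(shape, p$cell_center, a, b, p$polarity_axis_angle)

  labels <- if (p$n_spots > 0)
    ifelse(stats::runif(p$n_spots) < p$enrichment, "posterior", "anterior")
  else character(0)
  pos <- matrix(numeric(0), 0L, 2L)
  for (lab in labels)
    pos <- rbind(pos, sample_spot(p, lab, nucleus, u, pos))
  colnames(pos) <- c("row", "col")

  mrna <- matrix(p$background, shape[1L], shape[2L])
  for (i in seq_len(nrow(pos)))
    mrna <- add_gaussian(mrna, pos[i, 1L], pos[i, 2L],
                         p$unit_amplitude, p$unit_sigma)

  # protein channel: per-half constant intensities chosen so the posterior
  # share of total within-cell intensity is exactly protein_posterior_fraction
  rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  d <- (rows - nucleus[1L]) * u[1L] + (cols - nucleus[2L]) * u[2L]
  post_mask <- cellmask & d < 0
  ant_mask <- cellmask & d >= 0
  n_post <- sum(post_mask); n_ant <- sum(ant_mask)
  total <- p$protein_mean_intensity * (n_post + n_ant)
  protein <- matrix(p$background, shape[1L], shape[2L])
  if (n_post > 0)
    protein[post_mask] <- protein[post_mask] +
      p$protein_posterior_fraction * total / n_post
  if (n_ant > 0)
    protein[ant_mask] <- protein[ant_mask] +
      (1 - p$protein_posterior_fraction) * total / n_ant

  mrna <- apply_noise(mrna, p)
  protein <- apply_noise(protein, p)

  scene <- structure(
    list(params = p, spot_positions = pos, spot_half = labels,
         true_anterior_count = sum(labels == "anterior"),
         true_posterior_count = sum(labels == "posterior"),
         cell_polygon = ellipse_polygon(p$cell_center, a, b,
                                        p$polarity_axis_angle, n = 128L),
         cell_mask = cellmask,
         nucleus_centroid = nucleus, aggregation_point = aggregation),
    class = "fish_scene")
  list(scene = scene,
       mrna = fluor_image(mrna, channel = "mRNA"),
       protein = fluor_image(protein, channel = "protein"))
}

apply_noise <- function(img, p) {
  if (p$poisson_noise)
    img <- matrix(stats::rpois(length(img), lambda = img),
                  nrow(img), ncol(img))
  if (p$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = p$read_noise_sd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

#' @export
print.fish_scene <- function(x, ...) {
  cat(sprintf(
    "<fish_scene> %d x %d px, %d spots (%d anterior / %d posterior), f = %.2f\n",
    x$params$image_shape[1L], x$params$image_shape[2L], x$params$n_spots,
    x$true_anterior_count, x$true_posterior_count, x$params$enrichment))
  invisible(x)
}

#' Anterior/posterior ROI pair of a synthetic scene
#'
#' Bisects the scene's cell polygon about its nucleus centroid, oriented by
#' its aggregation point, exactly as [bisect_cell()] would on measured
#' geometry.
#'
#' @param scene a `fish_scene`.
#' @return An `roi_pair`.
#' @export
scene_roi_pair <- function(scene) {
  stopifnot(inherits(scene, "fish_scene"))
  bisect_cell(scene$cell_polygon, scene$nucleus_centroid,
              scene$aggregation_point)
}

#' Generate a cohort of scenes organised by stream position
#'
#' One scene per cell, with the posterior enrichment set by the cell's
#' position label (beginning, middle or end of a chemotactic stream, or
#' single). Per-cell seeds are derived deterministically from
#' `base_params$seed` so the cohort is reproducible as a whole.
#'
#' @param n_cells number of cells.
#' @param position_labels character vector of labels from
#'   `c("beginning", "middle", "end", "single")`, recycled to `n_cells`.
#' @param enrichment_by_position named list/vector mapping each label to a
#'   posterior spot fraction.
#' @param base_params a [scene_params()] object supplying all other
#'   parameters (its `seed` is the cohort master seed).
#' @param protein_tracks_mrna logical; if `TRUE` the protein channel's
#'   posterior fraction is set equal to the mRNA enrichment for each cell
#'   (an "ACA-like" cohort), otherwise `base_params$protein_posterior_fraction`
#'   is used for every cell (e.g. 0.5, a "cAR1-like" cohort).
#' @param poisson_spot_count logical; draw each cell's spot count from a
#'   Poisson distribution with mean `base_params$n_spots` instead of using
#'   the fixed value. This models cell-to-cell expression variability and,
#'   by Poisson thinning, makes the anterior and posterior counts of a cell
#'   independent — without it they are artificially anticorrelated (they sum
#'   to a constant), which no real cohort exhibits.
#' @return A list of per-cell lists (`scene`, `mrna`, `protein`, `position`).
#' @export
make_stream_cohort <- function(n_cells, position_labels,
                               enrichment_by_position, base_params,
                               protein_tracks_mrna = FALSE,
                               poisson_spot_count = TRUE) {
  if (length(position_labels) == 0L) stop("position_labels must be nonempty")
  known <- c("beginning", "middle", "end", "single")
  if (!all(position_labels %in% known))
    stop("unknown position label(s): ",
         paste(setdiff(position_labels, known), collapse = ", "))
  labs <- rep_len(position_labels, n_cells)
  missing <- setdiff(unique(labs), names(enrichment_by_position))
  if (length(missing))
    stop("no enrichment given for position(s): ",
         paste(missing, collapse = ", "))
  seeds <- derive_seeds(base_params$seed, 2L * n_cells)
  lapply(seq_len(n_cells), function(i) {
    p <- base_params
    p$enrichment <- as.numeric(enrichment_by_position[[labs[i]]])
    if (protein_tracks_mrna)
      p$protein_posterior_fraction <- p$enrichment
    if (poisson_spot_count) {
      set.seed(seeds[2L * i - 1L])
      p$n_spots <- stats::rpois(1L, base_params$n_spots)
    }
    p$seed <- seeds[2L * i]
    out <- render_scene(p)
    out$position <- labs[i]
    out
  })
}

# Deterministic stream of sub-seeds from a master seed.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(master_seed))
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
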