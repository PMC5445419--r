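# Per-ROI mRNA unit counts by two complementary estimators:
#
#  * linear estimate  — integrated ROI intensity divided by the integrated
#    intensity of one unit (2*pi*A*sigma^2); exact for isolated spots, but
#    blind to how intensity decomposes into spots;
#  * simulated estimate — repeated stochastic greedy reconstruction that
#    rebuilds the image one unit PSF at a time while the sum of squared
#    differences (SSD) to the original keeps decreasing; robust when spots
#    overlap, at the cost of Monte Carlo variance.

#' Linear estimate of the mRNA unit content of an ROI
#'
#' Integrated intensity inside the region divided by the integrated
#' intensity of a single unit.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param roi the region: a `(row, col)` polygon matrix or a logical mask
#'   matrix.
#' @param unit a [unit_model()].
#' @return A non-negative real number of units.
#' @export
linear_estimate <- function(image, roi, unit) {
  image <- as_fluor_image(image)
  if (unit$integrated_intensity <= 0)
    stop("unit integrated intensity must be positive")
  mask <- as_pixel_mask(roi, dim(image$pixels))
  if (!any(mask)) stop("roi contains no pixels")
  sum(image$pixels[mask]) / unit$integrated_intensity
}

#' Greedy stochastic reconstruction of an image from unit PSFs
#'
#' Rebuilds the (background-subtracted) image one unit at a time: at each
#' step a candidate position is drawn at the current residual maximum,
#' perturbed by a uniform jitter of up to `jitter_px` in each coordinate,
#' and then refined to the locally SSD-minimising subpixel position (the
#' jitter makes repeated runs explore different configurations where spots
#' overlap; the refinement enforces the squared-difference objective for
#' each placement). The placement is accepted if it decreases the SSD over
#' the mask by more than `stop_tol` times the initial SSD; the first
#' rejected placement ends the loop. The residual may go negative (no
#' clipping), so over-placement is penalised naturally by the SSD.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param unit a [unit_model()].
#' @param mask optional reconstruction domain (logical matrix or polygon);
#'   default is the whole image.
#' @param seed integer seed for the placement jitter.
#' @param jitter_px maximum jitter per coordinate in pixels; `0` makes the
#'   reconstruction deterministic.
#' @param stop_tol minimum accepted SSD decrease per placement, as a
#'   fraction of the initial SSD.
#' @param max_units safety cap on the number of placements; defaults to
#'   three times the linear estimate of the mask plus 20.
#' @return An object of class `recon_trace`: `placements` (n x 2 matrix),
#'   `ssd_initial`, `ssd_after_each` (non-increasing), `final_count`,
#'   `seed`, `converged` (`TRUE` when stopped by the SSD rule rather than
#'   the cap).
#' @export
reconstruct <- function(image, unit, mask = NULL, seed = 1L,
                        jitter_px = 1, stop_tol = 1e-4,
                        max_units = NULL) {
  image <- as_fluor_image(image)
  px <- image$pixels
  shape <- dim(px)
  m <- if (is.null(mask)) matrix(TRUE, shape[1L], shape[2L])
       else as_pixel_mask(mask, shape)
  if (!any(m)) stop("mask contains no pixels")
  bb <- which(m, arr.ind = TRUE)
  if ((max(bb[, 1L]) - min(bb[, 1L]) + 1) < 4 * unit$sigma &&
      (max(bb[, 2L]) - min(bb[, 2L]) + 1) < 4 * unit$sigma)
    stop("unit PSF is wider than the reconstruction mask")

  set.seed(as.integer(seed))
  resid <- px
  ssd0 <- sum(resid[m]^2)
  if (is.null(max_units))
    max_units <- ceiling(3 * sum(resid[m]) / unit$integrated_intensity) + 20L

  placements <- matrix(numeric(0), 0L, 2L)
  ssd_trace <- numeric(0)
  ssd <- ssd0
  converged <- FALSE
  neg_inf <- matrix(-Inf, shape[1L], shape[2L])
  w <- ceiling(5 * unit$sigma)
  # change in SSD from subtracting one unit PSF at position q, together
  # with the touched window
  delta_at <- function(q) {
    ri <- max(1L, floor(q[1L] - w)):min(shape[1L], ceiling(q[1L] + w))
    ci <- max(1L, floor(q[2L] - w)):min(shape[2L], ceiling(q[2L] + w))
    g <- unit$amplitude *
      (exp(-(ri - q[1L])^2 / (2 * unit$sigma^2)) %o%
       exp(-(ci - q[2L])^2 / (2 * unit$sigma^2)))
    old <- resid[ri, ci]
    new <- old - g
    wm <- m[ri, ci]
    list(delta = sum(new[wm]^2) - sum(old[wm]^2),
         ri = ri, ci = ci, new = new)
  }
  while (nrow(placements) < max_units) {
    masked <- ifelse(m, resid, neg_inf)
    idx <- arrayInd(which.max(masked), shape)
    pos <- as.numeric(idx) +
      if (jitter_px > 0) stats::runif(2, -jitter_px, jitter_px) else c(0, 0)
    # refine the jittered candidate to the local SSD minimum
    opt <- stats::optim(pos, function(q) delta_at(q)$delta,
                        method = "L-BFGS-B",
                        lower = pmax(pos - 1.5, 1),
                        upper = pmin(pos + 1.5, shape))
    pos <- opt$par
    upd <- delta_at(pos)
    ssd_new <- ssd + upd$delta
    if ((ssd - ssd_new) <= stop_tol * ssd0) { converged <- TRUE; break }
    resid[upd$ri, upd$ci] <- upd$new
    ssd <- ssd_new
    placements <- rbind(placements, pos)
    ssd_trace <- c(ssd_trace, ssd)
  }
  rownames(placements) <- NULL
  colnames(placements) <- c("row", "col")
  structure(
    list(placements = placements, ssd_initial = ssd0,
         ssd_after_each = ssd_trace, final_count = nrow(placements),
         shape = shape, seed = as.integer(seed), converged = converged),
    class = "recon_trace")
}

#' @export
print.recon_trace <- function(x, ...) {
  cat(sprintf(
    "<recon_trace> %d units placed, SSD %.4g -> %.4g%s (seed %d)\n",
    x$final_count, x$ssd_initial,
    if (x$final_count > 0) x$ssd_after_each[x$final_count] else x$ssd_initial,
    if (x$converged) "" else " [hit placement cap]", x$seed))
  invisible(x)
}

# Count placements of one trace falling inside each ROI of an roi_pair
# (assigned by the side of the bisecting line, boundary ties to anterior)
# or inside a single polygon/mask.
count_placements <- function(trace, rois, shape) {
  pl <- trace$placements
  if (inherits(rois, "roi_pair")) {
    if (nrow(pl) == 0L) return(c(anterior = 0, posterior = 0))
    d <- halfplane_side(pl, rois$bisecting_line$point,
                        rois$bisecting_line$anterior_normal)
    c(anterior = sum(d >= 0), posterior = sum(d < 0))
  } else {
    if (nrow(pl) == 0L) return(c(roi = 0))
    if (is.matrix(rois) && is.logical(rois)) {
      ij <- cbind(pmin(pmax(round(pl[, 1L]), 1L), shape[1L]),
                  pmin(pmax(round(pl[, 2L]), 1L), shape[2L]))
      c(roi = sum(rois[ij]))
    } else {
      inside <- pracma::inpolygon(pl[, 2L], pl[, 1L],
                                  rois[, 2L], rois[, 1L], boundary = TRUE)
      c(roi = sum(inside))
    }
  }
}

#' Simulated (reconstruction-based) per-ROI unit counts
#'
#' Runs [reconstruct()] `n_reps` times with seeds derived from
#' `master_seed`, counts the placements falling inside each ROI, and
#' reports the mean and standard deviation across repetitions alongside the
#' linear estimate of the same ROI.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param rois an `roi_pair` (anterior/posterior), or a single polygon or
#'   logical mask.
#' @param unit a [unit_model()].
#' @param n_reps number of reconstruction repetitions (`>= 1`).
#' @param master_seed seed from which per-repetition seeds are derived.
#' @param mask reconstruction domain passed to [reconstruct()]; default the
#'   whole image, so spot tails falling just outside an ROI still attract
#'   their unit to the right place.
#' @param jitter_px,stop_tol passed to [reconstruct()].
#' @return An object of class `count_estimate`: a data frame with one row
#'   per ROI and columns `roi_id`, `linear_count`, `sim_count_mean`,
#'   `sim_count_sd`, `n_reps`. The traces are attached as attribute
#'   `"traces"` and the unit as `"unit"`.
#' @export
simulated_estimate <- function(image, rois, unit, n_reps = 10L,
                               master_seed = 1L, mask = NULL,
                               jitter_px = 1, stop_tol = 1e-4) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  image <- as_fluor_image(image)
  shape <- dim(image$pixels)
  seeds <- derive_seeds(master_seed, n_reps)
  traces <- lapply(seeds, function(s)
    reconstruct(image, unit, mask = mask, seed = s,
                jitter_px = jitter_px, stop_tol = stop_tol))
  counts <- do.call(rbind, lapply(traces, count_placements,
                                  rois = rois, shape = shape))
  if (inherits(rois, "roi_pair")) {
    # split the whole image by the bisecting line so boundary tails are not
    # lost (consistent with the half-plane placement counting)
    masks <- roi_pair_masks(rois, shape,
                            cell_mask = matrix(TRUE, shape[1L], shape[2L]))
    lin <- c(anterior = linear_estimate(image, masks$anterior, unit),
             posterior = linear_estimate(image, masks$posterior, unit))
  } else {
    lin <- c(roi = linear_estimate(image, rois, unit))
  }
  out <- data.frame(
    roi_id = colnames(counts),
    linear_count = as.numeric(lin[colnames(counts)]),
    sim_count_mean = apply(counts, 2L, mean),
    sim_count_sd = if (n_reps == 1L) rep(0, ncol(counts))
                   else apply(counts, 2L, stats::sd),
    n_reps = n_reps,
    row.names = NULL)
  class(out) <- c("count_estimate", "data.frame")
  attr(out, "traces") <- traces
  attr(out, "unit") <- unit
  out
}

#' Average reconstructed image across repetitions
#'
#' Renders each trace's placements as unit PSFs and averages the renderings:
#' a spatial map of the estimated mRNA units.
#'
#' @param traces list of `recon_trace` objects.
#' @param shape image dimensions `c(rows, cols)`.
#' @param unit the [unit_model()] used for the reconstructions.
#' @return A [fluor_image()] with channel `"reconstruction"`.
#' @export
average_image <- function(traces, shape, unit) {
  if (length(traces) == 0L) stop("need at least one trace")
  acc <- matrix(0, shape[1L], shape[2L])
  for (tr in traces) {
    if (!is.null(tr$shape) && !all(tr$shape == shape))
      stop("trace shape mismatch: trace is ",
           paste(tr$shape, collapse = " x "), ", requested ",
           paste(shape, collapse = " x "))
    img <- matrix(0, shape[1L], shape[2L])
    for (i in seq_len(nrow(tr$placements)))
      img <- add_gaussian(img, tr$placements[i, 1L], tr$placements[i, 2L],
                          unit$amplitude, unit$sigma)
    acc <- acc + img
  }
  fluor_image(acc / length(traces), channel = "reconstruction")
}
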