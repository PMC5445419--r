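# Unit calibration: spot detection, Gaussian PSF fitting, and derivation of
# the characteristic "mRNA unit" from the trimmed fit-parameter
# distributions.
#
# The unit is the denomination in which all counts are reported. It is
# obtained by (i) finding isolated peaks, (ii) fitting each to an isotropic
# Gaussian PSF with a free local background, (iii) discarding fits outside a
# size window, and (iv) trimming the amplitude distribution from above until
# both the amplitude and width distributions are unimodal, then averaging.

#' Detect candidate spots as thresholded local maxima
#'
#' Finds 8-neighbourhood local maxima whose value exceeds `k_sigma` times a
#' robust noise scale (median absolute deviation of the image), and enforces
#' a minimum separation between peaks (keeping the brighter of any close
#' pair). Run on a background-subtracted image.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param min_separation_px minimum allowed distance between two peaks, in
#'   pixels (`> 0`).
#' @param k_sigma intensity threshold in units of the robust noise scale.
#' @return A data frame of candidates sorted by decreasing peak value, with
#'   columns `row`, `col`, `peak_value` and placeholder fit columns
#'   (`fit_amplitude`, `fit_sigma`, `fit_background`, `fit_rss`, `accepted`).
#' @export
detect_peaks <- function(image, min_separation_px = 3, k_sigma = 5) {
  if (min_separation_px <= 0) stop("min_separation_px must be positive")
  image <- as_fluor_image(image)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  noise <- stats::mad(px)
  thr <- k_sigma * noise

  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  ismax <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    ismax <- ismax & (px >= nb)
  }
  ismax <- ismax & (px > thr) & (px > 0)
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_candidates())
  vals <- px[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]

  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- idx[keep, , drop = FALSE]
    dd <- sqrt((prev[, 1L] - idx[i, 1L])^2 + (prev[, 2L] - idx[i, 2L])^2)
    keep[i] <- all(dd >= min_separation_px)
  }
  data.frame(row = as.numeric(idx[keep, 1L]),
             col = as.numeric(idx[keep, 2L]),
             peak_value = vals[keep],
             fit_amplitude = NA_real_, fit_sigma = NA_real_,
             fit_background = NA_real_, fit_rss = NA_real_,
             accepted = FALSE)
}

empty_candidates <- function() {
  data.frame(row = numeric(0), col = numeric(0), peak_value = numeric(0),
             fit_amplitude = numeric(0), fit_sigma = numeric(0),
             fit_background = numeric(0), fit_rss = numeric(0),
             accepted = logical(0))
}

#' Fit an isotropic Gaussian PSF to one candidate spot
#'
#' Least-squares fit of `b + A * exp(-((r - r0)^2 + (c - c0)^2) / (2 s^2))`
#' over a square window centred on the candidate, using
#' Levenberg-Marquardt. Non-convergent, non-positive-amplitude or
#' implausibly wide fits are marked not accepted.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param candidate one row of the [detect_peaks()] data frame (or a list
#'   with `row`, `col`).
#' @param window_px half-width of the fit window in pixels; the window is
#'   `(2 * window_px + 1)` pixels square and must lie inside the image.
#' @return The candidate row with `fit_amplitude`, `fit_sigma`,
#'   `fit_background`, `fit_rss`, refined `row`/`col` and `accepted` filled.
#' @export
fit_psf <- function(image, candidate, window_px = 5L) {
  image <- as_fluor_image(image)
  px <- image$pixels
  r0 <- round(candidate$row); c0 <- round(candidate$col)
  w <- as.integer(window_px)
  if (r0 - w < 1L || r0 + w > nrow(px) || c0 - w < 1L || c0 + w > ncol(px))
    stop("fit window extends beyond the image")
  ri <- (r0 - w):(r0 + w); ci <- (c0 - w):(c0 + w)
  win <- px[ri, ci]
  dat <- data.frame(r = rep(ri, times = length(ci)),
                    c = rep(ci, each = length(ri)),
                    z = as.vector(win))
  out <- candidate
  out$accepted <- FALSE
  if (max(win) - min(win) <= 0) return(out)   # flat window: nothing to fit

  start <- list(b = min(win), A = max(win) - min(win),
                r0 = candidate$row, c0 = candidate$col, s = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2)),
      data = dat, start = start,
      lower = c(b = -Inf, A = 0, r0 = min(ri) - 1, c0 = min(ci) - 1,
                s = 0.2),
      upper = c(b = Inf, A = Inf, r0 = max(ri) + 1, c0 = max(ci) + 1,
                s = 2 * w),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$fit_amplitude <- cf[["A"]]
  out$fit_sigma <- cf[["s"]]
  out$fit_background <- cf[["b"]]
  out$fit_rss <- sum(stats::residuals(fit)^2)
  out$row <- cf[["r0"]]; out$col <- cf[["c0"]]
  out$accepted <- cf[["A"]] > 0 && cf[["s"]] > 0 && cf[["s"]] < w
  out
}

# Sarle's bimodality coefficient with the finite-sample correction:
# (skewness^2 + 1) / (kurtosis + 3 (n-1)^2 / ((n-2)(n-3))).
# Values above ~0.555 (the uniform distribution's value) suggest
# bimodality. Zero-variance samples are maximally unimodal (returns 0).
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L) return(0)
  m <- mean(x); s2 <- stats::var(x)
  # a spread below 1% of the mean carries no mode structure; skewness and
  # kurtosis estimates on such samples are dominated by numerical noise
  if (sqrt(s2) <= 0.01 * max(abs(m), .Machine$double.eps)) return(0)
  z <- (x - m) / sqrt(s2 * (n - 1) / n)      # population-sd standardised
  g1 <- mean(z^3)
  g2 <- mean(z^4) - 3
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  (skew^2 + 1) / (kurt + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Derive the characteristic mRNA unit from fitted spot candidates
#'
#' Keeps accepted fits with width inside `size_bounds`, then iteratively
#' thresholds the fit-parameter distributions from above — at each step the
#' top `trim_step` quantile of whichever distribution (amplitude or width)
#' is currently the more bimodal is removed — until the bimodality
#' coefficient of both falls below `unimodality_threshold`. The means of
#' the surviving distributions define the unit. Trimming the width as well
#' as the amplitude matters in crowded images, where unresolved spot pairs
#' produce a wide-sigma mode that amplitude trimming alone cannot remove.
#'
#' @param candidates data frame from [fit_psf()] (rows with `accepted`,
#'   `fit_amplitude`, `fit_sigma`).
#' @param size_bounds `c(sigma_min, sigma_max)` in pixels.
#' @param trim_step fraction of the candidate set removed per trimming
#'   iteration (from the top of the amplitude distribution).
#' @param unimodality_threshold bimodality-coefficient threshold below which
#'   a distribution is considered unimodal; 0.555 is the uniform
#'   distribution's value.
#' @param min_support minimum number of surviving candidates.
#' @return An object of class `unit_model` with fields `amplitude`, `sigma`,
#'   `integrated_intensity` (`2 * pi * amplitude * sigma^2`), `n_support`
#'   and `trim_fraction_applied`.
#' @export
derive_unit <- function(candidates, size_bounds = c(0.8, 3.0),
                        trim_step = 0.02, unimodality_threshold = 0.555,
                        min_support = 10L) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("insufficient isolated spots: empty candidate list")
  keep <- candidates$accepted &
    candidates$fit_sigma >= size_bounds[1L] &
    candidates$fit_sigma <= size_bounds[2L]
  cand <- candidates[keep, , drop = FALSE]
  n0 <- nrow(cand)
  if (n0 < min_support)
    stop("insufficient isolated spots: ", n0, " accepted candidates (need ",
         min_support, ")")
  repeat {
    bc_a <- bimodality_coefficient(cand$fit_amplitude)
    bc_s <- bimodality_coefficient(cand$fit_sigma)
    if (bc_a < unimodality_threshold && bc_s < unimodality_threshold) break
    n_drop <- max(1L, ceiling(trim_step * nrow(cand)))
    if (nrow(cand) - n_drop < min_support)
      stop("insufficient isolated spots: trimming exhausted the candidates ",
           "before reaching unimodality")
    target <- if (bc_s >= bc_a) cand$fit_sigma else cand$fit_amplitude
    ord <- order(target, decreasing = TRUE)
    cand <- cand[-ord[seq_len(n_drop)], , drop = FALSE]
  }
  unit_model(amplitude = mean(cand$fit_amplitude),
             sigma = mean(cand$fit_sigma),
             n_support = nrow(cand),
             trim_fraction_applied = 1 - nrow(cand) / n0)
}

#' Construct an mRNA unit model
#'
#' @param amplitude unit PSF peak intensity.
#' @param sigma unit PSF width in pixels.
#' @param n_support number of candidates averaged.
#' @param trim_fraction_applied fraction of candidates removed by trimming.
#' @return An object of class `unit_model`.
#' @export
unit_model <- function(amplitude, sigma, n_support = NA_integer_,
                       trim_fraction_applied = NA_real_) {
  if (amplitude <= 0 || sigma <= 0)
    stop("unit amplitude and sigma must be positive")
  structure(
    list(amplitude = amplitude, sigma = sigma,
         integrated_intensity = 2 * pi * amplitude * sigma^2,
         n_support = n_support,
         trim_fraction_applied = trim_fraction_applied),
    class = "unit_model")
}

#' @export
print.unit_model <- function(x, ...) {
  cat(sprintf(
    "<unit_model> A = %.4g, sigma = %.4g px, I = %.4g (2*pi*A*sigma^2)\n",
    x$amplitude, x$sigma, x$integrated_intensity))
  if (!is.na(x$n_support))
    cat(sprintf("  support: %d candidates, trim fraction %.3f\n",
                x$n_support, x$trim_fraction_applied))
  invisible(x)
}

#' Calibrate the mRNA unit from one or more images
#'
#' Convenience wrapper chaining [subtract_background()], [detect_peaks()],
#' [fit_psf()] (skipping candidates whose window does not fit inside the
#' image) and [derive_unit()]. Candidates are pooled across images.
#'
#' @param images a [fluor_image()] or list of them (raw, not
#'   background-subtracted).
#' @param cell_masks optional mask or list of masks matched to `images`,
#'   passed to [subtract_background()].
#' @param min_separation_px,k_sigma passed to [detect_peaks()].
#' @param window_px passed to [fit_psf()].
#' @param size_bounds,trim_step,unimodality_threshold,min_support passed to
#'   [derive_unit()].
#' @return A `unit_model`; the pooled candidate table is attached as
#'   attribute `"candidates"`.
#' @export
calibrate_unit <- function(images, cell_masks = NULL,
                           min_separation_px = 3, k_sigma = 5,
                           window_px = 5L, size_bounds = c(0.8, 3.0),
                           trim_step = 0.02, unimodality_threshold = 0.555,
                           min_support = 10L) {
  if (inherits(images, "fluor_image")) images <- list(images)
  if (!is.null(cell_masks) && !is.list(cell_masks))
    cell_masks <- list(cell_masks)
  all_cand <- list()
  for (k in seq_along(images)) {
    img <- subtract_background(images[[k]],
                               if (is.null(cell_masks)) NULL
                               else cell_masks[[k]])
    cand <- detect_peaks(img, min_separation_px, k_sigma)
    fits <- lapply(seq_len(nrow(cand)), function(i) {
      r0 <- round(cand$row[i]); c0 <- round(cand$col[i])
      if (r0 - window_px < 1 || r0 + window_px > nrow(img$pixels) ||
          c0 - window_px < 1 || c0 + window_px > ncol(img$pixels))
        return(NULL)                          # too close to the border
      fit_psf(img, cand[i, ], window_px)
    })
    all_cand[[k]] <- do.call(rbind, fits)
  }
  pooled <- do.call(rbind, all_cand)
  unit <- derive_unit(pooled, size_bounds, trim_step,
                      unimodality_threshold, min_support)
  attr(unit, "candidates") <- pooled
  unit
}
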