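# Fluorescence image container and background handling.
#
# Images are plain numeric matrices indexed [row, col] wrapped in a light S3
# class. Continuous coordinates use the same (row, col) frame with the centre
# of pixel (i, j) at coordinates (i, j); all geometry (polygons, spot
# positions) lives in this frame.

#' Construct a fluorescence image
#'
#' Wraps a numeric matrix of pixel intensities together with a channel label
#' and projection provenance. Intensities must be finite and non-negative;
#' images smaller than 16 x 16 are rejected because spot fitting windows do
#' not fit inside them.
#'
#' @param pixels numeric matrix of non-negative intensities, `[row, col]`.
#' @param channel character label for the channel (e.g. `"mRNA"`,
#'   `"protein"`).
#' @param is_max_projection logical; whether the image is a maximum-intensity
#'   projection of a confocal stack.
#' @param pixel_size_um optional physical pixel size in micrometres.
#' @return An object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, channel = "mRNA", is_max_projection = TRUE,
                        pixel_size_um = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixel values")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16 x 16 pixels")
  if (any(pixels < 0))
    stop("image contains negative intensities")
  structure(
    list(pixels = pixels, channel = channel,
         is_max_projection = isTRUE(is_max_projection),
         pixel_size_um = pixel_size_um,
         background = NULL),
    class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d px, channel \"%s\"%s\n",
              nrow(x$pixels), ncol(x$pixels), x$channel,
              if (isTRUE(x$is_max_projection)) " (max projection)" else ""))
  cat(sprintf("  intensity range [%.3g, %.3g]",
              min(x$pixels), max(x$pixels)))
  if (!is.null(x$background))
    cat(sprintf(", background subtracted (%.3g)", x$background))
  cat("\n")
  invisible(x)
}

#' @export
dim.fluor_image <- function(x) dim(x$pixels)

#' @export
plot.fluor_image <- function(x, ...) {
  # image() draws column-major from the bottom; flip so row 1 is on top
  graphics::image(t(x$pixels)[, rev(seq_len(nrow(x$pixels)))],
                  col = grDevices::hcl.colors(64, "viridis"),
                  asp = nrow(x$pixels) / ncol(x$pixels), axes = FALSE, ...)
  invisible(x)
}

as_fluor_image <- function(x, channel = "mRNA") {
  if (inherits(x, "fluor_image")) x else fluor_image(x, channel = channel)
}

#' Subtract a scalar background estimate from an image
#'
#' Estimates the background as the median of the pixels outside `cell_mask`
#' when a mask is supplied, or the median of the whole image otherwise, then
#' subtracts it and clips at zero. The estimate is recorded in the returned
#' image's `background` field.
#'
#' @param image a [fluor_image()] (or bare matrix).
#' @param cell_mask optional cell region: a logical matrix of the image's
#'   dimensions or a polygon (two-column `(row, col)` matrix of vertices);
#'   pixels outside it are treated as pure background.
#' @return A background-subtracted `fluor_image`.
#' @export
subtract_background <- function(image, cell_mask = NULL) {
  image <- as_fluor_image(image)
  px <- image$pixels
  if (is.null(cell_mask)) {
    bg <- stats::median(px)
  } else {
    mask <- as_pixel_mask(cell_mask, dim(px))
    if (all(mask))
      stop("cell_mask covers the entire image; no background pixels left")
    bg <- stats::median(px[!mask])
  }
  out <- image
  out$pixels <- pmax(px - bg, 0)
  out$background <- bg
  out
}

# Coerce a mask specification (logical matrix or polygon) to a logical matrix.
as_pixel_mask <- function(mask, shape) {
  if (is.matrix(mask) && is.logical(mask)) {
    if (!all(dim(mask) == shape))
      stop("mask dimensions do not match the image")
    return(mask)
  }
  if (is.matrix(mask) && is.numeric(mask) && ncol(mask) == 2L)
    return(polygon_mask(mask, shape))
  stop("mask must be a logical matrix or a (row, col) polygon matrix")
}
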