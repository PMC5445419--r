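# Readers and writers: grayscale TIFF images, GeoJSON cell geometry,
# YAML run configuration.
#
# TIFF convention: intensities are stored divided by 65535 (the 16-bit
# range). 16-bit files hold rounded integer intensities exactly; 32-bit
# float files preserve fractional intensities to float32 precision.

TIFF_SCALE <- 65535

#' Read a grayscale 2D TIFF as a fluorescence image
#'
#' @param path file path.
#' @param channel channel label to attach.
#' @return A [fluor_image()]. Multi-page or multi-sample (RGB) TIFFs are
#'   rejected: the tool consumes single-channel maximum-intensity
#'   projections.
#' @export
read_image <- function(path, channel = "mRNA") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) != 1L)
    stop("unsupported format: expected a single-page grayscale TIFF, got ",
         length(pages), " pages")
  info <- attributes(pages[[1L]])
  if (!is.null(info$samples.per.pixel) && info$samples.per.pixel != 1L)
    stop("unsupported format: expected grayscale, got ",
         info$samples.per.pixel, " samples per pixel")
  bits <- info$bits.per.sample %||% 16L
  px <- if (bits >= 32L) {
    pages[[1L]] * TIFF_SCALE                 # float storage, scaled
  } else {
    tiff::readTIFF(path, as.is = TRUE) * 1.0 # integer storage, exact
  }
  if (length(dim(px)) != 2L)
    stop("unsupported format: expected a 2D grayscale image")
  px <- matrix(as.numeric(px), nrow(px), ncol(px))  # drop TIFF attributes
  fluor_image(px, channel = channel)
}

#' Write a fluorescence image as a grayscale TIFF
#'
#' @param image a [fluor_image()] or numeric matrix.
#' @param path output path.
#' @param bits 16 (unsigned integer, intensities rounded) or 32 (float,
#'   fractional intensities preserved).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  image <- as_fluor_image(image)
  px <- image$pixels
  if (bits == 16L) {
    if (max(px) > TIFF_SCALE)
      stop("intensities exceed the 16-bit range; use bits = 32")
    tiff::writeTIFF(round(px) / TIFF_SCALE, path, bits.per.sample = 16L)
  } else if (bits == 32L) {
    if (max(px) > TIFF_SCALE)
      stop("intensities exceed the storage range")
    tiff::writeTIFF(px / TIFF_SCALE, path, bits.per.sample = 32L)
  } else stop("bits must be 16 or 32")
  invisible(path)
}

# --- GeoJSON cell geometry ------------------------------------------------
#
# Dialect: a FeatureCollection whose features carry properties `role`
# (cell | nucleus | anterior | posterior | aggregation_center), `cell_id`,
# and optionally `stream_position`. Polygons are single closed rings;
# points are single positions. GeoJSON coordinates are [x, y] = [col, row].

ROI_ROLES <- c("cell", "nucleus", "anterior", "posterior",
               "aggregation_center")

poly_to_coords <- function(poly) {
  ring <- rbind(poly, poly[1L, ])            # close the ring
  lapply(seq_len(nrow(ring)),
         function(i) c(ring[i, 2L], ring[i, 1L]))
}

coords_to_poly <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[2]], p[[1]])))
  colnames(m) <- c("row", "col")
  m
}

# TRUE when any two non-adjacent edges of the closed ring intersect.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) list(p = poly[i, ], q = poly[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b)
    (a[2L] - o[2L]) * (b[1L] - o[1L]) - (a[1L] - o[1L]) * (b[2L] - o[2L])
  intersects <- function(s1, s2) {
    d1 <- cross(s2$p, s2$q, s1$p); d2 <- cross(s2$p, s2$q, s1$q)
    d3 <- cross(s1$p, s1$q, s2$p); d4 <- cross(s1$p, s1$q, s2$q)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next            # adjacent through the closure
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

#' Read cell geometry from GeoJSON
#'
#' Parses a FeatureCollection in the package's dialect (roles cell, nucleus,
#' anterior, posterior, aggregation_center; property `cell_id` mandatory)
#' and groups the features per cell. Open rings, self-intersecting polygons
#' and unknown roles are rejected with the offending feature index.
#'
#' @param path GeoJSON file path.
#' @return A named list (one element per `cell_id`), each with entries
#'   `cell_id`, `stream_position`, and whichever of `cell`, `nucleus`,
#'   `anterior`, `posterior`, `aggregation_center` were present (polygons as
#'   `(row, col)` matrices, points as length-2 vectors).
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  cells <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    props <- ft$properties
    role <- props$role
    if (is.null(role) || !(role %in% ROI_ROLES))
      stop("feature ", i, ": unknown or missing role \"",
           if (is.null(role)) "" else role, "\"")
    if (is.null(props$cell_id))
      stop("feature ", i, ": missing cell_id")
    id <- as.character(props$cell_id)
    geom <- ft$geometry
    value <- if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1L]]
      if (length(ring) < 4L)
        stop("feature ", i, ": polygon ring has fewer than 4 positions")
      first <- unlist(ring[[1L]]); last <- unlist(ring[[length(ring)]])
      if (!isTRUE(all.equal(first, last)))
        stop("feature ", i, ": polygon ring is not closed")
      poly <- coords_to_poly(ring[-length(ring)])
      if (polygon_self_intersects(poly))
        stop("feature ", i, ": polygon is self-intersecting")
      poly
    } else if (identical(geom$type, "Point")) {
      p <- unlist(geom$coordinates)
      c(p[[2]], p[[1]])
    } else stop("feature ", i, ": unsupported geometry type ", geom$type)
    if (is.null(cells[[id]]))
      cells[[id]] <- list(cell_id = id,
                          stream_position = props$stream_position %||% "single")
    cells[[id]][[role]] <- value
  }
  cells
}

#' Write cell geometry to GeoJSON
#'
#' Inverse of [read_rois()].
#'
#' @param cells list as returned by [read_rois()] (or assembled in code).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(cells, path) {
  features <- list()
  for (cell in cells) {
    for (role in intersect(names(cell), ROI_ROLES)) {
      val <- cell[[role]]
      geom <- if (is.matrix(val))
        list(type = "Polygon", coordinates = list(poly_to_coords(val)))
      else
        list(type = "Point", coordinates = c(val[2L], val[1L]))
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(role = role, cell_id = cell$cell_id,
                          stream_position = cell$stream_position %||% "single"),
        geometry = geom)
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a rendered scene to disk
#'
#' One float TIFF per channel, a GeoJSON with the cell polygon, nucleus and
#' aggregation centre, and a ground-truth CSV of spot positions and half
#' labels.
#'
#' @param rendered list from [render_scene()].
#' @param dir output directory (created if needed).
#' @param basename file name stem, e.g. `"cell_001"`.
#' @return The directory, invisibly.
#' @export
write_scene <- function(rendered, dir, basename = "cell") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- rendered$scene
  write_image(rendered$mrna, file.path(dir, paste0(basename, "_mrna.tif")),
              bits = 32L)
  write_image(rendered$protein,
              file.path(dir, paste0(basename, "_protein.tif")), bits = 32L)
  cell <- list(cell_id = basename,
               stream_position = rendered$position %||% "single",
               cell = sc$cell_polygon,
               nucleus = sc$nucleus_centroid,
               aggregation_center = sc$aggregation_point)
  write_rois(list(cell), file.path(dir, paste0(basename, "_rois.geojson")))
  truth <- data.frame(row = sc$spot_positions[, 1L],
                      col = sc$spot_positions[, 2L],
                      half = sc$spot_half)
  utils::write.csv(truth, file.path(dir, paste0(basename, "_truth.csv")),
                   row.names = FALSE)
  invisible(dir)
}
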