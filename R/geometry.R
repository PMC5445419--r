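# Cell geometry: polygons, axis fitting, eccentricity, and the
# anterior/posterior bisection about the nucleus.
#
# Polygons are two-column (row, col) matrices of vertices, implicitly closed
# (the last vertex connects back to the first). Areas use the shoelace
# formula; second-order area moments give the equivalent-inertia ellipse.

#' Regular polygon approximation of an ellipse
#'
#' @param center `(row, col)` centre.
#' @param a,b semi-major and semi-minor axis lengths in pixels (`a >= b`).
#' @param angle orientation of the major axis in radians; `0` points along
#'   increasing column.
#' @param n number of vertices.
#' @return An `n x 2` `(row, col)` vertex matrix.
#' @export
ellipse_polygon <- function(center, a, b, angle = 0, n = 128L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- axis_direction(angle)                 # unit vector along major axis
  v <- c(-u[2L], u[1L])                      # perpendicular
  pts <- cbind(a * cos(t), b * sin(t))
  out <- cbind(center[1L] + pts[, 1L] * u[1L] + pts[, 2L] * v[1L],
               center[2L] + pts[, 1L] * u[2L] + pts[, 2L] * v[2L])
  colnames(out) <- c("row", "col")
  out
}

# Unit direction vector (row, col) for an axis angle; angle 0 = +col.
axis_direction <- function(angle) c(sin(angle), cos(angle))

#' Polygon area (shoelace formula)
#'
#' @param poly `(row, col)` vertex matrix.
#' @return Non-negative area in square pixels.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 2L]; y <- poly[, 1L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 2L]; y <- poly[, 1L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(c(mean(y), mean(x)))
  cx <- sum((x + xs) * cr) / (6 * a)
  cy <- sum((y + ys) * cr) / (6 * a)
  c(cy, cx)
}

# Second-order central area moments of a polygon, returned as the 2x2
# covariance matrix of the uniform density over its interior, in (row, col).
polygon_covariance <- function(poly) {
  x <- poly[, 2L]; y <- poly[, 1L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) <= .Machine$double.eps)
    stop("degenerate polygon: zero area")
  cx <- sum((x + xs) * cr) / (6 * a)
  cy <- sum((y + ys) * cr) / (6 * a)
  ixx <- sum((y^2 + y * ys + ys^2) * cr) / 12      # about origin, d(col)
  iyy <- sum((x^2 + x * xs + xs^2) * cr) / 12
  ixy <- sum((x * ys + 2 * x * y + 2 * xs * ys + xs * y) * cr) / 24
  # central moments, normalised by area -> covariance of uniform density
  vrr <- ixx / a - cy^2
  vcc <- iyy / a - cx^2
  vrc <- ixy / a - cx * cy
  matrix(c(vrr, vrc, vrc, vcc), 2L, 2L)
}

#' Fit the equivalent-ellipse axes of a cell outline
#'
#' Computes the semi-axes of the ellipse with the same second-order area
#' moments as the polygon (the "equivalent inertia" ellipse). For an
#' axis-aligned ellipse with semi-axes a, b the eigenvalues of the interior
#' covariance are a^2/4 and b^2/4, so axes are recovered as twice the square
#' roots of the eigenvalues.
#'
#' @param cell_polygon `(row, col)` vertex matrix of a simple polygon with
#'   positive area.
#' @return A list with `a` (semi-major, px), `b` (semi-minor, px) and
#'   `orientation` (radians, angle of the major axis; 0 = along columns).
#' @export
fit_cell_axes <- function(cell_polygon) {
  if (!is.matrix(cell_polygon) || ncol(cell_polygon) != 2L ||
      nrow(cell_polygon) < 3L)
    stop("cell_polygon must be an n x 2 (row, col) matrix with n >= 3")
  v <- polygon_covariance(cell_polygon)
  e <- eigen(v, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  a <- 2 * sqrt(lam[1L])
  b <- 2 * sqrt(lam[2L])
  vec <- e$vectors[, 1L]                    # (row, col) components
  list(a = a, b = b, orientation = atan2(vec[1L], vec[2L]))
}

#' Eccentricity of a cell from its semi-axes
#'
#' The polarization score `sqrt(1 - b^2 / a^2)`: 0 for a circle
#' (non-polarized cell), approaching 1 for an elongated (polarized) cell.
#'
#' @param a semi-major axis, `a > 0`.
#' @param b semi-minor axis, `0 <= b <= a`.
#' @return Eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b))
    stop("a and b must be numeric of equal length")
  if (any(a <= 0)) stop("semi-major axis a must be positive")
  if (any(b < 0)) stop("semi-minor axis b must be non-negative")
  if (any(b > a)) stop("requires a >= b")
  sqrt(1 - b^2 / a^2)
}

# Signed distance of points from the bisecting line: positive on the
# anterior side (the side the `normal` points into). `points` is n x 2.
halfplane_side <- function(points, origin, normal) {
  (points[, 1L] - origin[1L]) * normal[1L] +
    (points[, 2L] - origin[2L]) * normal[2L]
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# { p : dot(p - origin, normal) >= 0 }.
clip_halfplane <- function(poly, origin, normal) {
  n <- nrow(poly)
  d <- halfplane_side(poly, origin, normal)
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_ <- poly[i, ]; pj <- poly[j, ]
    di <- d[i]; dj <- d[j]
    if (di >= 0) out <- rbind(out, pi_)
    if ((di > 0 && dj < 0) || (di < 0 && dj > 0)) {
      t <- di / (di - dj)
      out <- rbind(out, pi_ + t * (pj - pi_))
    }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Bisect a cell into anterior and posterior regions about the nucleus
#'
#' Cuts the cell polygon with the line through the nucleus centroid
#' perpendicular to the nucleus-to-aggregation-centre direction. The half
#' containing the aggregation direction is the anterior; the opposite half is
#' the posterior.
#'
#' @param cell_polygon `(row, col)` vertex matrix.
#' @param nucleus_centroid `(row, col)` point strictly inside the cell.
#' @param aggregation_point `(row, col)` position of the aggregation centre
#'   (must differ from the nucleus centroid).
#' @return An object of class `roi_pair`: list with `anterior` and
#'   `posterior` polygons and `bisecting_line` (`point`, `direction` of the
#'   cut line, and `anterior_normal`, the unit vector pointing into the
#'   anterior half).
#' @export
bisect_cell <- function(cell_polygon, nucleus_centroid, aggregation_point) {
  if (!point_in_polygon(nucleus_centroid, cell_polygon))
    stop("nucleus centroid must lie strictly inside the cell polygon")
  dvec <- c(aggregation_point[1L] - nucleus_centroid[1L],
            aggregation_point[2L] - nucleus_centroid[2L])
  len <- sqrt(sum(dvec^2))
  if (len < .Machine$double.eps)
    stop("aggregation point coincides with the nucleus centroid")
  normal <- dvec / len                       # points toward the aggregate
  direction <- c(-normal[2L], normal[1L])    # along the cut line
  anterior <- clip_halfplane(cell_polygon, nucleus_centroid, normal)
  posterior <- clip_halfplane(cell_polygon, nucleus_centroid, -normal)
  if (nrow(anterior) < 3L || nrow(posterior) < 3L)
    warning("bisection produced a degenerate half; nucleus may be near the boundary")
  structure(
    list(anterior = anterior, posterior = posterior,
         bisecting_line = list(point = nucleus_centroid,
                               direction = direction,
                               anterior_normal = normal)),
    class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf(
    "<roi_pair> anterior area %.1f px^2, posterior area %.1f px^2\n",
    polygon_area(x$anterior), polygon_area(x$posterior)))
  invisible(x)
}

#' ROI pair for a cell, honouring manually supplied halves
#'
#' When the cell entry (as read by [read_rois()]) already carries
#' `anterior` and `posterior` polygons — the manually segmented path — they
#' take precedence and are used as-is (the bisecting line is reconstructed
#' from the nucleus and aggregation centre when present, or from the two
#' half centroids otherwise). When absent, the cell is bisected
#' programmatically with [bisect_cell()].
#'
#' @param cell a list with `cell`, `nucleus`, `aggregation_center` and
#'   optionally `anterior`/`posterior` entries.
#' @return An `roi_pair`.
#' @export
cell_roi_pair <- function(cell) {
  if (!is.null(cell$anterior) && !is.null(cell$posterior)) {
    if (!is.null(cell$nucleus) && !is.null(cell$aggregation_center)) {
      origin <- cell$nucleus
      normal <- cell$aggregation_center - cell$nucleus
    } else {
      ca <- polygon_centroid(cell$anterior)
      cp <- polygon_centroid(cell$posterior)
      origin <- (ca + cp) / 2
      normal <- ca - cp
    }
    normal <- normal / sqrt(sum(normal^2))
    return(structure(
      list(anterior = cell$anterior, posterior = cell$posterior,
           bisecting_line = list(point = origin,
                                 direction = c(-normal[2L], normal[1L]),
                                 anterior_normal = normal)),
      class = "roi_pair"))
  }
  if (is.null(cell$cell) || is.null(cell$nucleus) ||
      is.null(cell$aggregation_center))
    stop("cell entry needs either anterior+posterior polygons or ",
         "cell+nucleus+aggregation_center")
  bisect_cell(cell$cell, cell$nucleus, cell$aggregation_center)
}

point_in_polygon <- function(point, poly, boundary = FALSE) {
  as.logical(pracma::inpolygon(point[2L], point[1L],
                               poly[, 2L], poly[, 1L],
                               boundary = boundary))
}

#' Rasterise a polygon to a pixel mask
#'
#' A pixel belongs to the mask when its centre lies inside (or on the
#' boundary of) the polygon.
#'
#' @param poly `(row, col)` vertex matrix.
#' @param shape image dimensions `c(rows, cols)`.
#' @return Logical matrix of dimensions `shape`.
#' @export
polygon_mask <- function(poly, shape) {
  rows <- seq_len(shape[1L]); cols <- seq_len(shape[2L])
  # restrict the point-in-polygon test to the bounding box
  rr <- range(poly[, 1L]); cc <- range(poly[, 2L])
  ri <- rows[rows >= floor(rr[1L]) & rows <= ceiling(rr[2L])]
  ci <- cols[cols >= floor(cc[1L]) & cols <= ceiling(cc[2L])]
  m <- matrix(FALSE, shape[1L], shape[2L])
  if (!length(ri) || !length(ci)) return(m)
  g <- expand.grid(row = ri, col = ci)
  inside <- pracma::inpolygon(g$col, g$row, poly[, 2L], poly[, 1L],
                              boundary = TRUE)
  m[cbind(g$row, g$col)] <- inside
  m
}

#' Anterior/posterior pixel masks for an ROI pair
#'
#' Rasterises an [bisect_cell()] `roi_pair` into two disjoint pixel masks
#' whose union is the cell mask. The partition is exact: the cell mask is
#' split by the sign of the half-plane distance of each pixel centre from
#' the bisecting line; boundary ties (distance exactly 0) go to the
#' anterior half.
#'
#' @param rois an `roi_pair`.
#' @param shape image dimensions `c(rows, cols)`.
#' @param cell_mask optional precomputed logical cell mask; when absent the
#'   cell is taken as the convex hull of the two half polygons.
#' @return List of logical matrices `anterior` and `posterior`.
#' @export
roi_pair_masks <- function(rois, shape, cell_mask = NULL) {
  stopifnot(inherits(rois, "roi_pair"))
  if (is.null(cell_mask)) {
    cell_poly <- rbind(rois$anterior, rois$posterior)
    hull <- grDevices::chull(cell_poly[, 2L], cell_poly[, 1L])
    cell_mask <- polygon_mask(cell_poly[hull, , drop = FALSE], shape)
  }
  line <- rois$bisecting_line
  rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  d <- (rows - line$point[1L]) * line$anterior_normal[1L] +
       (cols - line$point[2L]) * line$anterior_normal[2L]
  list(anterior = cell_mask & d >= 0, posterior = cell_mask & d < 0)
}

#' Posterior fraction of total cell intensity
#'
#' The proportion of total within-cell pixel intensity found in the posterior
#' half. Used on the protein channel to compare protein polarity with mRNA
#' polarity.
#'
#' @param image a background-subtracted [fluor_image()].
#' @param rois an [bisect_cell()] `roi_pair`, or a list with logical matrices
#'   `anterior` and `posterior`.
#' @return A number in `[0, 1]`. When the total intensity is zero the
#'   convention 0.5 is returned with a warning.
#' @export
posterior_intensity_fraction <- function(image, rois) {
  image <- as_fluor_image(image)
  masks <- if (inherits(rois, "roi_pair"))
    roi_pair_masks(rois, dim(image$pixels))
  else rois
  s_post <- sum(image$pixels[masks$posterior])
  s_ant <- sum(image$pixels[masks$anterior])
  tot <- s_post + s_ant
  if (tot <= 0) {
    warning("total cell intensity is zero; returning 0.5 by convention")
    return(0.5)
  }
  s_post / tot
}
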