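#' Planar polygon primitives for silhouette geometry
#'
#' Silhouettes are lateral-view polygons in cm, with x running
#' anterior--posterior and y ventral--dorsal. Yaw rotation axes are vertical
#' lines in 3-D; projected onto the lateral plane they become lines, usually
#' the vertical line through the hinge or the centre of mass.
#'
#' @name polygon-utils
#' @keywords internal
NULL

#' Construct a directed planar line (a rotation axis seen in projection)
#'
#' @param point Numeric length-2, a point on the line (cm).
#' @param direction Numeric length-2, the line's direction; need not be unit.
#' @return An object of class `axis_line`.
#' @examples
#' axis_line(c(0, 0), c(0, 1)) # the y axis
#' @export
axis_line <- function(point, direction = c(0, 1)) {
  stopifnot(is.numeric(point), length(point) == 2L, all(is.finite(point)),
            is.numeric(direction), length(direction) == 2L,
            all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) stop("axis direction must be non-zero", call. = FALSE)
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm),
            class = "axis_line")
}

# Signed perpendicular coordinate of points relative to an axis line.
# Positive on the side given by rotating the direction vector -90 degrees.
axis_offset <- function(axis, x, y) {
  d <- axis$direction
  p <- axis$point
  d[1L] * (y - p[2L]) - d[2L] * (x - p[1L])
}

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) {
    stopifnot(all(c("x", "y") %in% names(vertices)))
    vertices <- cbind(vertices$x, vertices$y)
  }
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must be an n x 2 matrix or have x/y columns",
                          call. = FALSE)
  # drop an explicitly closed ring
  n <- nrow(v)
  if (n >= 2L && isTRUE(all(v[1L, ] == v[n, ]))) v <- v[-n, , drop = FALSE]
  v
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param vertices An n x 2 matrix or a data frame with `x`/`y` columns;
#'   the closing edge is implicit.
#' @return Area in cm^2; `polygon_area_signed()` is positive for
#'   counter-clockwise rings.
#' @export
polygon_area <- function(vertices) abs(polygon_area_signed(vertices))

#' @rdname polygon_area
#' @export
polygon_area_signed <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

#' Polygon centroid (area-weighted)
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 centroid; errors on degenerate (zero-area) input.
#' @export
polygon_centroid <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  a <- polygon_area_signed(v)
  if (n < 3L || abs(a) < .Machine$double.eps)
    stop("cannot compute the centroid of a degenerate polygon", call. = FALSE)
  j <- c(2:n, 1L)
  cross <- v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]
  cx <- sum((v[, 1L] + v[j, 1L]) * cross) / (6 * a)
  cy <- sum((v[, 2L] + v[j, 2L]) * cross) / (6 * a)
  c(cx, cy)
}

# Segment-intersection based simplicity check; polygons here have tens of
# vertices at most so the O(n^2) scan is fine.
polygon_is_simple <- function(vertices, tol = 1e-12) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  segs <- cbind(v, v[j, , drop = FALSE])
  proper_cross <- function(a, b, c, d) {
    d1 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d2 <- (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1])
    d3 <- (d[1] - c[1]) * (a[2] - c[2]) - (d[2] - c[2]) * (a[1] - c[1])
    d4 <- (d[1] - c[1]) * (b[2] - c[2]) - (d[2] - c[2]) * (b[1] - c[1])
    (d1 * d2 < -tol) && (d3 * d4 < -tol)
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # skip edges sharing the first vertex
    for (k in js) {
      if (proper_cross(segs[i, 1:2], segs[i, 3:4], segs[k, 1:2], segs[k, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# {p : axis_offset(p) <= c} (keep side). Returns an m x 2 matrix (possibly
# with < 3 rows when the intersection is empty/degenerate).
clip_halfplane <- function(v, offsets, c) {
  n <- nrow(v)
  keep_in <- offsets <= c
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi <- v[i, ]; pj <- v[j, ]
    oi <- offsets[i]; oj <- offsets[j]
    if (keep_in[i]) out <- rbind(out, pi)
    if (keep_in[i] != keep_in[j]) {
      t <- (c - oi) / (oj - oi)
      out <- rbind(out, pi + t * (pj - pi))
    }
  }
  out
}

# Clip polygon to the slab c_lo <= offset <= c_hi (band parallel to the axis).
clip_slab <- function(vertices, axis, c_lo, c_hi) {
  v <- as_vertex_matrix(vertices)
  off <- axis_offset(axis, v[, 1L], v[, 2L])
  # keep offset <= c_hi
  v1 <- clip_halfplane(v, off, c_hi)
  if (nrow(v1) < 3L) return(v1)
  off1 <- axis_offset(axis, v1[, 1L], v1[, 2L])
  # keep offset >= c_lo  ==  -offset <= -c_lo
  v2 <- clip_halfplane(v1, -off1, -c_lo)
  v2
}

#' Chord length of a polygon along a line parallel to an axis
#'
#' Total length of the intersection between the polygon interior and the line
#' at signed perpendicular offset `u` from `axis` (the "height of the
#' morphology at the measurement point" in a hand-measured rectangle
#' decomposition).
#'
#' @inheritParams polygon_area
#' @param axis An [axis_line()].
#' @param u Signed perpendicular offset (cm).
#' @return Chord length in cm.
#' @keywords internal
polygon_chord_length <- function(vertices, axis, u) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  off <- axis_offset(axis, v[, 1L], v[, 2L])
  d <- axis$direction
  ts <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    oi <- off[i]; oj <- off[j]
    if ((oi > u) != (oj > u)) {
      f <- (u - oi) / (oj - oi)
      p <- v[i, ] + f * (v[j, ] - v[i, ])
      # coordinate along the axis direction
      ts <- c(ts, sum((p - axis$point) * d))
    }
  }
  if (length(ts) < 2L) return(0)
  ts <- sort(ts)
  sum(ts[seq(2, length(ts), by = 2)] - ts[seq(1, length(ts) - 1, by = 2)])
}

#' Vectorised even-odd point-in-polygon test
#'
#' @inheritParams polygon_area
#' @param px,py Numeric vectors of query coordinates.
#' @return Logical vector, `TRUE` for points inside the polygon.
#' @export
points_in_polygon <- function(vertices, px, py) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  xj <- v[n, 1L]; yj <- v[n, 2L]
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

#' Rasterize a polygon to a binary mask
#'
#' Pixel (i, j) of the mask (row i counted from the bottom) has its centre at
#' `origin + ((j - 0.5), (i - 0.5)) * resolution`; a pixel is foreground when
#' its centre lies inside the polygon.
#'
#' @inheritParams polygon_area
#' @param resolution Pixel edge length, cm/pixel.
#' @param padding Extra margin around the bounding box, cm.
#' @return A list with `mask` (logical matrix), `origin` (cm) and `resolution`.
#' @export
rasterize_polygon <- function(vertices, resolution, padding = 0) {
  stopifnot(resolution > 0, padding >= 0)
  v <- as_vertex_matrix(vertices)
  origin <- c(min(v[, 1L]) - padding, min(v[, 2L]) - padding)
  nx <- ceiling((max(v[, 1L]) + padding - origin[1L]) / resolution)
  ny <- ceiling((max(v[, 2L]) + padding - origin[2L]) / resolution)
  cx <- origin[1L] + (seq_len(nx) - 0.5) * resolution
  cy <- origin[2L] + (seq_len(ny) - 0.5) * resolution
  px <- rep(cx, times = ny)
  py <- rep(cy, each = nx)
  inside <- points_in_polygon(v, px, py)
  mask <- matrix(inside, nrow = ny, ncol = nx, byrow = TRUE)
  list(mask = mask, origin = origin, resolution = resolution)
}
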