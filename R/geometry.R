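#' Planar polygon utilities
#'
#' All geometry in this package lives in a planar metric frame (coordinates
#' in meters). Polygons are two-column numeric matrices of vertices in order
#' (closing vertex optional). These helpers cover the operations the pipeline
#' needs: signed/absolute area, point-in-polygon membership, and intersection
#' of an arbitrary polygon with a convex polygon (cells, image footprints and
#' areas of interest are rectangles, so every clip in the pipeline has a
#' convex operand).
#'
#' @name geometry
NULL

#' Build an axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in meters.
#' @return A 4x2 matrix of vertices in counter-clockwise order.
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Drop a duplicated closing vertex, coerce to matrix, basic checks.
as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L)
    stop("polygon must be a two-column numeric matrix", call. = FALSE)
  if (nrow(poly) >= 2L && all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(poly))) stop("polygon has non-finite vertices", call. = FALSE)
  poly
}

#' Polygon area (shoelace formula)
#'
#' @param poly two-column vertex matrix.
#' @return Absolute enclosed area in square meters.
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(nrow(p), seq_len(nrow(p) - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Validate a polygon
#'
#' Checks vertex count, finiteness, non-zero area, and absence of
#' self-intersection (pairwise proper segment crossings).
#'
#' @param poly two-column vertex matrix.
#' @return `TRUE` invisibly, or an error describing the defect.
#' @export
validate_polygon <- function(poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ]))
        stop(sprintf("polygon self-intersects (edges %d and %d)", i, j),
             call. = FALSE)
    }
  }
  if (polygon_area(p) <= 0) stop("polygon has zero area", call. = FALSE)
  invisible(TRUE)
}

# Proper crossing test (shared endpoints / collinear touches not flagged).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Point-in-polygon test (winding number)
#'
#' Vectorized over points. Points on the polygon boundary count as inside,
#' the convention used when removing detections that fall in exclusion
#' polygons.
#'
#' @param x,y point coordinates (equal-length numeric vectors).
#' @param poly two-column vertex matrix.
#' @return Logical vector, `TRUE` where the point is inside or on the boundary.
#' @export
points_in_polygon <- function(x, y, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  px <- p[, 1L]; py <- p[, 2L]
  qx <- px[c(2:n, 1L)]; qy <- py[c(2:n, 1L)]
  wn <- integer(length(x))
  on_edge <- logical(length(x))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    # boundary: collinear and within the segment's bounding box
    on_edge <- on_edge | (cr == 0 &
                            x >= min(x1, x2) & x <= max(x1, x2) &
                            y >= min(y1, y2) & y <= max(y1, y2))
    wn <- wn + ((y1 <= y) & (y2 > y) & (cr > 0)) -
      ((y1 > y) & (y2 <= y) & (cr < 0))
  }
  on_edge | wn != 0L
}

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' @param subject two-column vertex matrix (any simple polygon).
#' @param clip two-column vertex matrix; must be convex.
#' @return Vertex matrix of the intersection, or `NULL` when empty.
#' @export
clip_polygon_convex <- function(subject, clip) {
  s <- as_polygon(subject)
  cl <- as_polygon(clip)
  # orient clip counter-clockwise
  if (signed_area(cl) < 0) cl <- cl[rev(seq_len(nrow(cl))), , drop = FALSE]
  out <- s
  nc <- nrow(cl)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- cl[e, ]; b <- cl[if (e == nc) 1L else e + 1L, ]
    out <- clip_halfplane(out, a, b)
  }
  if (is.null(out) || nrow(out) < 3L || polygon_area_safe(out) <= 0) return(NULL)
  out
}

signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(nrow(p), seq_len(nrow(p) - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area_safe <- function(p) {
  if (is.null(p) || nrow(p) < 3L) return(0)
  abs(signed_area(p))
}

# keep the side left of directed edge a->b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  side <- (b[1] - a[1]) * (poly[, 2L] - a[2]) - (b[2] - a[2]) * (poly[, 1L] - a[1])
  res <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i]; cj <- side[j]
    if (ci >= 0) res <- rbind(res, poly[i, ])
    if ((ci > 0 && cj < 0) || (ci < 0 && cj > 0)) {
      t <- ci / (ci - cj)
      res <- rbind(res, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(res) == 0L) NULL else res
}

#' Area of intersection between a polygon and a convex polygon
#'
#' @param poly subject polygon (vertex matrix).
#' @param clip convex polygon (vertex matrix).
#' @return Intersection area in square meters (0 when disjoint).
#' @export
polygon_intersection_area <- function(poly, clip) {
  polygon_area_safe(clip_polygon_convex(poly, clip))
}

# Fast rectangle-overlap area for two axis-aligned rectangles given as
# (xmin, ymin, xmax, ymax); used by the raster aggregation hot path.
rect_overlap_area <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0)) *
    pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
}

# Bounding box of a polygon as c(xmin, ymin, xmax, ymax).
poly_bbox <- function(poly) {
  p <- as_polygon(poly)
  c(min(p[, 1L]), min(p[, 2L]), max(p[, 1L]), max(p[, 2L]))
}

# TRUE when the polygon is an axis-aligned rectangle (fast paths).
is_axis_rect <- function(poly) {
  p <- as_polygon(poly)
  if (nrow(p) != 4L) return(FALSE)
  xs <- sort(unique(p[, 1L])); ys <- sort(unique(p[, 2L]))
  length(xs) == 2L && length(ys) == 2L &&
    isTRUE(all.equal(polygon_area(p), diff(xs) * diff(ys)))
}

# Uniform points inside a polygon by rejection from its bounding box.
sample_points_in_polygon <- function(n, poly, max_iter = 1000L) {
  if (n <= 0L) return(cbind(x = numeric(0), y = numeric(0)))
  bb <- poly_bbox(poly)
  out <- matrix(numeric(0), ncol = 2L)
  it <- 0L
  while (nrow(out) < n && it < max_iter) {
    m <- max(2L * (n - nrow(out)), 8L)
    x <- stats::runif(m, bb[1], bb[3])
    y <- stats::runif(m, bb[2], bb[4])
    keep <- points_in_polygon(x, y, poly)
    out <- rbind(out, cbind(x[keep], y[keep]))
    it <- it + 1L
  }
  if (nrow(out) < n)
    stop("rejection sampling failed; polygon area may be degenerate", call. = FALSE)
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Minimum distance from a point to the polygon boundary.
dist_to_boundary <- function(x, y, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  q <- p[c(2:n, 1L), , drop = FALSE]
  dmin <- rep(Inf, length(x))
  for (e in seq_len(n)) {
    ex <- q[e, 1L] - p[e, 1L]; ey <- q[e, 2L] - p[e, 2L]
    len2 <- ex^2 + ey^2
    t <- ((x - p[e, 1L]) * ex + (y - p[e, 2L]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    dx <- x - (p[e, 1L] + t * ex); dy <- y - (p[e, 2L] + t * ey)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}
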