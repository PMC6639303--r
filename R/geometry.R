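# Planar geometry helpers shared by the synthetic generators, ROI handling
# and the injury-axis computation. All coordinates are 1-based pixel-centre
# (row, col) pairs; polygons are n x 2 matrices of vertices in order.

#' Ellipse specification
#'
#' Describes an elliptical cell footprint by centre, semi-axes and rotation.
#' Used both by the synthetic generators (analytic masks) and to build
#' polygonal ROIs.
#'
#' @param center Numeric length-2, (row, col) centre in pixels.
#' @param semiaxes Numeric length-2, semi-axis lengths in pixels; the first
#'   entry is the major axis before rotation.
#' @param angle Rotation of the first semi-axis, radians, counter-clockwise
#'   in the (row, col) plane.
#' @return An object of class `ellipse_spec`.
#' @export
ellipse_spec <- function(center, semiaxes, angle = 0) {
  stopifnot(length(center) == 2, length(semiaxes) == 2, length(angle) == 1)
  if (any(!is.finite(c(center, semiaxes, angle))) || any(semiaxes <= 0))
    stop("degenerate ellipse geometry: semi-axes must be positive and finite")
  structure(list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 angle = as.numeric(angle)),
            class = "ellipse_spec")
}

# rotated (u, v) coordinates of pixel-centre grid relative to ellipse centre
ellipse_uv <- function(spec, dim) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dr <- rr - spec$center[1]
  dc <- cc - spec$center[2]
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  list(u = dr * ca + dc * sa, v = -dr * sa + dc * ca)
}

#' Logical pixel mask of an ellipse
#'
#' @param spec An [ellipse_spec()].
#' @param dim Image dimensions c(rows, cols).
#' @return Logical rows x cols matrix, TRUE for pixel centres inside.
#' @export
ellipse_mask <- function(spec, dim) {
  uv <- ellipse_uv(spec, dim)
  (uv$u / spec$semiaxes[1])^2 + (uv$v / spec$semiaxes[2])^2 <= 1
}

#' Point on an ellipse boundary
#'
#' @param spec An [ellipse_spec()].
#' @param theta Boundary parameter in radians (0 = tip of the first
#'   semi-axis).
#' @return (row, col) coordinate.
#' @export
ellipse_point <- function(spec, theta) {
  u <- spec$semiaxes[1] * cos(theta)
  v <- spec$semiaxes[2] * sin(theta)
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  c(spec$center[1] + u * ca - v * sa, spec$center[2] + u * sa + v * ca)
}

#' Polygon inscribed in an ellipse
#'
#' @param spec An [ellipse_spec()].
#' @param n Number of vertices.
#' @return n x 2 matrix of (row, col) vertices.
#' @export
ellipse_polygon <- function(spec, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  t(vapply(th, function(x) ellipse_point(spec, x), numeric(2)))
}

#' Test points against a polygon (even-odd rule)
#'
#' Vectorised ray-casting; points exactly on an edge may fall on either
#' side, so callers that must accept boundary points combine this with a
#' distance-to-boundary tolerance.
#'
#' @param points m x 2 matrix of (row, col) coordinates.
#' @param poly n x 2 polygon vertex matrix.
#' @return Logical vector of length m.
#' @export
point_in_polygon <- function(points, poly) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(poly)
  inside <- logical(nrow(points))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if (yi != yj) {
      cross <- ((yi > points[, 1]) != (yj > points[, 1])) &
        (points[, 2] < (xj - xi) * (points[, 1] - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Rasterise a polygon to a logical mask
#'
#' @param poly n x 2 polygon vertex matrix.
#' @param dim Image dimensions c(rows, cols).
#' @return Logical rows x cols matrix of pixel centres inside the polygon.
#' @export
polygon_mask <- function(poly, dim) {
  pts <- cbind(rep(seq_len(dim[1]), dim[2]), rep(seq_len(dim[2]), each = dim[1]))
  matrix(point_in_polygon(pts, poly), dim[1], dim[2])
}

# signed orientation of triple (a, b, c); 0 when collinear
.orient <- function(a, b, c) {
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (abs(v) < 1e-12) 0 else sign(v)
}

.on_segment <- function(a, b, p) {
  p[1] <= max(a[1], b[1]) + 1e-12 && p[1] >= min(a[1], b[1]) - 1e-12 &&
    p[2] <= max(a[2], b[2]) + 1e-12 && p[2] >= min(a[2], b[2]) - 1e-12
}

# TRUE when segments p1-p2 and p3-p4 intersect (including collinear overlap)
segments_intersect <- function(p1, p2, p3, p4) {
  o1 <- .orient(p1, p2, p3); o2 <- .orient(p1, p2, p4)
  o3 <- .orient(p3, p4, p1); o4 <- .orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && .on_segment(p1, p2, p3)) ||
    (o2 == 0 && .on_segment(p1, p2, p4)) ||
    (o3 == 0 && .on_segment(p3, p4, p1)) ||
    (o4 == 0 && .on_segment(p3, p4, p2))
}

#' Check that a polygon is simple (non-self-intersecting)
#'
#' @param poly n x 2 polygon vertex matrix.
#' @return TRUE, or FALSE with attribute `edges` naming an offending pair of
#'   edge indices.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next               # shared vertex with closing edge
      a1 <- poly[i, ]; a2 <- poly[i %% n + 1, ]
      b1 <- poly[j, ]; b2 <- poly[j %% n + 1, ]
      if (segments_intersect(a1, a2, b1, b2)) {
        out <- FALSE
        attr(out, "edges") <- c(i, j)
        return(out)
      }
    }
  }
  TRUE
}

#' Do two polygons overlap?
#'
#' @param a,b Polygon vertex matrices.
#' @return TRUE when they share any area or touch.
#' @export
polygons_overlap <- function(a, b) {
  if (any(point_in_polygon(a, b)) || any(point_in_polygon(b, a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_intersect(a[i, ], a[i %% na + 1, ],
                             b[j, ], b[j %% nb + 1, ])) return(TRUE)
    }
  }
  FALSE
}

# Euclidean distance from point p to segment a-b
.point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

# minimum distance from point to polygon boundary
polygon_boundary_dist <- function(p, poly) {
  n <- nrow(poly)
  min(vapply(seq_len(n), function(i) {
    .point_segment_dist(p, poly[i, ], poly[i %% n + 1, ])
  }, numeric(1)))
}

#' Rasterise a straight segment to an ordered pixel path
#'
#' @param p0,p1 (row, col) endpoints.
#' @return m x 2 integer matrix of pixel coordinates from p0 to p1 with no
#'   consecutive duplicates.
#' @export
rasterize_segment <- function(p0, p1) {
  n <- max(1, ceiling(max(abs(p1 - p0))))
  tt <- seq(0, 1, length.out = n + 1)
  pts <- round(cbind(p0[1] + tt * (p1[1] - p0[1]),
                     p0[2] + tt * (p1[2] - p0[2])))
  pts[!duplicated(pts), , drop = FALSE]
}
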