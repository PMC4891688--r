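# Planar geometry for pore annotations: polylines, ROI polygons, point-to-edge
# distances and the projection (foreshortening) arithmetic.  All coordinates
# are in nm, y increasing downward (image convention); an image pixel
# (row, col), 1-based, has its center at ((col - 0.5) * px, (row - 0.5) * px).

#' Polyline in physical (nm) coordinates
#'
#' @param vertices two-column matrix (or coercible) of x, y coordinates in nm.
#' @param closed logical; a closed polyline includes the segment joining the
#'   last vertex back to the first.  A closed input whose last vertex repeats
#'   the first is normalized by dropping the duplicate.
#' @return an object of class `goldrim_polyline`.
#' @export
polyline <- function(vertices, closed = FALSE) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L || anyNA(v) || any(!is.finite(v)))
    stop_validation("vertices", "must be a finite numeric n x 2 matrix")
  if (isTRUE(closed) && nrow(v) >= 2L &&
      all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 2L || (closed && n < 3L))
    stop_validation("vertices", "need >= 2 vertices (>= 3 if closed)")
  d <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-n, , drop = FALSE])^2))
  if (any(d == 0) || (closed && all(v[1L, ] == v[n, ])))
    stop_validation("vertices", "consecutive vertices must be distinct")
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(vertices = v, closed = isTRUE(closed)),
            class = "goldrim_polyline")
}

as_polyline <- function(x, closed = FALSE) {
  if (inherits(x, "goldrim_polyline")) x else polyline(x, closed = closed)
}

#' Total length of a polyline
#'
#' Sum of segment lengths, including the closing segment for closed polylines.
#'
#' @param p a [polyline()] (or a vertex matrix, treated as open).
#' @return length in nm.
#' @export
polyline_length <- function(p) {
  p <- as_polyline(p)
  v <- p$vertices
  if (p$closed) v <- rbind(v, v[1L, ])
  n <- nrow(v)
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-n, , drop = FALSE])^2)))
}

# TRUE when any two non-adjacent segments of the closed polygon intersect.
segments_self_intersect <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    j <- if (i == 1L) (i + 2L):(n - 1L) else (i + 2L):n
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))) return(TRUE)
  }
  FALSE
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Region-of-interest polygon
#'
#' A simple (non-self-intersecting) closed polygon with a region label, used
#' to accumulate particle statistics inside pore and non-pore regions.
#'
#' @param vertices closed boundary: a vertex matrix or closed [polyline()].
#' @param label `"pore"` or `"non_pore"`.
#' @return an object of class `goldrim_roi`.
#' @export
roi_polygon <- function(vertices, label = c("pore", "non_pore")) {
  label <- match.arg(label)
  p <- if (inherits(vertices, "goldrim_polyline")) {
    if (!vertices$closed) stop_validation("vertices", "boundary must be closed")
    vertices
  } else polyline(vertices, closed = TRUE)
  v <- p$vertices
  if (segments_self_intersect(v))
    stop_validation("vertices", "polygon is self-intersecting")
  if (shoelace_area(v) <= 0)
    stop_validation("vertices", "polygon must have positive area")
  structure(list(boundary = p, label = label), class = "goldrim_roi")
}

roi_vertices <- function(p) {
  if (inherits(p, "goldrim_roi")) return(p$boundary$vertices)
  pl <- as_polyline(p, closed = TRUE)
  if (!pl$closed) stop_validation("p", "polygon boundary must be closed")
  pl$vertices
}

#' Polygon area (shoelace)
#'
#' Absolute (orientation-independent) area of a simple polygon.
#'
#' @param p an [roi_polygon()], closed [polyline()], or vertex matrix.
#' @return area in nm^2.
#' @export
polygon_area <- function(p) {
  v <- roi_vertices(p)
  if (!inherits(p, "goldrim_roi") && segments_self_intersect(v))
    stop_validation("p", "polygon is self-intersecting")
  shoelace_area(v)
}

# Even-odd membership for a matrix of points; boundary points are inside.
points_in_polygon <- function(pts, p, eps = NULL) {
  v <- roi_vertices(p)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  if (is.null(eps)) eps <- 1e-9 * max(1, abs(v))
  n <- nrow(v)
  jx <- c(2:n, 1L)
  inside <- rep(FALSE, nrow(pts))
  on_edge <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[jx[i], 1]; y2 <- v[jx[i], 2]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xi <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- inside[crosses]
      hit <- xor(hit, x[crosses] < xi)
      inside[crosses] <- hit
    }
    on_edge <- on_edge | (point_segment_distance(x, y, x1, y1, x2, y2) <= eps)
  }
  inside | on_edge
}

#' Point-in-polygon test (even-odd rule)
#'
#' Boundary points count as inside: particles whose centroid falls exactly on
#' a drawn region boundary are attributed to that region.
#'
#' @param pt numeric length-2 point, or an n x 2 matrix of points.
#' @param p an [roi_polygon()] (or closed polyline / vertex matrix).
#' @return logical vector of membership.
#' @export
point_in_polygon <- function(pt, p) {
  points_in_polygon(pt, p)
}

# Distance from points (x, y) to segment (x1, y1)-(x2, y2); vectorized over
# the points.
point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / l2))
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

#' Shortest distance from point(s) to a polyline
#'
#' Minimum Euclidean distance from each query point to any segment of the
#' polyline; the closest point may lie in a segment interior or at a vertex.
#' This is the measurement behind particle-to-pore-edge distances.
#'
#' @param pt length-2 point or n x 2 matrix of points (nm).
#' @param edge a [polyline()] (or vertex matrix, treated as open).
#' @return numeric vector of distances in nm.
#' @export
min_edge_distance <- function(pt, edge) {
  edge <- as_polyline(edge)
  v <- edge$vertices
  if (edge$closed) v <- rbind(v, v[1L, ])
  pts <- matrix(as.numeric(pt), ncol = 2L)
  x <- pts[, 1]; y <- pts[, 2]
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(v) - 1L)) {
    best <- pmin(best, point_segment_distance(
      x, y, v[i, 1], v[i, 2], v[i + 1L, 1], v[i + 1L, 2]))
  }
  best
}

#' Pore annotation: edge, flanking boundaries, orientation class
#'
#' Bundles the traced pore edge with the outer and inner boundaries flanking
#' the rim (between which particle areas are accumulated).  The measured pore
#' perimeter convention is the average of the outer and inner boundary
#' lengths; see [pore_perimeter()].
#'
#' @param edge pore-edge [polyline()] (usually closed).
#' @param outer,inner closed polylines flanking the rim; every `inner` vertex
#'   must lie inside `outer`.
#' @param orientation_class `"en_face"`, `"oblique"`, `"edge_on"`, or `NULL`
#'   to classify automatically from [circularity()] of the edge.
#' @param en_face_cutoff circularity at or above which a pore is called
#'   en face (default 0.9); below `edge_on_cutoff` (default 0.2) it is called
#'   edge-on.
#' @return an object of class `goldrim_annotation`.
#' @export
pore_annotation <- function(edge, outer, inner, orientation_class = NULL,
                            en_face_cutoff = 0.9, edge_on_cutoff = 0.2) {
  edge <- as_polyline(edge, closed = TRUE)
  outer <- as_polyline(outer, closed = TRUE)
  inner <- as_polyline(inner, closed = TRUE)
  if (!all(points_in_polygon(inner$vertices, outer$vertices)))
    stop_validation("inner", "all inner vertices must lie within the outer boundary")
  if (is.null(orientation_class)) {
    orientation_class <- classify_orientation(
      circularity(edge), en_face_cutoff, edge_on_cutoff)
  }
  orientation_class <- match.arg(orientation_class,
                                 c("en_face", "oblique", "edge_on"))
  structure(list(edge = edge, outer = outer, inner = inner,
                 orientation_class = orientation_class),
            class = "goldrim_annotation")
}

#' Measured pore perimeter
#'
#' The pore perimeter is estimated as the average of the lengths of the outer
#' and inner boundaries flanking the rim.
#'
#' @param ann a [pore_annotation()].
#' @return perimeter in nm.
#' @export
pore_perimeter <- function(ann) {
  if (!inherits(ann, "goldrim_annotation"))
    stop_validation("ann", "must be a pore_annotation")
  (polyline_length(ann$outer) + polyline_length(ann$inner)) / 2
}

#' Projected perimeter of a tilted circular pore
#'
#' A circular pore of diameter `d` viewed at angle `tilt` between its axis and
#' the viewing axis projects to an ellipse with semiaxes d/2 and
#' (d/2)*cos(tilt).  The perimeter is evaluated by numerical quadrature of the
#' arc-length integral, so it equals pi*d exactly at tilt 0 and 2*d at
#' tilt pi/2 (the pore seen edge-on).
#'
#' @param d pore diameter in nm.
#' @param tilt angle in radians, in `[0, pi/2]`.
#' @return projected perimeter in nm.
#' @export
projected_perimeter <- function(d, tilt) {
  check_scalar(d, "d"); check_scalar(tilt, "tilt")
  if (d <= 0) stop_validation("d", "must be > 0")
  if (tilt < 0 || tilt > pi / 2)
    stop_validation("tilt", "must lie in [0, pi/2]")
  a <- d / 2
  b <- a * cos(tilt)
  4 * integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                0, pi / 2, rel.tol = 1e-12, abs.tol = 0)$value
}

#' Worst-case fractional perimeter foreshortening
#'
#' The supremum over tilt of (pi*d - projected perimeter) / (pi*d): the
#' projected perimeter of a circle of diameter d shrinks from pi*d (en face)
#' to 2*d (edge-on), so the maximum fractional error of a perimeter measured
#' in projection is (pi - 2)/pi, approximately 36%.
#'
#' @return the fraction (pi - 2)/pi.
#' @export
perimeter_error_bound <- function() (pi - 2) / pi

#' Circularity of a closed outline
#'
#' Minor/major axis ratio of the best-fit (second-moment) ellipse of the
#' outline vertices, in (0, 1].  For the projection of a tilted circle traced
#' at uniform parametric spacing this equals cos(tilt) exactly, so it is used
#' to select pores oriented roughly en face.
#'
#' @param x a closed [polyline()], vertex matrix, or [pore_annotation()]
#'   (whose edge is used); at least 5 vertices.
#' @return axis ratio in (0, 1].
#' @export
circularity <- function(x) {
  if (inherits(x, "goldrim_annotation")) x <- x$edge
  v <- if (inherits(x, "goldrim_polyline")) x$vertices else as.matrix(x)
  if (nrow(v) < 5L)
    stop_validation("x", "need >= 5 vertices to fit an ellipse")
  v <- sweep(v, 2L, colMeans(v))
  ev <- eigen(crossprod(v) / nrow(v), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1L] == 0) stop_validation("x", "degenerate outline")
  sqrt(ev[2L] / ev[1L])
}

#' Orientation class from circularity
#'
#' @param circ circularity in (0, 1].
#' @param en_face_cutoff,edge_on_cutoff class boundaries (defaults 0.9, 0.2).
#' @return `"en_face"`, `"oblique"`, or `"edge_on"`.
#' @export
classify_orientation <- function(circ, en_face_cutoff = 0.9,
                                 edge_on_cutoff = 0.2) {
  if (circ >= en_face_cutoff) "en_face"
  else if (circ <= edge_on_cutoff) "edge_on"
  else "oblique"
}

# Regular closed polygon approximating a circle (test + annotation helper).
circle_polyline <- function(center, r, n = 720L, phase = 0) {
  t <- phase + 2 * pi * (seq_len(n) - 1L) / n
  polyline(cbind(center[1] + r * cos(t), center[2] + r * sin(t)), closed = TRUE)
}
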