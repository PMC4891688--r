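# Independent oracles used to freeze expected values.  Each deliberately
# avoids the code path it checks.

# Regular n-gon approximating a circle.
ngon <- function(center, r, n = 720L, phase = 0) {
  t <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + r * cos(t), center[2] + r * sin(t))
}

# Two-sided Mann-Whitney p by brute-force enumeration of group labelings,
# with U accumulated from pairwise comparisons (not ranks).
oracle_mw_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x); n <- length(v)
  u_of <- function(idx) {
    a <- v[idx]; b <- v[-idx]
    sum(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  us <- apply(utils::combn(n, n1), 2L, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Min distance from a point to a polyline by dense sampling along segments.
oracle_min_dist <- function(pt, verts, closed = FALSE, n_per_seg = 1e5L) {
  v <- verts
  if (closed) v <- rbind(v, v[1L, ])
  best <- Inf
  for (i in seq_len(nrow(v) - 1L)) {
    t <- seq(0, 1, length.out = n_per_seg)
    sx <- v[i, 1] + t * (v[i + 1L, 1] - v[i, 1])
    sy <- v[i, 2] + t * (v[i + 1L, 2] - v[i, 2])
    best <- min(best, sqrt(min((pt[1] - sx)^2 + (pt[2] - sy)^2)))
  }
  best
}

# Ellipse perimeter by midpoint Riemann sum of the arc-length integrand.
oracle_ellipse_perimeter <- function(a, b, n = 2e5L) {
  t <- (seq_len(n) - 0.5) * 2 * pi / n
  sum(sqrt((a * sin(t))^2 + (b * cos(t))^2)) * 2 * pi / n
}

# Pixel-center rasterization: number of pixel centers inside a disk.
oracle_raster_count <- function(cx, cy, r, px) {
  cols <- floor((cx - r) / px):ceiling((cx + r) / px + 1)
  rows <- floor((cy - r) / px):ceiling((cy + r) / px + 1)
  xs <- (cols - 0.5) * px
  ys <- (rows - 0.5) * px
  sum(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= r^2)
}

# Even-odd membership by counting crossings of a ray cast in an oblique,
# vertex-avoiding direction (independent of the horizontal-ray code path).
oracle_in_poly <- function(pts, verts) {
  n <- nrow(verts)
  jx <- c(2:n, 1L)
  dir <- c(cos(0.1234567), sin(0.1234567))
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    crossings <- 0L
    for (i in seq_len(n)) {
      a <- verts[i, ]; b <- verts[jx[i], ]
      e <- b - a
      den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
      if (abs(den) < 1e-14) next
      w <- a - p
      t <- (w[1] * (-e[2]) - w[2] * (-e[1])) / den
      s <- (dir[1] * w[2] - dir[2] * w[1]) / den
      if (t > 0 && s >= 0 && s < 1) crossings <- crossings + 1L
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Scene with hand-placed particles (bypasses the stochastic placement).
scene_with_particles <- function(radius = 50, half_angle = 0.6, tilt = 0,
                                 azimuth = 0, xyz = NULL, diameter = 1.3,
                                 class = "rim", thickness = 5) {
  s <- make_scene(vesicle_model(radius, thickness, half_angle),
                  orientation(tilt, azimuth))
  if (!is.null(xyz)) {
    s$particles <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              diameter = diameter, class = class,
                              stringsAsFactors = FALSE)
  }
  s
}

# Points on the rim circle (vesicle frame) at given rim angles.
rim_points <- function(radius, half_angle, phi) {
  cbind(radius * sin(half_angle) * cos(phi),
        radius * sin(half_angle) * sin(phi),
        radius * cos(half_angle))
}
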