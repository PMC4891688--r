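# Synthetic scene model: a spherical vesicle bearing one circular pore whose
# rim is decorated with gold particles at a fixed linear density, viewed at an
# arbitrary tilt and projected orthographically (transmission imaging: no
# occlusion).  All lengths are nm, angles rad.
#
# Vesicle frame: pore axis along +z, rim circle at polar angle
# `pore_half_angle`.  Lab frame: viewing axis +z, projection drops z;
# lab = Rz(azimuth) %*% Ry(tilt) %*% vesicle.

#' Vesicle with a circular pore
#'
#' @param radius outer vesicle radius (nm).
#' @param membrane_thickness shell thickness (nm), in (0, radius).
#' @param pore_half_angle polar half-angle of the pore rim circle about the
#'   pore axis (rad), in (0, pi/2).  The pore diameter is
#'   `d = 2 * radius * sin(pore_half_angle)`.
#' @return an object of class `goldrim_vesicle`.
#' @export
vesicle_model <- function(radius, membrane_thickness = 5, pore_half_angle) {
  check_scalar(radius, "radius")
  check_scalar(membrane_thickness, "membrane_thickness")
  check_scalar(pore_half_angle, "pore_half_angle")
  if (radius <= 0) stop_validation("radius", "must be > 0")
  if (membrane_thickness <= 0 || membrane_thickness >= radius)
    stop_validation("membrane_thickness", "must lie in (0, radius)")
  if (pore_half_angle <= 0 || pore_half_angle >= pi / 2)
    stop_validation("pore_half_angle", "must lie in (0, pi/2)")
  structure(list(radius = radius,
                 membrane_thickness = membrane_thickness,
                 pore_half_angle = pore_half_angle),
            class = "goldrim_vesicle")
}

#' Viewing orientation
#'
#' @param tilt angle between the pore axis and the viewing axis (rad), in
#'   `[0, pi/2]`.  `tilt = pi/2` is accepted and flagged edge-on.
#' @param azimuth rotation about the viewing axis (rad).
#' @return an object of class `goldrim_orientation`.
#' @export
orientation <- function(tilt = 0, azimuth = 0) {
  check_scalar(tilt, "tilt"); check_scalar(azimuth, "azimuth")
  if (tilt < 0 || tilt > pi / 2)
    stop_validation("tilt", "must lie in [0, pi/2]")
  structure(list(tilt = tilt, azimuth = azimuth,
                 edge_on = tilt >= pi / 2 - 1e-12),
            class = "goldrim_orientation")
}

#' Particle placement parameters
#'
#' @param linear_density lambda, rim particles per nm of rim circumference.
#' @param labeling_efficiency p, fraction of rim sites carrying a gold
#'   particle (thins lambda), in `[0, 1]`.
#' @param rim_jitter_sd Gaussian sd of radial (cross-rim) displacement (nm);
#'   the jitter is truncated at 3 sd so ground-truth rim particles stay within
#'   `3 * rim_jitter_sd + diameter` of the rim.
#' @param background_area_density nonspecific particles per nm^2 of membrane
#'   surface outside the pore and rim-exclusion band.
#' @param rim_exclusion width (nm) of the band around the rim from which
#'   background particles are excluded, keeping ground-truth classes
#'   separable.
#' @param particle_diameter_mean,particle_diameter_sd nanogold diameter
#'   distribution (nm); the default 1.3 +/- 0.14 matches commercial nanogold.
#'   Diameters are truncated at 4 sd.
#' @param seed integer seed making placement deterministic, or `NULL` to draw
#'   from the current RNG stream.
#' @param count_mode `"poisson"` (stochastic recruitment) or `"fixed"`
#'   (rounded expected count, for deterministic tests).
#' @return an object of class `goldrim_placement`.
#' @export
placement_params <- function(linear_density = 1 / 6, labeling_efficiency = 1,
                             rim_jitter_sd = 0.3,
                             background_area_density = 0,
                             rim_exclusion = 5,
                             particle_diameter_mean = 1.3,
                             particle_diameter_sd = 0.14,
                             seed = NULL,
                             count_mode = c("poisson", "fixed")) {
  count_mode <- match.arg(count_mode)
  for (f in c("linear_density", "labeling_efficiency", "rim_jitter_sd",
              "background_area_density", "rim_exclusion",
              "particle_diameter_mean", "particle_diameter_sd"))
    check_scalar(get(f), f)
  if (linear_density < 0) stop_validation("linear_density", "must be >= 0")
  if (labeling_efficiency < 0 || labeling_efficiency > 1)
    stop_validation("labeling_efficiency", "must lie in [0, 1]")
  if (rim_jitter_sd < 0) stop_validation("rim_jitter_sd", "must be >= 0")
  if (background_area_density < 0)
    stop_validation("background_area_density", "must be >= 0")
  if (rim_exclusion < 0) stop_validation("rim_exclusion", "must be >= 0")
  if (particle_diameter_mean <= 0)
    stop_validation("particle_diameter_mean", "must be > 0")
  if (particle_diameter_sd < 0)
    stop_validation("particle_diameter_sd", "must be >= 0")
  structure(list(linear_density = linear_density,
                 labeling_efficiency = labeling_efficiency,
                 rim_jitter_sd = rim_jitter_sd,
                 background_area_density = background_area_density,
                 rim_exclusion = rim_exclusion,
                 particle_diameter_mean = particle_diameter_mean,
                 particle_diameter_sd = particle_diameter_sd,
                 seed = seed, count_mode = count_mode),
            class = "goldrim_placement")
}

# alias so default arguments can reach the constructor even when an argument
# shadows the name
new_orientation <- orientation

empty_particles <- function() {
  data.frame(x = numeric(), y = numeric(), z = numeric(),
             diameter = numeric(), class = character(),
             stringsAsFactors = FALSE)
}

#' Construct an empty scene
#'
#' @param vesicle a [vesicle_model()].
#' @param orientation an [orientation()].
#' @return an object of class `goldrim_scene`; the rim circle is defined
#'   analytically (`rim_radius`, `pore_diameter`, `rim_circumference`).
#' @export
make_scene <- function(vesicle, orientation = new_orientation()) {
  if (!inherits(vesicle, "goldrim_vesicle"))
    stop_validation("vesicle", "must be a vesicle_model")
  if (!inherits(orientation, "goldrim_orientation"))
    stop_validation("orientation", "must be an orientation")
  R <- vesicle$radius
  a <- vesicle$pore_half_angle
  structure(list(vesicle = vesicle, orientation = orientation,
                 rim_radius = R * sin(a),
                 pore_diameter = 2 * R * sin(a),
                 rim_circumference = 2 * pi * R * sin(a),
                 particles = empty_particles()),
            class = "goldrim_scene")
}

rotation_matrix <- function(o) {
  ct <- cos(o$tilt); st <- sin(o$tilt)
  ca <- cos(o$azimuth); sa <- sin(o$azimuth)
  ry <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3L, 3L, byrow = TRUE)
  rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  rz %*% ry
}

sample_diameters <- function(n, params) {
  d <- rnorm_trunc(n, params$particle_diameter_mean,
                   params$particle_diameter_sd, k = 4)
  pmax(d, 1e-6)
}

#' Place gold particles along the pore rim
#'
#' The number of particles is Poisson with mean
#' `linear_density * labeling_efficiency * rim_circumference` (or that mean
#' rounded, in fixed-count mode).  Rim angles are uniform; each particle is
#' displaced across the rim by a radial Gaussian jitter (sd `rim_jitter_sd`,
#' truncated at 3 sd) applied to the polar angle, staying on the vesicle
#' sphere.  Draw order under the seed: count, rim angles, jitter, diameters.
#'
#' @param scene a [make_scene()] result.
#' @param params a [placement_params()].
#' @return the scene with rim-class particles appended (vesicle frame).
#' @export
place_rim_particles <- function(scene, params) {
  stopifnot(inherits(scene, "goldrim_scene"),
            inherits(params, "goldrim_placement"))
  C <- scene$rim_circumference
  if (params$linear_density * C >= 1e6)
    stop_goldrim("goldrim_parameter_error",
                 "linear_density * circumference exceeds the sanity cap (1e6)")
  mu <- params$linear_density * params$labeling_efficiency * C
  R <- scene$vesicle$radius
  alpha <- scene$vesicle$pore_half_angle
  pts <- with_seed(params$seed, {
    n <- if (params$count_mode == "fixed") as.integer(round(mu)) else rpois(1L, mu)
    phi <- runif(n, 0, 2 * pi)
    delta <- rnorm_trunc(n, 0, params$rim_jitter_sd, k = 3)
    dia <- sample_diameters(n, params)
    theta <- pmin(pi - 1e-9, pmax(1e-9, alpha + delta / R))
    data.frame(x = R * sin(theta) * cos(phi),
               y = R * sin(theta) * sin(phi),
               z = R * cos(theta),
               diameter = dia, class = rep("rim", n),
               stringsAsFactors = FALSE)
  })
  scene$particles <- rbind(scene$particles, pts)
  scene
}

#' Place nonspecific background particles on the membrane
#'
#' Particles are uniform on the vesicle sphere excluding the pore cap and the
#' rim-exclusion band: polar angles are restricted to
#' `>= pore_half_angle + rim_exclusion / radius`.  The count is Poisson with
#' mean `background_area_density` times the eligible spherical area
#' `2 * pi * R^2 * (1 + cos(beta))`.
#'
#' @inheritParams place_rim_particles
#' @return the scene with background-class particles appended.
#' @export
place_background_particles <- function(scene, params) {
  stopifnot(inherits(scene, "goldrim_scene"),
            inherits(params, "goldrim_placement"))
  R <- scene$vesicle$radius
  beta <- min(pi, scene$vesicle$pore_half_angle + params$rim_exclusion / R)
  area <- 2 * pi * R^2 * (1 + cos(beta))
  mu <- params$background_area_density * area
  pts <- with_seed(params$seed, {
    n <- if (params$count_mode == "fixed") as.integer(round(mu)) else rpois(1L, mu)
    z <- runif(n, -1, cos(beta))
    phi <- runif(n, 0, 2 * pi)
    dia <- sample_diameters(n, params)
    s <- sqrt(pmax(0, 1 - z^2))
    data.frame(x = R * s * cos(phi), y = R * s * sin(phi), z = R * z,
               diameter = dia, class = rep("background", n),
               stringsAsFactors = FALSE)
  })
  scene$particles <- rbind(scene$particles, pts)
  scene
}

# Exact 3D distance from vesicle-frame points to the rim circle (polar alpha,
# radius R): the rim lies in the plane z = R cos(alpha) at cylindrical radius
# R sin(alpha).
rim_distance_3d <- function(xyz, R, alpha) {
  rho <- R * sin(alpha)
  zc <- R * cos(alpha)
  rxy <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  sqrt((rxy - rho)^2 + (xyz[, 3] - zc)^2)
}

#' Orthographic projection of a scene with exact ground truth
#'
#' Projects along the lab +z axis (transmission imaging: no occlusion).  The
#' rim circle projects to an ellipse with semiaxes `rim_radius` and
#' `rim_radius * cos(tilt)`; particle centers are projected exactly and each
#' particle's true 3D distance to the rim circle is recorded.
#'
#' @param scene a scene (possibly with no particles).
#' @param n_vertices number of vertices of the projected-rim polyline.
#' @return an object of class `goldrim_truth` with fields
#'   `true_circumference`, `projected_rim` (closed [polyline()], lab nm,
#'   centered on the vesicle), `particles_2d`
#'   (x, y, class, diameter, true_distance), `tilt`, plus the scene geometry
#'   needed to reconstruct flanking annotations (`vesicle_radius`,
#'   `pore_half_angle`, `orientation`, `rim_semiaxes`, `pore_diameter`).
#' @export
project_scene <- function(scene, n_vertices = 720L) {
  stopifnot(inherits(scene, "goldrim_scene"))
  if (n_vertices < 8L) stop_validation("n_vertices", "must be >= 8")
  M <- rotation_matrix(scene$orientation)
  R <- scene$vesicle$radius
  alpha <- scene$vesicle$pore_half_angle
  rim <- project_sphere_circle(M, R, alpha, n_vertices)
  p <- scene$particles
  if (nrow(p) > 0) {
    lab <- as.matrix(p[, c("x", "y", "z")]) %*% t(M)
    p2 <- data.frame(x = lab[, 1], y = lab[, 2], class = p$class,
                     diameter = p$diameter,
                     true_distance = rim_distance_3d(
                       as.matrix(p[, c("x", "y", "z")]), R, alpha),
                     stringsAsFactors = FALSE)
  } else {
    p2 <- data.frame(x = numeric(), y = numeric(), class = character(),
                     diameter = numeric(), true_distance = numeric(),
                     stringsAsFactors = FALSE)
  }
  structure(list(true_circumference = pi * scene$pore_diameter,
                 projected_rim = rim,
                 particles_2d = p2,
                 tilt = scene$orientation$tilt,
                 vesicle_radius = R,
                 membrane_thickness = scene$vesicle$membrane_thickness,
                 pore_half_angle = alpha,
                 orientation = scene$orientation,
                 pore_diameter = scene$pore_diameter,
                 rim_semiaxes = c(scene$rim_radius,
                                  scene$rim_radius * cos(scene$orientation$tilt))),
            class = "goldrim_truth")
}

# Projection of the sphere circle at polar angle `theta` (vesicle frame) under
# rotation M, as a closed polyline in lab nm.
project_sphere_circle <- function(M, R, theta, n_vertices) {
  t <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  v <- cbind(R * sin(theta) * cos(t), R * sin(theta) * sin(t),
             R * cos(theta))
  lab <- v %*% t(M)
  polyline(lab[, 1:2], closed = TRUE)
}

# Outer/inner boundaries flanking the rim: projections of the sphere circles
# at polar angles alpha -/+ half the band width (arc length on the sphere).
# "Outer" is the boundary outside the pore (larger polar angle).
flanking_polylines <- function(truth, band = 5, n_vertices = 720L) {
  stopifnot(inherits(truth, "goldrim_truth"))
  M <- rotation_matrix(truth$orientation)
  R <- truth$vesicle_radius
  half <- (band / 2) / R
  a <- truth$pore_half_angle
  list(outer = project_sphere_circle(M, R, min(pi - 1e-6, a + half), n_vertices),
       inner = project_sphere_circle(M, R, max(1e-6, a - half), n_vertices))
}
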