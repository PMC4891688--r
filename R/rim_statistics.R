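# Summary statistics of rim-bound particles: region densities, edge-distance
# distributions, interparticle spacing, particle-area-vs-circumference
# regression and the Mann-Whitney rank comparison.

#' Particle density in a region of interest
#'
#' Density is the dimensionless ratio of particle area to non-particle area
#' within the region: `normalization * cluster_area /
#' (region_area - cluster_area)`.  A figure-caption variant dividing by the
#' full region ("boundary") area is available via `denominator`.  The
#' normalization factor rescales the particle area of a control probe whose
#' applied concentration differed from the labeled protein (e.g. a control
#' gold dose measured at 64.4% of the labeled dose is normalized with
#' `1 / 0.644`).
#'
#' @param clusters a [detect_particles()] result; clusters are assigned to
#'   the region by centroid membership (boundary counts as inside).
#' @param roi an [roi_polygon()].
#' @param normalization multiplicative factor applied to the cluster area.
#' @param denominator `"non_particle"` (region minus particle area; default)
#'   or `"region"` (full region area).
#' @return an object of class `goldrim_density`: a one-row data frame with
#'   `region_label`, `cluster_area`, `region_area`, `normalization`,
#'   `density`.
#' @export
region_density <- function(clusters, roi, normalization = 1,
                           denominator = c("non_particle", "region")) {
  denominator <- match.arg(denominator)
  if (!inherits(roi, "goldrim_roi"))
    stop_validation("roi", "must be an roi_polygon")
  region_area <- polygon_area(roi)
  cluster_area <- 0
  if (!is.null(clusters) && nrow(clusters) > 0) {
    inside <- points_in_polygon(
      cbind(clusters$centroid_x_nm, clusters$centroid_y_nm), roi)
    cluster_area <- sum(clusters$area_nm2[inside])
  }
  density_record(roi$label, cluster_area, region_area, normalization,
                 denominator)
}

# Core density arithmetic, shared with pipeline regions that are not simple
# polygons (e.g. the rim annulus or the vesicle area outside the pore).
density_record <- function(region_label, cluster_area, region_area,
                           normalization = 1,
                           denominator = c("non_particle", "region")) {
  denominator <- match.arg(denominator)
  if (cluster_area >= region_area)
    stop_goldrim("goldrim_degenerate_region_error",
                 "cluster area (%.3g) >= region area (%.3g)",
                 cluster_area, region_area)
  denom <- if (denominator == "non_particle")
    region_area - cluster_area else region_area
  structure(data.frame(region_label = region_label,
                       cluster_area = cluster_area,
                       region_area = region_area,
                       normalization = normalization,
                       density = normalization * cluster_area / denom,
                       stringsAsFactors = FALSE),
            class = c("goldrim_density", "data.frame"))
}

#' Particle-to-edge distance distribution
#'
#' Histogram of shortest distances from particle centers to the pore edge,
#' with the fraction within a threshold (1 nm by default); the observation
#' behind "localized mostly within 1 nm of the pore edges" is exactly this
#' fraction on en-face pores.
#'
#' @param particles n x 2 matrix of centers (nm) or a [detect_particles()]
#'   result.
#' @param edge edge [polyline()] or a [pore_annotation()] (its edge is used;
#'   a warning is issued if the annotation is not en face, since oblique
#'   projections foreshorten true distances).
#' @param bin_width histogram bin width in nm.
#' @return an object of class `goldrim_edge_distances` with fields
#'   `distances`, `breaks`, `counts`, `bin_width`.
#' @export
edge_distance_summary <- function(particles, edge, bin_width = 0.5) {
  if (inherits(particles, "goldrim_clusters"))
    particles <- cbind(particles$centroid_x_nm, particles$centroid_y_nm)
  particles <- matrix(as.numeric(particles), ncol = 2L)
  if (nrow(particles) == 0)
    stop_goldrim("goldrim_empty_input_error", "no particles supplied")
  check_scalar(bin_width, "bin_width")
  if (bin_width <= 0) stop_validation("bin_width", "must be > 0")
  if (inherits(edge, "goldrim_annotation")) {
    if (edge$orientation_class != "en_face")
      warning("edge annotation is not en face; distances are foreshortened")
    edge <- edge$edge
  }
  d <- min_edge_distance(particles, edge)
  upper <- max(bin_width, ceiling(max(d) / bin_width) * bin_width)
  breaks <- seq(0, upper, by = bin_width)
  counts <- as.integer(table(cut(d, breaks, include.lowest = TRUE,
                                 right = TRUE)))
  structure(list(distances = d, breaks = breaks, counts = counts,
                 bin_width = bin_width),
            class = "goldrim_edge_distances")
}

#' Fraction of particles within a distance of the edge
#'
#' Monotone non-decreasing in `threshold`.
#'
#' @param x an [edge_distance_summary()] result.
#' @param threshold distance in nm (default 1).
#' @return fraction in `[0, 1]`.
#' @export
fraction_within <- function(x, threshold = 1) {
  stopifnot(inherits(x, "goldrim_edge_distances"))
  mean(x$distances <= threshold)
}

#' Per-pore summary record
#'
#' @param pore_id identifier.
#' @param perimeter measured pore perimeter (nm), > 0.
#' @param particle_area total detected particle area at the pore (nm^2).
#' @param particle_count number of detected clusters at the pore.
#' @param tilt_class `"en_face"`, `"oblique"`, `"edge_on"`, or `NA`.
#' @return an object of class `goldrim_pore_record`; `spacing` is
#'   `perimeter / particle_count`, or `NA` when no particle was detected.
#' @export
pore_record <- function(pore_id, perimeter, particle_area, particle_count,
                        tilt_class = NA_character_) {
  check_scalar(perimeter, "perimeter")
  if (perimeter <= 0) stop_validation("perimeter", "must be > 0")
  check_scalar(particle_area, "particle_area")
  if (particle_area < 0) stop_validation("particle_area", "must be >= 0")
  particle_count <- as.integer(particle_count)
  if (is.na(particle_count) || particle_count < 0)
    stop_validation("particle_count", "must be a non-negative integer")
  structure(list(pore_id = pore_id, perimeter = perimeter,
                 particle_area = particle_area,
                 particle_count = particle_count,
                 spacing = if (particle_count > 0)
                   perimeter / particle_count else NA_real_,
                 tilt_class = tilt_class),
            class = "goldrim_pore_record")
}

#' Average interparticle spacing at a pore
#'
#' Pore circumference divided by the number of detected particles: an upper
#' bound on the true molecular spacing, since unlabeled molecules and merged
#' clusters both deflate the count.
#'
#' @param record a [pore_record()].
#' @return spacing in nm, or `NA` (flagged undefined) when no particle was
#'   detected.
#' @export
interparticle_spacing <- function(record) {
  stopifnot(inherits(record, "goldrim_pore_record"))
  record$spacing
}

pore_records_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r) {
    stopifnot(inherits(r, "goldrim_pore_record"))
    data.frame(pore_id = r$pore_id, perimeter = r$perimeter,
               particle_area = r$particle_area,
               particle_count = r$particle_count, spacing = r$spacing,
               tilt_class = r$tilt_class, stringsAsFactors = FALSE)
  }))
}

#' Regression of total particle area on pore circumference
#'
#' Ordinary least squares of per-pore total particle area against measured
#' perimeter, reporting slope, intercept and R^2, plus the through-origin
#' slope.  A linear relation with intercept near zero is the signature of a
#' constant linear particle density independent of pore size.
#'
#' @param records list of [pore_record()]s, or a data frame with columns
#'   `perimeter` and `particle_area`.
#' @return an object of class `goldrim_regression` with fields `slope`
#'   (nm^2/nm), `intercept` (nm^2), `r_squared`, `n`,
#'   `slope_through_origin`.
#' @export
density_vs_circumference_regression <- function(records) {
  df <- pore_records_frame(records)
  n <- nrow(df)
  if (n < 3L) stop_validation("records", "need at least 3 pores")
  if (sd(df$perimeter) == 0)
    stop_goldrim("goldrim_ill_conditioned_error",
                 "all pore perimeters are identical")
  fit <- lm(particle_area ~ perimeter, data = df)
  fit0 <- lm(particle_area ~ perimeter + 0, data = df)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((df$particle_area - mean(df$particle_area))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = n,
                 slope_through_origin = unname(coef(fit0)[1L])),
            class = "goldrim_regression")
}

#' Mann-Whitney U test (exact by enumeration, or normal approximation)
#'
#' U is computed from midranks (ties share the mean rank).  In `"exact"`
#' mode (automatic when `n1 + n2 <= 14`) the two-sided p-value is obtained by
#' full enumeration of all `choose(n1 + n2, n1)` group labelings of the
#' pooled ranks: the probability of a U at least as far from its null mean
#' `n1 * n2 / 2` as observed.  Otherwise a normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param x,y numeric samples (e.g. region densities), each non-empty.
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @return an object of class `goldrim_ranktest` with fields `u_statistic`
#'   (U of `x`), `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(c(x, y)))
    stop_validation("x", "samples must be non-empty and free of NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (mode == "exact" || (mode == "auto" && n <= 14L)) {
    cmb <- utils::combn(n, n1)
    us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    t_counts <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(t_counts^3 - t_counts) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "goldrim_ranktest")
}
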