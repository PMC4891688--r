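# Gold-particle detection by intensity band and physical-area threshold.
# Candidate pixels fall in the closed intensity band [band_low, band_high]
# (optionally everything at or below band_high), are grouped into connected
# components, and components smaller than `min_area` (nm^2) are discarded.
# Area is bookkept on the pixel grid (pixel count times pixel area), matching
# how total particle area is used as a proxy for particle number.

#' Detection parameters
#'
#' Defaults mirror the empirically determined thresholds: intensity band
#' 30-50 out of 256 and minimum area 0.32 nm^2 (which excludes most small
#' debris while including essentially all nanogold).
#'
#' @param band_low,band_high closed intensity band, `0 <= low <= high <= 255`.
#' @param min_area minimum cluster area in nm^2.
#' @param connectivity pixel connectivity, 4 or 8.  8 is the default: a round
#'   1.3 nm particle sampled at 0.2 nm/px produces diagonal adjacency.
#' @param include_below_band when `TRUE`, pixels darker than `band_low` also
#'   count as candidates (gold may saturate darker than the nominal band).
#' @return an object of class `goldrim_detection_params`.
#' @export
detection_params <- function(band_low = 30, band_high = 50, min_area = 0.32,
                             connectivity = 8, include_below_band = FALSE) {
  check_scalar(band_low, "band_low"); check_scalar(band_high, "band_high")
  check_scalar(min_area, "min_area")
  if (band_low < 0 || band_high > 255 || band_low > band_high)
    stop_validation("band_low", "need 0 <= band_low <= band_high <= 255")
  if (min_area < 0) stop_validation("min_area", "must be >= 0")
  if (!connectivity %in% c(4, 8))
    stop_validation("connectivity", "must be 4 or 8")
  structure(list(band_low = band_low, band_high = band_high,
                 min_area = min_area, connectivity = as.integer(connectivity),
                 include_below_band = isTRUE(include_below_band)),
            class = "goldrim_detection_params")
}

#' Detect gold-particle clusters
#'
#' @param image a [projection_image()].
#' @param params a [detection_params()].
#' @return an object of class `goldrim_clusters`: a data frame with columns
#'   `cluster_id`, `centroid_x_nm`, `centroid_y_nm`, `area_nm2`, `n_pixels`
#'   (centroids are unweighted means of member pixel centers, image nm
#'   frame), with the member pixel coordinates in `attr(, "pixels")`.  An
#'   empty frame is a valid result.
#' @export
detect_particles <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "goldrim_image"))
  if (!inherits(params, "goldrim_detection_params"))
    stop_validation("params", "must be detection_params()")
  m <- image$intensities
  lo <- if (params$include_below_band) 0 else params$band_low
  mask <- m >= lo & m <= params$band_high
  labels <- label_components_cpp(mask, params$connectivity)
  px <- image$pixel_size
  ids <- which(labels > 0)
  if (length(ids) == 0) return(empty_clusters(px))
  lab <- labels[ids]
  row <- (ids - 1L) %% nrow(m) + 1L
  col <- (ids - 1L) %/% nrow(m) + 1L
  n_pix <- tabulate(lab)
  keep <- which(n_pix * px^2 >= params$min_area & n_pix > 0)
  if (length(keep) == 0) return(empty_clusters(px))
  cx <- tapply((col - 0.5) * px, lab, mean)
  cy <- tapply((row - 0.5) * px, lab, mean)
  out <- data.frame(cluster_id = seq_along(keep),
                    centroid_x_nm = as.numeric(cx[as.character(keep)]),
                    centroid_y_nm = as.numeric(cy[as.character(keep)]),
                    area_nm2 = n_pix[keep] * px^2,
                    n_pixels = n_pix[keep])
  pixels <- lapply(keep, function(k)
    cbind(row = row[lab == k], col = col[lab == k]))
  structure(out, pixels = pixels, pixel_size = px,
            class = c("goldrim_clusters", "data.frame"))
}

empty_clusters <- function(px) {
  structure(data.frame(cluster_id = integer(), centroid_x_nm = numeric(),
                       centroid_y_nm = numeric(), area_nm2 = numeric(),
                       n_pixels = integer()),
            pixels = list(), pixel_size = px,
            class = c("goldrim_clusters", "data.frame"))
}

#' Total particle area
#'
#' Sum of cluster areas; the proxy for particle number that is robust to
#' touching particles being merged into one cluster.
#'
#' @param clusters a [detect_particles()] result (or any data frame with an
#'   `area_nm2` column).
#' @return total area in nm^2 (0 for an empty set).
#' @export
total_cluster_area <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0) return(0)
  sum(clusters$area_nm2)
}

#' Diameter of the circle with a given area
#'
#' @param area area in nm^2 (vectorized).
#' @return `2 * sqrt(area / pi)` in nm.
#' @export
equivalent_circle_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area < 0))
    stop_validation("area", "must be >= 0")
  2 * sqrt(area / pi)
}

#' Fraction of particles passing the area threshold
#'
#' Given normally distributed particle diameters, the fraction whose diameter
#' exceeds the equivalent-circle diameter of `min_area`.  With the commercial
#' nanogold distribution (1.3 +/- 0.14 nm) and the 0.32 nm^2 threshold this
#' exceeds 0.99: the threshold sits more than 4 sd below the mean diameter.
#'
#' @param mean_d,sd_d diameter distribution (nm), `mean_d > 0`, `sd_d >= 0`.
#' @param min_area area threshold in nm^2.
#' @return included fraction in `[0, 1]`; 1 when `sd_d = 0` and the mean is
#'   above the threshold diameter.
#' @export
diameter_inclusion_fraction <- function(mean_d, sd_d, min_area) {
  check_scalar(mean_d, "mean_d"); check_scalar(sd_d, "sd_d")
  if (mean_d <= 0) stop_validation("mean_d", "must be > 0")
  if (sd_d < 0) stop_validation("sd_d", "must be >= 0")
  d_thr <- equivalent_circle_diameter(min_area)
  if (sd_d == 0) return(as.numeric(mean_d > d_thr) + 0)
  pnorm((mean_d - d_thr) / sd_d)
}

#' Write clusters to CSV
#'
#' Columns: cluster_id, centroid_x_nm, centroid_y_nm, area_nm2, n_pixels.
#'
#' @param clusters a [detect_particles()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_clusters_csv <- function(clusters, path) {
  write.csv(as.data.frame(clusters), path, row.names = FALSE)
  invisible(path)
}
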