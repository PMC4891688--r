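# Reproducible simulate -> detect -> measure -> report pipeline.
#
# One master seed drives every stochastic draw in a documented order: the
# per-vesicle geometry (radius, pore half-angle, tilt, azimuth) is drawn
# first, then one sub-seed per vesicle and stage (rim placement, background
# placement, noise), so cohorts are reproducible byte-for-byte.

#' Pipeline run configuration
#'
#' Defaults describe the experimental regime the generator emulates: vesicle
#' radii 50-150 nm; pores from small to nearly vesicle-spanning (half-angle
#' 0.3-1.3 rad); mostly en-face views (tilt 0-0.35 rad); rim linear density
#' 1/6 particles per nm with 80% labeling efficiency; radial rim jitter
#' 0.3 nm; sparse nonspecific background (5e-5 particles per nm^2 of
#' membrane); nanogold 1.3 +/- 0.14 nm rendered at 0.25 nm/px, noise free.
#'
#' @param seed master integer seed.
#' @param n_vesicles number of vesicles (one pore each).
#' @param radius_range,pore_half_angle_range,tilt_range uniform sampling
#'   ranges (lo, hi) for the vesicle geometry, nm / rad / rad.
#' @param membrane_thickness shell thickness in nm.
#' @param linear_density,labeling_efficiency,rim_jitter_sd,
#'   background_area_density,rim_exclusion,particle_diameter_mean,
#'   particle_diameter_sd see [placement_params()].
#' @param pixel_size,noise_sd,margin,z_step see [render_image()].
#' @param rim_band full width (nm) of the band between the inner and outer
#'   pore boundaries used for annotation and densities.
#' @param en_face_cutoff circularity at or above which a pore counts as
#'   en face.
#' @param band_low,band_high,min_area,connectivity see [detection_params()].
#' @param normalization factor applied to cluster areas in densities.
#' @param out_dir default output directory for [run_simulate()].
#' @return an object of class `goldrim_config`.
#' @export
run_config <- function(seed = 1L, n_vesicles = 10L,
                       radius_range = c(50, 150),
                       membrane_thickness = 5,
                       pore_half_angle_range = c(0.3, 1.3),
                       tilt_range = c(0, 0.35),
                       linear_density = 1 / 6,
                       labeling_efficiency = 0.8,
                       rim_jitter_sd = 0.3,
                       background_area_density = 5e-5,
                       rim_exclusion = 5,
                       particle_diameter_mean = 1.3,
                       particle_diameter_sd = 0.14,
                       pixel_size = 0.25, noise_sd = 0,
                       margin = 20, z_step = 0.25,
                       rim_band = 5, en_face_cutoff = 0.9,
                       band_low = 30, band_high = 50, min_area = 0.32,
                       connectivity = 8, normalization = 1,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  for (f in c("radius_range", "pore_half_angle_range", "tilt_range")) {
    r <- cfg[[f]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r))
      stop_validation(f, "must be a numeric (lo, hi) pair")
    if (r[1] > r[2]) stop_validation(f, "range is reversed: (%g, %g)", r[1], r[2])
  }
  check_scalar(seed, "seed")
  if (n_vesicles < 1) stop_validation("n_vesicles", "must be >= 1")
  # delegate remaining validation to the constructors they feed
  placement_params(linear_density, labeling_efficiency, rim_jitter_sd,
                   background_area_density, rim_exclusion,
                   particle_diameter_mean, particle_diameter_sd)
  detection_params(band_low, band_high, min_area, connectivity)
  if (pixel_size <= 0) stop_validation("pixel_size", "must be > 0")
  if (rim_band <= 0) stop_validation("rim_band", "must be > 0")
  structure(cfg, class = "goldrim_config")
}

#' Load a configuration file (YAML or JSON)
#'
#' Fields present in the file override [run_config()] defaults; `overrides`
#' (e.g. parsed CLI flags) override both.
#'
#' @param path YAML or JSON config file, or `NULL` for pure defaults.
#' @param overrides named list of final overrides.
#' @return a `goldrim_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop_validation(unknown[1L], "unknown configuration field")
  do.call(run_config, vals)
}

config_placement <- function(cfg, seed = NULL) {
  placement_params(cfg$linear_density, cfg$labeling_efficiency,
                   cfg$rim_jitter_sd, cfg$background_area_density,
                   cfg$rim_exclusion, cfg$particle_diameter_mean,
                   cfg$particle_diameter_sd, seed = seed)
}

config_detection <- function(cfg) {
  detection_params(cfg$band_low, cfg$band_high, cfg$min_area,
                   cfg$connectivity)
}

runif_range <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else runif(n, r[1], r[2])

#' Simulate a cohort of porated vesicles to disk
#'
#' Writes, per vesicle, an 8-bit TIFF (`img_NNN.tif`), a calibration sidecar
#' (`img_NNN.json`) and ground truth in the image frame
#' (`img_NNN_truth.json`), plus `manifest.csv` and an echo of the
#' configuration (`config.yaml`).  Outputs are deterministic in the master
#' seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return the manifest data frame, invisibly.
#' @export
run_simulate <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "goldrim_config"))
  if (is.null(out_dir)) stop_validation("out_dir", "no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_goldrim("goldrim_io_error", "cannot create %s", out_dir)
  n <- config$n_vesicles
  draws <- with_seed(config$seed, list(
    radius = runif_range(n, config$radius_range),
    half_angle = runif_range(n, config$pore_half_angle_range),
    tilt = runif_range(n, config$tilt_range),
    azimuth = runif(n, 0, 2 * pi),
    rim_seed = sample.int(.Machine$integer.max - 1L, n),
    bg_seed = sample.int(.Machine$integer.max - 1L, n),
    noise_seed = sample.int(.Machine$integer.max - 1L, n)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ves <- vesicle_model(draws$radius[i], config$membrane_thickness,
                         draws$half_angle[i])
    scn <- make_scene(ves, orientation(draws$tilt[i], draws$azimuth[i]))
    scn <- place_rim_particles(scn, config_placement(config, draws$rim_seed[i]))
    scn <- place_background_particles(scn, config_placement(config, draws$bg_seed[i]))
    truth <- project_scene(scn)
    img <- render_image(scn, config$pixel_size, noise_sd = config$noise_sd,
                        seed = draws$noise_seed[i], margin = config$margin,
                        z_step = config$z_step)
    id <- sprintf("img_%03d", i)
    write_tiff(img, file.path(out_dir, paste0(id, ".tif")))
    write_sidecar(img, file.path(out_dir, paste0(id, ".json")))
    write_truth(truth, file.path(out_dir, paste0(id, "_truth.json")),
                offset = img$offset)
    rows[[i]] <- data.frame(
      image_id = id, image_file = paste0(id, ".tif"),
      truth_file = paste0(id, "_truth.json"),
      radius = draws$radius[i], pore_half_angle = draws$half_angle[i],
      tilt = draws$tilt[i],
      pore_diameter = scn$pore_diameter,
      true_circumference = truth$true_circumference,
      n_rim = sum(truth$particles_2d$class == "rim"),
      n_background = sum(truth$particles_2d$class == "background"),
      seed = config$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  cfg_plain <- unclass(config)
  cfg_plain$out_dir <- NULL
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

# Measure one image against its annotation.  Returns density rows (pore and
# non-pore), the pore record row and the per-particle edge distances of
# pore-associated clusters.
measure_image <- function(image, ann, regions, config, image_id = "image") {
  det <- detect_particles(image, config_detection(config))
  outer <- ann$outer
  inner <- ann$inner
  a_outer <- polygon_area(outer$vertices)
  a_inner <- polygon_area(inner$vertices)
  cent <- cbind(det$centroid_x_nm, det$centroid_y_nm)
  in_outer <- if (nrow(det) > 0) points_in_polygon(cent, outer$vertices) else logical()
  in_inner <- if (nrow(det) > 0) points_in_polygon(cent, inner$vertices) else logical()
  at_pore <- in_outer & !in_inner
  pore_area_det <- sum(det$area_nm2[at_pore])
  pore_row <- density_record("pore", pore_area_det, a_outer - a_inner,
                             config$normalization)
  non_pore <- regions$non_pore
  npr <- NULL
  if (!is.null(non_pore)) {
    in_ves <- if (nrow(det) > 0)
      points_in_polygon(cent, non_pore) else logical()
    np_area_det <- sum(det$area_nm2[in_ves & !in_outer])
    npr <- density_record("non_pore", np_area_det,
                          polygon_area(non_pore) - a_outer,
                          config$normalization)
  }
  perim <- pore_perimeter(ann)
  circ <- circularity(ann$edge)
  rec <- pore_record(image_id, perim, pore_area_det, sum(at_pore),
                     tilt_class = classify_orientation(circ, config$en_face_cutoff))
  dist <- if (any(at_pore))
    min_edge_distance(cent[at_pore, , drop = FALSE], ann$edge) else numeric()
  list(densities = rbind(
         cbind(image_id = image_id, as.data.frame(pore_row)),
         if (!is.null(npr)) cbind(image_id = image_id, as.data.frame(npr))),
       pore = data.frame(pore_id = image_id, perimeter_nm = perim,
                         particle_area_nm2 = pore_area_det,
                         particle_count = sum(at_pore),
                         spacing_nm = rec$spacing, circularity = circ,
                         tilt_class = rec$tilt_class,
                         stringsAsFactors = FALSE),
       distances = dist,
       clusters = det)
}

#' Measure a simulated or annotated cohort
#'
#' Pairs every image (`*.tif`) with its annotation: `<id>_ann.json` if
#' present, otherwise `<id>_truth.json` (ground truth converted through
#' [annotation_from_truth()]).  Writes `densities.csv`, `pores.csv`,
#' `distances.csv` (en-face pores only) and `tests.csv` (Mann-Whitney
#' comparison of pore vs non-pore densities) into `out_dir`, with each row
#' carrying the image id and the image file's md5 hash.
#'
#' @param in_dir directory holding images and annotations.
#' @param out_dir output directory (default `in_dir`).
#' @param config a [run_config()]; detection and annotation settings are
#'   taken from it.
#' @return list with `densities`, `pores`, `distances`, `tests` data frames,
#'   invisibly.
#' @export
run_measure <- function(in_dir, out_dir = in_dir, config = run_config()) {
  stopifnot(inherits(config, "goldrim_config"))
  imgs <- sort(list.files(in_dir, pattern = "\\.tiff?$", full.names = TRUE))
  ids <- sub("\\.tiff?$", "", basename(imgs))
  ann_paths <- file.path(in_dir, paste0(ids, "_ann.json"))
  truth_paths <- file.path(in_dir, paste0(ids, "_truth.json"))
  has_pair <- file.exists(ann_paths) | file.exists(truth_paths)
  stray_ann <- setdiff(list.files(in_dir, pattern = "_(ann|truth)\\.json$"),
                       c(paste0(ids, "_ann.json"), paste0(ids, "_truth.json")))
  if (length(imgs) == 0 || any(!has_pair) || length(stray_ann) > 0)
    stop_goldrim("goldrim_paired_input_error",
                 "unpaired inputs: %s",
                 paste(c(ids[!has_pair], stray_ann,
                         if (length(imgs) == 0) "(no images)"),
                       collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dens <- list(); pores <- list(); dists <- list()
  for (k in seq_along(imgs)) {
    img <- read_image(imgs[k])
    if (file.exists(ann_paths[k])) {
      a <- read_annotation(ann_paths[k])
      ann <- a$annotation
      regions <- list(non_pore = if (!is.null(a$regions$non_pore))
        a$regions$non_pore$boundary$vertices)
    } else {
      truth <- read_truth(truth_paths[k])
      a <- annotation_from_truth(truth, rim_band = config$rim_band,
                                 offset = c(0, 0),
                                 en_face_cutoff = config$en_face_cutoff)
      ann <- a$annotation
      regions <- list(non_pore = a$regions$non_pore$boundary$vertices)
    }
    m <- measure_image(img, ann, regions, config, image_id = ids[k])
    hash <- unname(tools::md5sum(imgs[k]))
    m$densities$image_md5 <- hash
    m$pore$image_md5 <- hash
    dens[[k]] <- m$densities
    pores[[k]] <- m$pore
    if (m$pore$tilt_class == "en_face" && length(m$distances) > 0)
      dists[[k]] <- data.frame(image_id = ids[k], distance_nm = m$distances,
                               stringsAsFactors = FALSE)
  }
  densities <- do.call(rbind, dens)
  pores_df <- do.call(rbind, pores)
  distances <- if (length(dists) > 0) do.call(rbind, dists) else
    data.frame(image_id = character(), distance_nm = numeric())
  x <- densities$density[densities$region_label == "pore"]
  y <- densities$density[densities$region_label == "non_pore"]
  tests <- if (length(x) > 0 && length(y) > 0) {
    mw <- mann_whitney(x, y)
    data.frame(comparison = "pore_vs_nonpore_density",
               U = mw$u_statistic, p = mw$p_value, method = mw$method,
               n1 = mw$n1, n2 = mw$n2, stringsAsFactors = FALSE)
  } else {
    data.frame(comparison = character(), U = numeric(), p = numeric(),
               method = character(), n1 = integer(), n2 = integer())
  }
  write.csv(densities, file.path(out_dir, "densities.csv"), row.names = FALSE)
  write.csv(pores_df, file.path(out_dir, "pores.csv"), row.names = FALSE)
  write.csv(distances, file.path(out_dir, "distances.csv"), row.names = FALSE)
  write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
  invisible(list(densities = densities, pores = pores_df,
                 distances = distances, tests = tests))
}

#' Summarize a measured cohort
#'
#' Prints pooled interparticle spacing (total perimeter over total count),
#' the particle-area-vs-circumference regression, mean densities by region
#' and the rank-test table.
#'
#' @param dir directory holding the `run_measure()` CSVs.
#' @return summary list, invisibly.
#' @export
run_report <- function(dir) {
  pores <- read.csv(file.path(dir, "pores.csv"))
  densities <- read.csv(file.path(dir, "densities.csv"))
  tests <- read.csv(file.path(dir, "tests.csv"))
  pooled_spacing <- if (sum(pores$particle_count) > 0)
    sum(pores$perimeter_nm) / sum(pores$particle_count) else NA_real_
  reg <- if (nrow(pores) >= 3 && sd(pores$perimeter_nm) > 0)
    density_vs_circumference_regression(
      data.frame(perimeter = pores$perimeter_nm,
                 particle_area = pores$particle_area_nm2)) else NULL
  cat(sprintf("pores analyzed: %d\n", nrow(pores)))
  cat(sprintf("pooled interparticle spacing: %.2f nm\n", pooled_spacing))
  if (!is.null(reg))
    cat(sprintf(
      "area vs circumference: slope %.4f nm^2/nm, intercept %.3f nm^2, R^2 %.3f (through origin: %.4f)\n",
      reg$slope, reg$intercept, reg$r_squared, reg$slope_through_origin))
  for (lbl in unique(densities$region_label))
    cat(sprintf("mean %s density: %.5f (n = %d)\n", lbl,
                mean(densities$density[densities$region_label == lbl]),
                sum(densities$region_label == lbl)))
  if (nrow(tests) > 0)
    cat(sprintf("%s: U = %g, p = %.4g (%s, n1 = %d, n2 = %d)\n",
                tests$comparison, tests$U, tests$p, tests$method,
                tests$n1, tests$n2))
  invisible(list(pooled_spacing = pooled_spacing, regression = reg,
                 densities = densities, tests = tests))
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `measure`, `report`.  Flags: `--config PATH`,
#' `--seed N`, `--n N`, `--out DIR`, `--in DIR`, `--pixel-size NM`,
#' `--band LO:HI`, `--min-area NM2`.  CLI flags override config-file values.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0, invisibly.
#' @export
goldrim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop_goldrim("goldrim_cli_error",
                 "usage: goldrim <simulate|measure|report> [options]")
  verb <- args[1L]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--n", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--in", type = "character", default = NULL,
                          dest = "in_dir"),
    optparse::make_option("--pixel-size", type = "double", default = NULL,
                          dest = "pixel_size"),
    optparse::make_option("--band", type = "character", default = NULL),
    optparse::make_option("--min-area", type = "double", default = NULL,
                          dest = "min_area"))
  parsed <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                                 args = args[-1L])
  ov <- list()
  if (!is.null(parsed$seed)) ov$seed <- parsed$seed
  if (!is.null(parsed$n)) ov$n_vesicles <- parsed$n
  if (!is.null(parsed$pixel_size)) ov$pixel_size <- parsed$pixel_size
  if (!is.null(parsed$min_area)) ov$min_area <- parsed$min_area
  if (!is.null(parsed$band)) {
    b <- as.numeric(strsplit(parsed$band, ":")[[1L]])
    ov$band_low <- b[1L]; ov$band_high <- b[2L]
  }
  if (!is.null(parsed$out)) ov$out_dir <- parsed$out
  cfg <- load_config(parsed$config, ov)
  switch(verb,
         simulate = run_simulate(cfg),
         measure = run_measure(parsed$in_dir %||% parsed$out %||% ".",
                               parsed$out %||% parsed$in_dir %||% ".", cfg),
         report = run_report(parsed$in_dir %||% parsed$out %||% "."),
         stop_goldrim("goldrim_cli_error", "unknown verb: %s", verb))
  invisible(0L)
}
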