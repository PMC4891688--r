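# Rendering of calibrated 8-bit projection images from scenes.
#
# Intensity model (cryo-EM densities are dark): gold particles are hard disks
# at intensity 40, the center of the default 30-50 detection band; membrane is
# mapped from the projected shell path length into [80, 150] (the longer the
# path, the darker); lumen and exterior are >= 180.  In noise-free images the
# detection band therefore selects all gold and nothing else.

#' Calibrated 8-bit projection image
#'
#' @param intensities integer matrix in `[0, 255]`, at least 8 x 8; rows are
#'   image y (increasing downward), columns x.
#' @param pixel_size physical pixel size in nm/px.
#' @param offset length-2 nm vector added to centered lab coordinates to get
#'   image-frame coordinates (image frame has its origin at the outer corner
#'   of pixel `[1, 1]`).
#' @return an object of class `goldrim_image`.
#' @export
projection_image <- function(intensities, pixel_size, offset = c(0, 0)) {
  m <- as.matrix(intensities)
  if (nrow(m) < 8L || ncol(m) < 8L)
    stop_validation("intensities", "image must be at least 8 x 8 pixels")
  if (anyNA(m) || any(m < 0) || any(m > 255))
    stop_validation("intensities", "intensities must lie in [0, 255]")
  storage.mode(m) <- "integer"
  check_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_validation("pixel_size", "must be > 0")
  structure(list(intensities = m, pixel_size = pixel_size,
                 offset = as.numeric(offset)),
            class = "goldrim_image")
}

#' Render a scene to a calibrated 8-bit image
#'
#' Orthographic transmission rendering.  Membrane intensity is linear in the
#' ray path length through the shell, mapped into `[80, 150]` against the
#' maximal tangential chord `2 * sqrt(R^2 - (R - t)^2)`; empty rays render at
#' 200; gold particles are drawn last as hard disks at intensity 40 (pixel
#' centers within `diameter / 2` of the projected center).  Optional Gaussian
#' noise (off by default) is added, rounded and clipped to `[0, 255]`.
#'
#' @param scene a populated (or empty) scene.
#' @param pixel_size nm per pixel.
#' @param noise_sd intensity sd of additive Gaussian noise; 0 disables it.
#' @param seed seed for the noise draw (ignored when `noise_sd = 0`).
#' @param margin nm of empty space around the vesicle.
#' @param z_step quadrature step (nm) of the shell path-length integral.
#' @return a [projection_image()]; its `offset` maps ground-truth (centered)
#'   coordinates into the image frame.
#' @export
render_image <- function(scene, pixel_size, noise_sd = 0, seed = NULL,
                         margin = 20, z_step = 0.25) {
  stopifnot(inherits(scene, "goldrim_scene"))
  check_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_validation("pixel_size", "must be > 0")
  R <- scene$vesicle$radius
  Ri <- R - scene$vesicle$membrane_thickness
  half_w <- R + margin
  n <- max(8L, as.integer(ceiling(2 * half_w / pixel_size)))
  offset <- c(n, n) * pixel_size / 2
  axis <- rotation_matrix(scene$orientation) %*% c(0, 0, 1)
  L <- shell_path_length_cpp(n, n, pixel_size, offset[1], offset[2],
                             R, Ri, scene$vesicle$pore_half_angle,
                             axis[1], axis[2], axis[3], z_step)
  lmax <- 2 * sqrt(R^2 - Ri^2)
  img <- matrix(200L, n, n)
  memb <- L > 0
  img[memb] <- as.integer(round(150 - 70 * pmin(1, L[memb] / lmax)))
  # gold disks on top
  truth <- project_scene(scene, n_vertices = 16L)
  p <- truth$particles_2d
  if (nrow(p) > 0) {
    subpixel <- FALSE
    for (k in seq_len(nrow(p))) {
      r <- p$diameter[k] / 2
      cx <- p$x[k] + offset[1]
      cy <- p$y[k] + offset[2]
      cols <- max(1L, floor((cx - r) / pixel_size)):min(n, ceiling((cx + r) / pixel_size) + 1L)
      rows <- max(1L, floor((cy - r) / pixel_size)):min(n, ceiling((cy + r) / pixel_size) + 1L)
      px_x <- (cols - 0.5) * pixel_size
      px_y <- (rows - 0.5) * pixel_size
      hit <- outer((px_y - cy)^2, (px_x - cx)^2, "+") <= r^2
      if (!any(hit)) subpixel <- TRUE
      img[rows, cols][hit] <- 40L
    }
    if (subpixel)
      warning("pixel_size too coarse: at least one particle covers no pixel center")
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, {
      noisy <- img + rnorm(length(img), 0, noise_sd)
      matrix(as.integer(pmin(255, pmax(0, round(noisy)))), n, n)
    })
  }
  projection_image(img, pixel_size, offset)
}
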