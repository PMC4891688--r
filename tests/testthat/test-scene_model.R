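test_that("scene construction validates fields and defines the rim analytically", {
  s <- make_scene(vesicle_model(100, 5, 0.2), orientation(0))
  expect_equal(s$rim_radius, 100 * sin(0.2))
  expect_equal(s$pore_diameter, 200 * sin(0.2))
  expect_equal(nrow(s$particles), 0L)
  expect_error(vesicle_model(100, 5, 0), class = "goldrim_validation_error")
  expect_error(vesicle_model(-1, 5, 0.2), class = "goldrim_validation_error")
  expect_error(vesicle_model(100, 120, 0.2), class = "goldrim_validation_error")
  expect_error(orientation(-0.1), class = "goldrim_validation_error")
  o <- orientation(pi / 2)
  expect_true(o$edge_on)
  expect_false(orientation(0.3)$edge_on)
})

test_that("ground-truth circumference equals pi * d to 1e-9 relative", {
  set.seed(3)
  for (i in 1:20) {
    R <- runif(1, 30, 200)
    a <- runif(1, 0.05, 1.5)
    s <- make_scene(vesicle_model(R, 4, a), orientation(runif(1, 0, pi / 2)))
    tr <- project_scene(s, n_vertices = 64L)
    d <- 2 * R * sin(a)
    expect_lt(abs(tr$true_circumference - pi * d) / (pi * d), 1e-9)
  }
})

test_that("rim placement: expected counts, determinism, zero density", {
  # choose radius so the rim circumference is exactly 120 nm
  ves <- vesicle_model(120 / (2 * pi * sin(0.5)), 3, 0.5)
  s <- make_scene(ves)
  expect_equal(s$rim_circumference, 120)

  p0 <- placement_params(linear_density = 0, seed = 1)
  expect_equal(nrow(place_rim_particles(s, p0)$particles), 0L)

  pfix <- placement_params(linear_density = 1 / 6, labeling_efficiency = 1,
                           seed = 1, count_mode = "fixed")
  expect_equal(nrow(place_rim_particles(s, pfix)$particles), 20L)

  p1 <- placement_params(linear_density = 1 / 6, labeling_efficiency = 1,
                         seed = 42)
  s1 <- place_rim_particles(s, p1)
  s2 <- place_rim_particles(s, p1)
  expect_identical(s1$particles, s2$particles)

  # Monte-Carlo oracle over seeds: mean Poisson count within 3 standard errors
  counts_full <- integer(500)
  counts_thin <- integer(500)
  pthin <- placement_params(linear_density = 1 / 6, labeling_efficiency = 0.8)
  for (k in seq_len(500)) {
    p1$seed <- k
    pthin$seed <- k
    counts_full[k] <- nrow(place_rim_particles(s, p1)$particles)
    counts_thin[k] <- nrow(place_rim_particles(s, pthin)$particles)
  }
  expect_lt(abs(mean(counts_full) - 20), 3 * sd(counts_full) / sqrt(500))
  expect_lt(abs(mean(counts_thin) - 16), 3 * sd(counts_thin) / sqrt(500))

  pcap <- placement_params(linear_density = 1e5, seed = 1)
  expect_error(place_rim_particles(s, pcap), class = "goldrim_parameter_error")
})

test_that("rim jitter keeps true distances within 3 sd + diameter", {
  s <- make_scene(vesicle_model(80, 5, 0.7), orientation(0.4, 1.1))
  p <- placement_params(linear_density = 1, rim_jitter_sd = 0.5, seed = 9)
  tr <- project_scene(place_rim_particles(s, p))
  rim <- tr$particles_2d
  expect_gt(nrow(rim), 50)
  expect_true(all(rim$true_distance <= 3 * 0.5 + rim$diameter))
})

test_that("background placement respects density, exclusion band, determinism", {
  s <- make_scene(vesicle_model(60, 5, 0.01 + 1e-3))
  p0 <- placement_params(background_area_density = 0, seed = 1)
  expect_equal(nrow(place_background_particles(s, p0)$particles), 0L)

  # near-degenerate pore, no exclusion: expected count ~ 4 pi R^2 rho
  rho <- 2e-4
  pbg <- placement_params(background_area_density = rho, rim_exclusion = 0)
  counts <- integer(400)
  for (k in seq_len(400)) {
    pbg$seed <- k
    counts[k] <- nrow(place_background_particles(s, pbg)$particles)
  }
  expect_lt(abs(mean(counts) - 4 * pi * 60^2 * rho),
            3 * sd(counts) / sqrt(400) + 4 * pi * 60^2 * rho * 0.01)

  # brute-force ground-truth check of the exclusion band
  s2 <- make_scene(vesicle_model(90, 5, 0.8))
  pex <- placement_params(background_area_density = 5e-3, rim_exclusion = 5,
                          seed = 17)
  tr <- project_scene(place_background_particles(s2, pex))
  expect_gt(nrow(tr$particles_2d), 100)
  min_chord <- 2 * 90 * sin(5 / (2 * 90))  # chord of a 5 nm arc
  expect_true(all(tr$particles_2d$true_distance >= min_chord - 1e-9))
})

test_that("projection geometry: circle at tilt 0, ellipse axes, polyline length", {
  s0 <- make_scene(vesicle_model(50, 5, asin(10 / 50)), orientation(0))
  tr0 <- project_scene(s0)
  radii <- sqrt(rowSums(tr0$projected_rim$vertices^2))
  expect_equal(radii, rep(10, length(radii)), tolerance = 1e-9)

  s1 <- make_scene(vesicle_model(50, 5, asin(10 / 50)), orientation(pi / 3))
  tr1 <- project_scene(s1)
  expect_equal(tr1$rim_semiaxes, c(10, 5), tolerance = 1e-12)
  v <- tr1$projected_rim$vertices
  ctr <- colMeans(v)
  expect_equal(max(sqrt(rowSums(sweep(v, 2, ctr)^2))), 10, tolerance = 1e-6)
  expect_equal(min(sqrt(rowSums(sweep(v, 2, ctr)^2))), 5, tolerance = 1e-6)

  # 720-vertex projected rim length matches the elliptic-integral perimeter
  # within 0.1%
  pp <- projected_perimeter(20, pi / 3)
  expect_lt(abs(polyline_length(tr1$projected_rim) - pp) / pp, 0.001)
})

test_that("rendering: empty scene, single-particle raster oracle, determinism", {
  s <- make_scene(vesicle_model(20, 5, 0.3))
  s$particles <- s$particles[0, ]
  # no membrane only happens without a vesicle; instead check all non-gold
  img <- render_image(s, 0.5, margin = 5)
  expect_true(all(img$intensities >= 80))
  expect_true(any(img$intensities >= 180))
  expect_true(all(img$intensities[img$intensities < 180] <= 150))

  # one 1.3 nm particle at 0.2 nm/px: pixel count equals the rasterization
  # oracle (~33 pixels), all at intensity 40
  xyz <- rim_points(50, 0.6, 0)
  s2 <- scene_with_particles(50, 0.6, tilt = 0, xyz = xyz, diameter = 1.3)
  img2 <- render_image(s2, 0.2)
  tr2 <- project_scene(s2)
  n40 <- sum(img2$intensities == 40L)
  want <- oracle_raster_count(tr2$particles_2d$x[1] + img2$offset[1],
                              tr2$particles_2d$y[1] + img2$offset[2],
                              1.3 / 2, 0.2)
  expect_equal(n40, want)
  expect_gt(n40, 25); expect_lt(n40, 40)

  # noise off: identical renders; noise on: same seed -> identical
  expect_identical(render_image(s2, 0.4)$intensities,
                   render_image(s2, 0.4)$intensities)
  na <- render_image(s2, 0.4, noise_sd = 5, seed = 3)
  nb <- render_image(s2, 0.4, noise_sd = 5, seed = 3)
  expect_identical(na$intensities, nb$intensities)
  nc <- render_image(s2, 0.4, noise_sd = 5, seed = 4)
  expect_false(identical(na$intensities, nc$intensities))

  # a particle smaller than a pixel footprint warns
  s3 <- scene_with_particles(50, 0.6, xyz = xyz, diameter = 0.3)
  expect_warning(render_image(s3, 2, margin = 5), "coarse")
})

test_that("scenes and images are bitwise-identical for one seed", {
  ves <- vesicle_model(70, 5, 0.8)
  ori <- orientation(0.25, 2)
  p <- placement_params(linear_density = 1 / 6, background_area_density = 1e-4,
                        seed = 123)
  build <- function() {
    s <- make_scene(ves, ori)
    s <- place_rim_particles(s, p)
    place_background_particles(s, p)
  }
  s1 <- build(); s2 <- build()
  expect_identical(s1, s2)
  expect_identical(render_image(s1, 0.4)$intensities,
                   render_image(s2, 0.4)$intensities)
})
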