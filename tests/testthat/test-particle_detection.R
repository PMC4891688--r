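blank_image <- function(n = 32L, value = 200L, px = 0.2) {
  projection_image(matrix(value, n, n), px)
}

test_that("uniform bright image yields no detections", {
  det <- detect_particles(blank_image())
  expect_s3_class(det, "goldrim_clusters")
  expect_equal(nrow(det), 0L)
  expect_equal(total_cluster_area(det), 0)
})

test_that("five disjoint rendered disks give exactly five clusters, no false positives", {
  xyz <- rim_points(50, 0.6, 2 * pi * (0:4) / 5)
  s <- scene_with_particles(50, 0.6, tilt = 0.2, azimuth = 0.7, xyz = xyz)
  img <- render_image(s, 0.2)
  tr <- project_scene(s)
  det <- detect_particles(img)
  expect_equal(nrow(det), 5L)
  # each true particle matched by one centroid within half a diameter
  truth_xy <- cbind(tr$particles_2d$x + img$offset[1],
                    tr$particles_2d$y + img$offset[2])
  d <- as.matrix(dist(rbind(truth_xy, cbind(det$centroid_x_nm,
                                            det$centroid_y_nm))))[1:5, 6:10]
  expect_true(all(apply(d, 1, min) < 0.65))
  # total area equals an independent pixel recount of the intensity band
  mask <- img$intensities >= 30 & img$intensities <= 50
  expect_equal(total_cluster_area(det), sum(mask) * 0.2^2)
})

test_that("area threshold drops sub-threshold blobs", {
  m <- matrix(200L, 32L, 32L)
  m[10:11, 10:11] <- 40L                      # 4 px * 0.04 = 0.16 nm^2
  expect_equal(nrow(detect_particles(projection_image(m, 0.2))), 0L)
  m[20:22, 20:22] <- 40L                      # 9 px * 0.04 = 0.36 nm^2
  det <- detect_particles(projection_image(m, 0.2))
  expect_equal(nrow(det), 1L)
  expect_equal(det$area_nm2, 0.36)
  expect_equal(det$centroid_x_nm, (21 - 0.5) * 0.2)
  expect_equal(det$centroid_y_nm, (21 - 0.5) * 0.2)
})

test_that("band semantics: closed band by default, include_below_band flag", {
  m <- matrix(200L, 16L, 16L)
  m[4, 4] <- 29L; m[8, 8] <- 30L; m[12, 12] <- 50L
  img <- projection_image(m, 1)
  det <- detect_particles(img, detection_params(min_area = 0))
  expect_equal(nrow(det), 2L)
  det2 <- detect_particles(img, detection_params(min_area = 0,
                                                 include_below_band = TRUE))
  expect_equal(nrow(det2), 3L)
})

test_that("connectivity: diagonal blobs merge under 8- but not 4-connectivity", {
  m <- matrix(200L, 16L, 16L)
  m[5, 5] <- 40L; m[6, 6] <- 40L
  img <- projection_image(m, 1)
  expect_equal(nrow(detect_particles(img, detection_params(min_area = 0,
                                                           connectivity = 8))), 1L)
  expect_equal(nrow(detect_particles(img, detection_params(min_area = 0,
                                                           connectivity = 4))), 2L)
})

test_that("detection is deterministic and monotone in its thresholds", {
  set.seed(5)
  m <- matrix(sample(c(200L, 40L, 25L, 60L), 48 * 48, replace = TRUE,
                     prob = c(0.85, 0.08, 0.04, 0.03)), 48L, 48L)
  img <- projection_image(m, 0.3)
  base <- detect_particles(img, detection_params(min_area = 0.3))
  expect_identical(base, detect_particles(img, detection_params(min_area = 0.3)))
  # lowering min_area never removes a cluster
  more <- detect_particles(img, detection_params(min_area = 0.1))
  expect_true(nrow(more) >= nrow(base))
  expect_true(total_cluster_area(more) >= total_cluster_area(base))
  # raising band_high never removes a candidate pixel
  mask_50 <- m >= 30 & m <= 50
  mask_70 <- m >= 30 & m <= 70
  expect_true(all(mask_70[mask_50]))
  wide <- detect_particles(img, detection_params(band_high = 70, min_area = 0.1))
  expect_true(sum(wide$n_pixels) >= sum(more$n_pixels))
})

test_that("total_cluster_area is additive over disjoint image regions", {
  m <- matrix(200L, 40L, 40L)
  m[5:7, 5:7] <- 40L
  m[30:33, 30:33] <- 40L
  img <- projection_image(m, 0.3)
  both <- total_cluster_area(detect_particles(img))
  left <- m; left[25:40, ] <- 200L
  right <- m; right[1:24, ] <- 200L
  expect_equal(both,
               total_cluster_area(detect_particles(projection_image(left, 0.3))) +
               total_cluster_area(detect_particles(projection_image(right, 0.3))))
})

test_that("equivalent circle diameter inverts the area formula", {
  expect_equal(equivalent_circle_diameter(0), 0)
  expect_equal(equivalent_circle_diameter(pi / 4), 1)
  expect_equal(equivalent_circle_diameter(0.32), 2 * sqrt(0.32 / pi))
  expect_error(equivalent_circle_diameter(-1),
               class = "goldrim_validation_error")
})

test_that("diameter inclusion fraction reproduces the >99% threshold argument", {
  # 1.3 +/- 0.14 nm gold vs the 0.32 nm^2 area threshold
  expect_gt(diameter_inclusion_fraction(1.3, 0.14, 0.32), 0.99)
  expect_equal(diameter_inclusion_fraction(1.3, 0, 0.32), 1)
  expect_equal(diameter_inclusion_fraction(0.5, 0, 0.32), 0)
  # threshold exactly 4 sd below the mean: the normal upper tail at z = 4
  sd_d <- 0.14
  d_thr <- equivalent_circle_diameter(0.32)
  mean_d <- d_thr + 4 * sd_d
  expect_equal(diameter_inclusion_fraction(mean_d, sd_d, 0.32),
               0.9999683, tolerance = 1e-5)
})

test_that("cluster CSV export round-trips", {
  m <- matrix(200L, 32L, 32L)
  m[10:12, 10:12] <- 40L
  det <- detect_particles(projection_image(m, 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clusters_csv(det, path)
  back <- read.csv(path)
  expect_equal(back$area_nm2, det$area_nm2)
  expect_equal(names(back), c("cluster_id", "centroid_x_nm", "centroid_y_nm",
                              "area_nm2", "n_pixels"))
})
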