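fake_clusters <- function(xy, areas) {
  structure(data.frame(cluster_id = seq_len(nrow(xy)),
                       centroid_x_nm = xy[, 1], centroid_y_nm = xy[, 2],
                       area_nm2 = areas, n_pixels = NA_integer_),
            class = c("goldrim_clusters", "data.frame"))
}

test_that("region density follows the particle/non-particle ratio definition", {
  roi <- roi_polygon(rbind(c(0, 0), c(40, 0), c(40, 25), c(0, 25)), "pore")
  expect_equal(polygon_area(roi), 1000)
  empty <- region_density(NULL, roi)
  expect_equal(empty$density, 0)
  cl <- fake_clusters(rbind(c(10, 10), c(30, 12), c(100, 100)), c(20, 30, 99))
  d <- region_density(cl, roi)          # the (100,100) cluster is outside
  expect_equal(d$cluster_area, 50)
  expect_equal(d$density, 50 / 950)
  # control normalization: a gold dose measured at 64.4% of the labeled dose
  dn <- region_density(cl, roi, normalization = 1 / 0.644)
  expect_equal(dn$density, (50 / 0.644) / 950)
  # figure-caption variant: divide by the full region area
  db <- region_density(cl, roi, denominator = "region")
  expect_equal(db$density, 50 / 1000)
  big <- fake_clusters(cbind(10, 10), 1000)
  expect_error(region_density(big, roi),
               class = "goldrim_degenerate_region_error")
})

test_that("region density is invariant under rigid motion of clusters + ROI", {
  set.seed(11)
  v <- ngon(c(0, 0), 10, 36L)
  xy <- cbind(runif(20, -12, 12), runif(20, -12, 12))
  areas <- runif(20, 0.3, 2)
  rot <- function(m, th, dx, dy) {
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    sweep(m %*% t(Rm), 2L, -c(dx, dy))
  }
  d0 <- region_density(fake_clusters(xy, areas), roi_polygon(v, "pore"))
  d1 <- region_density(fake_clusters(rot(xy, 0.83, 5, -7), areas),
                       roi_polygon(rot(v, 0.83, 5, -7), "pore"))
  expect_equal(d1$density, d0$density, tolerance = 1e-12)
})

test_that("edge distance summary: histogram, fraction_within, failure modes", {
  edge <- polyline(rbind(c(0, 0), c(10, 0)))
  on_edge <- rbind(c(1, 0), c(5, 0), c(9, 0))
  s <- edge_distance_summary(on_edge, edge)
  expect_equal(fraction_within(s, 1), 1)
  s2 <- edge_distance_summary(rbind(c(5, 2)), edge)
  expect_equal(fraction_within(s2, 1), 0)
  expect_equal(fraction_within(s2, 2), 1)
  expect_error(edge_distance_summary(matrix(numeric(), ncol = 2), edge),
               class = "goldrim_empty_input_error")
  # fraction_within is monotone in its threshold
  set.seed(2)
  pts <- cbind(runif(50, 0, 10), runif(50, -3, 3))
  s3 <- edge_distance_summary(pts, edge, bin_width = 0.25)
  th <- seq(0, 4, by = 0.1)
  fr <- vapply(th, function(t) fraction_within(s3, t), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(sum(s3$counts), 50L)
  # non-en-face annotation warns
  ann <- pore_annotation(ngon(c(0, 0), 10, 64L), ngon(c(0, 0), 12, 64L),
                         ngon(c(0, 0), 8, 64L), orientation_class = "oblique")
  expect_warning(edge_distance_summary(rbind(c(0, 10)), ann), "en face")
})

test_that("interparticle spacing is perimeter over detected count", {
  expect_equal(interparticle_spacing(pore_record("a", 60, 10, 10)), 6)
  expect_equal(interparticle_spacing(pore_record("b", 100, 10, 10)), 10)
  expect_true(is.na(interparticle_spacing(pore_record("c", 60, 0, 0))))
  expect_error(pore_record("d", -1, 0, 0), class = "goldrim_validation_error")
})

test_that("area-vs-circumference regression matches the hand least-squares oracle", {
  exact <- data.frame(perimeter = c(10, 20, 40), particle_area = c(5, 10, 20))
  r <- density_vs_circumference_regression(exact)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope_through_origin, 0.5, tolerance = 1e-12)

  df <- data.frame(perimeter = c(10, 20, 30), particle_area = c(4, 9, 17))
  r2 <- density_vs_circumference_regression(df)
  # hand least squares: Sxy = 130, Sxx = 200
  expect_equal(r2$slope, 0.65, tolerance = 1e-12)
  expect_equal(r2$intercept, -3, tolerance = 1e-12)
  expect_equal(r2$n, 3L)

  expect_error(density_vs_circumference_regression(df[1:2, ]),
               class = "goldrim_validation_error")
  same <- data.frame(perimeter = c(10, 10, 10), particle_area = 1:3)
  expect_error(density_vs_circumference_regression(same),
               class = "goldrim_ill_conditioned_error")
})

test_that("count-level cohorts at constant linear density intersect the origin", {
  # Monte-Carlo oracle: per-pore area = a0 * Poisson(lambda * C); the fitted
  # intercept should be unbiased around 0
  set.seed(31)
  a0 <- 1.3; lambda <- 1 / 6
  intercepts <- replicate(100, {
    C <- runif(30, 100, 500)
    area <- a0 * rpois(30, lambda * C)
    density_vs_circumference_regression(
      data.frame(perimeter = C, particle_area = area))$intercept
  })
  expect_lt(abs(mean(intercepts)), 3 * sd(intercepts) / sqrt(100))
})

test_that("mann_whitney: frozen examples and tie handling", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 0.1)            # 2 of the 20 labelings as extreme
  expect_identical(mw$method, "exact")
  sym <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sym$u_statistic, 9)
  expect_equal(sym$p_value, 0.1)
  tie <- mann_whitney(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(tie$p_value, 1)
  expect_equal(tie$u_statistic, 8)
  expect_error(mann_whitney(numeric(), 1:3),
               class = "goldrim_validation_error")
})

test_that("mann_whitney properties: U symmetry and exact = enumeration oracle", {
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(1:7, 1L); n2 <- sample(1:7, 1L)
    x <- sample(1:8, n1, replace = TRUE)    # integer data: ties are common
    y <- sample(1:8, n2, replace = TRUE)
    a <- mann_whitney(x, y, mode = "exact")
    b <- mann_whitney(y, x, mode = "exact")
    expect_equal(a$u_statistic + b$u_statistic, n1 * n2)
    expect_equal(a$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact test at moderate n", {
  set.seed(19)
  x <- rnorm(7); y <- rnorm(7) + 0.5
  pe <- mann_whitney(x, y, mode = "exact")$p_value
  pa <- mann_whitney(x, y, mode = "approx")$p_value
  expect_lt(abs(pe - pa), 0.05)
  big <- mann_whitney(rnorm(20), rnorm(20))
  expect_identical(big$method, "normal_approx")
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("rim-loaded vs background-only cohorts separate at pores, not elsewhere", {
  # Scaled-down power/type-I study: 12 replicate cohorts of 5 labeled vs 5
  # control images (small vesicles, coarse pixels to stay fast).  The
  # pore-region comparison should reject essentially always, the non-pore
  # comparison almost never.
  cohort_p <- function(seed) {
    cfgs <- list(
      labeled = run_config(seed = seed, n_vesicles = 5,
                           radius_range = c(50, 65),
                           pore_half_angle_range = c(0.6, 1.0),
                           tilt_range = c(0, 0.2), labeling_efficiency = 1,
                           background_area_density = 2e-4,
                           pixel_size = 0.5, margin = 10, z_step = 0.5),
      control = run_config(seed = seed + 5000L, n_vesicles = 5,
                           radius_range = c(50, 65),
                           pore_half_angle_range = c(0.6, 1.0),
                           tilt_range = c(0, 0.2), linear_density = 0,
                           background_area_density = 2e-4,
                           pixel_size = 0.5, margin = 10, z_step = 0.5))
    dens <- lapply(cfgs, function(cfg) {
      dir <- withr::local_tempdir()
      run_simulate(cfg, out_dir = dir)
      res <- run_measure(dir, withr::local_tempdir(), cfg)
      res$densities
    })
    get <- function(d, lbl) d$density[d$region_label == lbl]
    c(pore = mann_whitney(get(dens$labeled, "pore"),
                          get(dens$control, "pore"))$p_value,
      non_pore = mann_whitney(get(dens$labeled, "non_pore"),
                              get(dens$control, "non_pore"))$p_value)
  }
  ps <- vapply(1:12, cohort_p, numeric(2))
  expect_gte(mean(ps["pore", ] < 0.05), 0.95)
  expect_lte(mean(ps["non_pore", ] < 0.05), 0.10)
})
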