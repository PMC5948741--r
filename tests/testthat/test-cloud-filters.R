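# Cleaning filters, ground plane and calibration.

test_that("statistical filter removes exactly the isolated far point", {
  base <- grid_cloud(10, 10, spacing = 1)
  cl <- point_cloud(rbind(cbind(base$x, base$y, base$z), c(5, 5, 10)))
  out <- remove_statistical_outliers(cl, k = 10, std_ratio = 2)
  expect_identical(removed_indices(out), 101L)
  expect_identical(nrow(out), 100L)
  # brute-force oracle agrees on the k-NN statistics route
  d_oracle <- brute_knn_mean_dist(phenocloud:::cloud_xyz(cl), 10)
  thr <- mean(d_oracle) + 2 * sd(d_oracle)
  expect_identical(which(d_oracle > thr), 101L)
})

test_that("a perfectly homogeneous cloud loses nothing", {
  # all k-NN mean distances equal by symmetry -> zero spread, nothing removed
  cl <- ring_cloud(100)
  out <- remove_statistical_outliers(cl, k = 8, std_ratio = 2)
  expect_identical(nrow(out), nrow(cl))
  expect_length(removed_indices(out), 0L)
})

test_that("k >= n is an input error", {
  cl <- grid_cloud(3, 3)
  expect_error(remove_statistical_outliers(cl, k = 9),
               class = "phenocloud_input_error")
  expect_error(remove_statistical_outliers(cl, k = 20),
               class = "phenocloud_input_error")
})

test_that("kNN statistics agree with brute force on random clouds", {
  for (seed in 1:3) {
    xyz <- withr::with_seed(seed, matrix(runif(150 * 3, 0, 5), ncol = 3))
    got <- phenocloud:::cpp_knn(xyz, 6)$mean_dist
    expect_equal(got, brute_knn_mean_dist(xyz, 6), tolerance = 1e-12)
  }
})

test_that("grid filter uses closed-interval semantics at the 0.5 cm threshold", {
  sheet <- flat_sheet(10)
  cl <- point_cloud(rbind(
    c(5, 5, 0.4), c(4, 4, 0.5), c(6, 6, 0.6), c(5, 4, 0)
  ))
  out <- grid_distance_filter(cl, reference = sheet, max_dist_cm = 0.5)
  expect_identical(removed_indices(out), 3L)
  expect_equal(out$z, c(0.4, 0.5, 0))
})

test_that("grid filter edge cases: on-surface identity and zero threshold", {
  sheet <- flat_sheet(10)
  on_surf <- point_cloud(cbind(runif(20, 1, 9), runif(20, 1, 9), 0))
  expect_identical(nrow(grid_distance_filter(on_surf, sheet)), 20L)
  mixed <- point_cloud(rbind(c(2, 2, 0), c(3, 3, 1e-3)))
  out0 <- grid_distance_filter(mixed, sheet, max_dist_cm = 0)
  expect_identical(nrow(out0), 1L)
  uncal <- as_point_cloud(on_surf, unit_state = "uncalibrated")
  expect_error(grid_distance_filter(uncal, sheet),
               class = "phenocloud_unit_error")
})

test_that("filters are idempotent and order-preserving subsets", {
  base <- ring_cloud(120)
  cl <- point_cloud(rbind(cbind(base$x, base$y, base$z),
                          c(3, 3, 8), c(7, 7, -6)))
  once <- remove_statistical_outliers(cl, k = 10, std_ratio = 2)
  twice <- remove_statistical_outliers(once, k = 10, std_ratio = 2)
  expect_identical(phenocloud:::cloud_xyz(once), phenocloud:::cloud_xyz(twice))
  sheet <- flat_sheet(12)
  g1 <- grid_distance_filter(cl, sheet)
  g2 <- grid_distance_filter(g1, sheet)
  expect_identical(phenocloud:::cloud_xyz(g1), phenocloud:::cloud_xyz(g2))
  # survivors preserve input order
  expect_true(!is.unsorted(setdiff(seq_len(nrow(cl)), removed_indices(g1))))
  # local-plane variant: idempotent once the outliers are gone
  lp1 <- grid_distance_filter(cl, max_dist_cm = 0.5, k = 8)
  lp2 <- grid_distance_filter(lp1, max_dist_cm = 0.5, k = 8)
  expect_identical(phenocloud:::cloud_xyz(lp1), phenocloud:::cloud_xyz(lp2))
})

test_that("bounding-box crop separates a labelled neighbour", {
  m <- generate_dicot(8, n_leaves = 4, seed = 11)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 15, seed = 11))
  sc <- build_scene(cl, n_neighbors = 1, seed = 12, exclusion_radius_cm = 8)
  merged <- scene_cloud(sc)
  cal <- apply_scale(merged, calibrate_scale(sc$markers))
  lim <- 7.9
  out <- crop_bounding_box(cal, c(-lim, -lim, -1), c(lim, lim, 50))
  expect_false(any(out$source == "neighbor1"))
  expect_identical(sum(out$source == "plant"), sum(cal$source == "plant"))
  # box containing everything is the identity
  all_in <- crop_bounding_box(cal, rep(-1e4, 3), rep(1e4, 3))
  expect_identical(nrow(all_in), nrow(cal))
  expect_warning(crop_bounding_box(cal, c(1e5, 1e5, 1e5), c(1e6, 1e6, 1e6)),
                 "empty")
  expect_error(crop_bounding_box(cal, c(1, 1, 1), c(0, 2, 2)),
               class = "phenocloud_parameter_error")
})

test_that("ground plane fit recovers exact and noisy planes", {
  flat <- grid_cloud(20, 20)
  pl <- fit_ground_plane(flat, seed = 1)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$offset, 0, tolerance = 1e-9)

  noisy <- withr::with_seed(7, point_cloud(cbind(
    runif(500, 0, 20), runif(500, 0, 20), rnorm(500, 0, 0.05)
  )))
  pln <- fit_ground_plane(noisy, seed = 2)
  # within 1 degree of vertical and of the total-least-squares oracle
  oracle <- phenocloud:::tls_plane(phenocloud:::cloud_xyz(noisy))
  expect_gt(abs(sum(pln$normal * c(0, 0, 1))), cos(pi / 180))
  expect_gt(abs(sum(pln$normal * oracle$normal)), cos(pi / 180))

  three <- point_cloud(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)))
  p3 <- fit_ground_plane(three, seed = 3)
  expect_equal(abs(p3$normal[3]), 1, tolerance = 1e-12)
  expect_equal(p3$offset * sign(p3$normal[3]), 1, tolerance = 1e-12)

  collinear <- point_cloud(cbind(1:5, 1:5, 1:5))
  expect_error(fit_ground_plane(collinear, seed = 4),
               class = "phenocloud_degenerate_error")
  expect_error(fit_ground_plane(point_cloud(rbind(c(0, 0, 0), c(1, 1, 1))),
                                seed = 5),
               class = "phenocloud_degenerate_error")
})

test_that("scale calibration: worked examples and error cases", {
  one <- tibble::tibble(ax = 0, ay = 0, az = 0, bx = 5, by = 0, bz = 0)
  est <- calibrate_scale(one)  # true length defaults to 10 cm
  expect_identical(est$cm_per_unit, 2)
  expect_identical(est$residual_pct, 0)

  three <- tibble::tibble(
    ax = 0, ay = c(0, 1, 2), az = 0,
    bx = 10 / c(1.9, 2.0, 2.1), by = c(0, 1, 2), bz = 0,
    true_length_cm = 10
  )
  est3 <- calibrate_scale(three)
  expect_equal(est3$cm_per_unit, 2, tolerance = 1e-12)
  expect_equal(est3$residual_pct, 5, tolerance = 1e-12)
  expect_equal(est3$cm_per_unit, mean(est3$per_marker_ratios), tolerance = 1e-12)

  coincident <- tibble::tibble(ax = 1, ay = 1, az = 1, bx = 1, by = 1, bz = 1)
  expect_error(calibrate_scale(coincident),
               class = "phenocloud_degenerate_error")
})

test_that("calibration is exact on noiseless scenes across the scale range", {
  m <- generate_dicot(9, n_leaves = 4, seed = 21)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 10, seed = 21))
  for (s in c(0.1, 1, 2, 37.5, 100)) {
    sc <- build_scene(cl, scale_factor = s, seed = 22)
    est <- calibrate_scale(sc$markers)
    expect_equal(est$cm_per_unit, s, tolerance = 1e-12)
    expect_lt(est$residual_pct, 1e-9)
    back <- apply_scale(sc$plant, est)
    expect_equal(back$x, cl$x, tolerance = 1e-9)
    expect_equal(back$z, cl$z, tolerance = 1e-9)
  }
})

test_that("apply_scale transforms coordinates and guards unit state", {
  cl <- as_point_cloud(point_cloud(rbind(c(1, 1, 1))), unit_state = "uncalibrated")
  out <- apply_scale(cl, 2)
  expect_equal(phenocloud:::cloud_xyz(out)[1, ], c(2, 2, 2))
  expect_identical(unit_state(out), "cm")
  expect_error(apply_scale(out, 2), class = "phenocloud_unit_error")
  id <- apply_scale(as_point_cloud(point_cloud(rbind(c(3, 4, 5))),
                                   unit_state = "uncalibrated"), 1)
  expect_equal(phenocloud:::cloud_xyz(id)[1, ], c(3, 4, 5))
})
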