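# Point-cloud degradation: clean sampling lies on the surface, ghost points
# and tip dropout follow their seeded draws exactly, everything deterministic.

test_that("undegraded samples lie exactly on the mesh surface", {
  m <- generate_dicot(10, n_leaves = 4, seed = 5)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 30, seed = 2))
  d <- phenocloud:::cpp_point_mesh_dist(cbind(cl$x, cl$y, cl$z),
                                        m$mesh$vertices, m$mesh$faces)
  expect_lt(max(d), 1e-9)
})

test_that("ghost-point count matches the seeded draw exactly", {
  sheet <- flat_sheet(side = 6)  # 36 cm^2 -> ~1080 samples at density 30
  spec <- degradation_spec(point_density = 30, outlier_rate = 0.02, seed = 9)
  cl <- sample_point_cloud(sheet, spec)
  d <- phenocloud:::cpp_point_mesh_dist(cbind(cl$x, cl$y, cl$z),
                                        sheet$vertices, sheet$faces)
  n_far <- sum(d > 1)
  # oracle: re-run the same seeded sampler and take its own outlier labels
  cl2 <- sample_point_cloud(sheet, spec)
  expect_identical(n_far, sum(cl2$is_outlier))
  expect_identical(n_far, as.integer(round(0.02 * nrow(cl))))
  # displacements stay in the specified 2-10 cm band
  expect_true(all(d[cl$is_outlier] >= 2 - 1e-9 & d[cl$is_outlier] <= 10 + 1e-9))
})

test_that("tip dropout removes the distal share of each leaf's samples", {
  m <- generate_dicot(14, n_leaves = 5, seed = 8)
  full <- sample_point_cloud(m, degradation_spec(point_density = 120, seed = 3))
  drop5 <- sample_point_cloud(m, degradation_spec(
    point_density = 120, tip_dropout_fraction = 0.05, tip_dropout_jitter = 0,
    seed = 3
  ))
  leaf_full <- sum(full$component > 0)
  leaf_drop <- sum(drop5$component > 0)
  # surviving leaf support ~ 95% of leaf area, within Monte-Carlo error
  expect_equal(leaf_drop / leaf_full, 0.95, tolerance = 0.015)
  # removed samples are exactly those beyond the analytic threshold
  u_star <- phenocloud:::leaf_tip_threshold(0.05, "dicot")
  expect_true(all(drop5$u[drop5$component > 0] <= u_star + 1e-12))
})

test_that("tip-threshold inversion agrees with the area profile", {
  for (f in c(0.01, 0.05, 0.2, 0.5)) {
    for (morph in c("dicot", "monocot")) {
      t_star <- phenocloud:::leaf_tip_threshold(f, morph)
      expect_equal(phenocloud:::leaf_tip_area_fraction(t_star, morph), f,
                   tolerance = 1e-9)
    }
  }
  expect_equal(phenocloud:::leaf_tip_threshold(0, "dicot"), 1)
  expect_equal(phenocloud:::leaf_tip_threshold(1, "monocot"), 0)
})

test_that("sampling is deterministic and validates its inputs", {
  m <- generate_monocot(18, leaf_width_cm = 0.9, seed = 2)
  spec <- degradation_spec(point_density = 25, noise_sigma_cm = 0.05, seed = 7)
  a <- sample_point_cloud(m, spec)
  b <- sample_point_cloud(m, spec)
  expect_identical(a$x, b$x)
  expect_identical(a$z, b$z)
  empty <- triangle_mesh(matrix(0, 0, 3), NULL)
  expect_error(sample_point_cloud(empty, spec), class = "phenocloud_input_error")
  expect_error(degradation_spec(outlier_rate = 1.5),
               class = "phenocloud_parameter_error")
  expect_error(degradation_spec(point_density = 0),
               class = "phenocloud_parameter_error")
})

test_that("degrade_mesh reports exact retained leaf areas", {
  m <- generate_monocot(20, leaf_width_cm = 1, seed = 6)
  rec <- degrade_mesh(m, tip_dropout_fraction = 0.1, tip_dropout_jitter = 0,
                      warp_amplitude_cm = 0, seed = 4)
  retained <- attr(rec, "leaf_area_retained_cm2")
  expect_equal(retained, 0.9 * m$per_leaf_areas_cm2, tolerance = 1e-9)
  fa <- phenocloud:::face_areas(rec)
  comp <- rec$vertex_component[rec$faces[, 1]]
  for (i in seq_along(retained)) {
    expect_equal(sum(fa[comp == i]), retained[i], tolerance = 1e-3)
  }
})
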