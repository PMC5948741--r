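# The generator's contract: exact constructor traits, analytic leaf areas
# matched by the tessellated mesh, and bit-level determinism.

test_that("constructor height is exact and truth areas are self-consistent", {
  cases <- list(
    generate_dicot(12, n_leaves = 6, seed = 7),
    generate_dicot(7.25, n_leaves = 4, seed = 1),
    generate_monocot(20, n_leaves = 5, seed = 3)
  )
  expect_equal(cases[[1]]$truth_height_cm, 12.0)
  expect_equal(cases[[2]]$truth_height_cm, 7.25)
  expect_equal(cases[[3]]$truth_height_cm, 20.0)
  for (m in cases) {
    expect_equal(m$truth_leaf_area_cm2, sum(m$per_leaf_areas_cm2),
                 tolerance = 1e-9)
    expect_true(all(m$per_leaf_areas_cm2 > 0))
    expect_true(all(is.finite(m$mesh$vertices)))
    expect_gt(min(phenocloud:::face_areas(m$mesh)), 0)
  }
})

test_that("per-leaf mesh triangle sums match analytic areas within 0.1%", {
  for (seed in c(2, 11, 23)) {
    for (morph in c("dicot", "monocot")) {
      m <- if (morph == "dicot") {
        generate_dicot(runif(1, 5, 25), n_leaves = 5, seed = seed)
      } else {
        h <- runif(1, 12, 28)
        generate_monocot(h, n_leaves = 4, leaf_width_cm = 0.05 * h,
                         seed = seed)
      }
      fa <- phenocloud:::face_areas(m$mesh)
      comp <- m$mesh$vertex_component[m$mesh$faces[, 1]]
      for (i in seq_along(m$per_leaf_areas_cm2)) {
        tri <- sum(fa[comp == i])
        expect_equal(tri, m$per_leaf_areas_cm2[i],
                     tolerance = 1e-3,
                     label = sprintf("%s seed %d leaf %d", morph, seed, i))
      }
    }
  }
})

test_that("whole-mesh area equals leaf area plus stem lateral area", {
  m <- generate_dicot(15, seed = 4)
  expect_equal(mesh_surface_area(m$mesh),
               m$truth_leaf_area_cm2 + m$stem_area_cm2,
               tolerance = 5e-3)
  mo <- generate_monocot(22, leaf_width_cm = 1.1, seed = 4)
  expect_equal(mesh_surface_area(mo$mesh),
               mo$truth_leaf_area_cm2 + mo$stem_area_cm2,
               tolerance = 5e-3)
})

test_that("identical seeds give bit-identical plants", {
  a <- generate_dicot(9.5, n_leaves = 5, seed = 42)
  b <- generate_dicot(9.5, n_leaves = 5, seed = 42)
  expect_mesh_equal(a$mesh, b$mesh)
  expect_identical(a$per_leaf_areas_cm2, b$per_leaf_areas_cm2)
  c_ <- generate_dicot(9.5, n_leaves = 5, seed = 43)
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("monocot leaves respect the minimum aspect ratio", {
  m <- generate_monocot(20, n_leaves = 5, leaf_width_cm = 1.0, seed = 3)
  aspect <- m$params$leaf_length_cm / m$params$leaf_width_cm
  expect_true(all(aspect >= 10))
  expect_error(generate_monocot(10, leaf_width_cm = 2, seed = 1),
               class = "phenocloud_parameter_error")
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_dicot(-3, seed = 1), class = "phenocloud_parameter_error")
  expect_error(generate_dicot(10, n_leaves = 0, seed = 1),
               class = "phenocloud_parameter_error")
  expect_error(generate_monocot(0, seed = 1), class = "phenocloud_parameter_error")
})

test_that("heights drawn by the simulator stay in the configured range", {
  sp <- phenocloud:::species_table()
  expect_true(all(sp$height_min >= 4) && all(sp$height_max <= 30))
})
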