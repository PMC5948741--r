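# Trait extraction: mesh areas, the cylindrical height method, provenance.

test_that("mesh surface area: exact micro-cases", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1L, 2L, 3L), 1))
  expect_identical(mesh_surface_area(tri), 0.5)
  sq <- flat_sheet(1)
  expect_identical(mesh_surface_area(sq), 1)
  empty <- triangle_mesh(matrix(0, 0, 3), NULL)
  expect_warning(a0 <- mesh_surface_area(empty), "no faces")
  expect_identical(a0, 0)
})

test_that("surface area is rigid-motion invariant and scales as s^2", {
  m <- generate_dicot(11, n_leaves = 4, seed = 31)
  a0 <- mesh_surface_area(m$mesh)
  for (seed in 1:3) {
    rt <- withr::with_seed(seed, {
      ax <- runif(3, -1, 1)
      list(rot = phenocloud:::rotation_about_axis(ax, runif(1, 0, 2 * pi)),
           tr = runif(3, -50, 50))
    })
    moved <- transform_mesh(m$mesh, rotation = rt$rot, translation = rt$tr)
    expect_equal(mesh_surface_area(moved), a0, tolerance = 1e-9)
  }
  for (s in c(0.5, 2, 10)) {
    scaled <- transform_mesh(m$mesh, scale = s)
    expect_equal(mesh_surface_area(scaled), a0 * s^2, tolerance = 1e-9)
  }
})

test_that("height of a noiseless dense dicot is recovered to 0.05 cm", {
  m <- generate_dicot(12, n_leaves = 6, seed = 7)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 200, seed = 7))
  g <- plane(c(0, 0, 1), 0)
  h <- estimate_plant_height(cl, g)
  expect_equal(h, 12, tolerance = 0.05 / 12)
})

test_that("height scales linearly under uniform scaling", {
  m <- generate_dicot(10, n_leaves = 5, seed = 13)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 120, seed = 13))
  g <- plane(c(0, 0, 1), 0)
  h1 <- estimate_plant_height(cl, g)
  # the method's length parameters scale along with the cloud
  for (s in c(0.5, 2, 10)) {
    scl <- point_cloud(phenocloud:::cloud_xyz(cl) * s)
    hs <- estimate_plant_height(scl, g, stem_radius_cm = s, bin_cm = s,
                                base_slab_cm = s * c(0.5, 2.5))
    expect_equal(hs, h1 * s, tolerance = 1e-9)
  }
})

test_that("single point and degenerate clouds give zero height", {
  g <- plane(c(0, 0, 1), 0)
  one <- point_cloud(rbind(c(0, 0, 5)))
  expect_identical(estimate_plant_height(one, g), 0)
  below <- point_cloud(rbind(c(0, 0, -2)))
  expect_identical(estimate_plant_height(below, g), 0)
  expect_error(estimate_plant_height(point_cloud(matrix(0, 0, 3)), g),
               class = "phenocloud_input_error")
})

test_that("a stem tilted 30 degrees is truncated by the cylinder method", {
  h_true <- 12
  cl <- stem_tube_cloud(height = h_true)
  rot <- phenocloud:::rotation_about_axis(c(0, 1, 0), 30 * pi / 180)
  tilted <- point_cloud(phenocloud:::cloud_xyz(cl) %*% t(rot))
  g <- plane(c(0, 0, 1), 0)
  h_max <- estimate_plant_height(tilted, g, method = "max_extent")
  expect_equal(h_max, h_true * cos(30 * pi / 180), tolerance = 0.02)
  h_cyl <- estimate_plant_height(tilted, g, method = "cylinder")
  expect_lte(h_cyl, h_max + 1e-9)
  expect_lt(h_cyl, 0.9 * h_true * cos(30 * pi / 180))
})

test_that("height ignores added points far from the axis and low", {
  cl <- stem_tube_cloud(height = 10)
  g <- plane(c(0, 0, 1), 0)
  h0 <- estimate_plant_height(cl, g)
  extra <- rbind(c(5, 5, 3), c(-6, 2, 8), c(4, -4, 0.1))
  aug <- point_cloud(rbind(phenocloud:::cloud_xyz(cl), extra))
  expect_identical(estimate_plant_height(aug, g), h0)
})

test_that("extract_traits recovers noiseless truth within 1%", {
  m <- generate_dicot(9, n_leaves = 5, seed = 17)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 150, seed = 17))
  g <- plane(c(0, 0, 1), 0)
  tr <- extract_traits(cl, m$mesh, g, config = list(plant_id = "p1"))
  expect_equal(tr$est_height_cm, 9, tolerance = 0.01)
  expect_equal(tr$est_leaf_area_cm2 - m$stem_area_cm2, m$truth_leaf_area_cm2,
               tolerance = 0.01)
  expect_identical(tr$plant_id, "p1")
})

test_that("extract_traits handles a missing mesh and round-trips flags", {
  m <- generate_dicot(8, n_leaves = 4, seed = 19)
  cl <- sample_point_cloud(m, degradation_spec(point_density = 60, seed = 19))
  g <- plane(c(0, 0, 1), 0)
  expect_warning(tr <- extract_traits(cl, NULL, g), "No mesh")
  expect_identical(tr$est_leaf_area_cm2, 0)
  expect_gt(tr$est_height_cm, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(back$method_flags, tr$method_flags)
  flags <- jsonlite::fromJSON(back$method_flags)
  expect_identical(flags$height_method, "cylinder")
  expect_equal(flags$stem_radius_cm, 1)
})

test_that("estimated leaf area decreases as tip dropout grows", {
  m <- generate_monocot(20, leaf_width_cm = 1, seed = 23)
  mean_area <- function(f) {
    mean(vapply(1:4, function(s) {
      mesh_surface_area(degrade_mesh(m, tip_dropout_fraction = f,
                                     warp_amplitude_cm = 0, seed = s))
    }, numeric(1)))
  }
  areas <- vapply(c(0, 0.05, 0.15, 0.3), mean_area, numeric(1))
  expect_true(all(diff(areas) < 0))
})
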