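# 2D leaf-area pipeline: index arithmetic, Otsu, square detection, recovery.

ga <- coeffs_preset("ga2018")

solid_image <- function(h, w, rgb) {
  rgb_image(array(rep(rgb, each = h * w), c(h, w, 3)))
}

test_that("linear index matches forced arithmetic on the presets", {
  green <- solid_image(2, 2, c(0, 255, 0))
  expect_equal(linear_index(green, ga)[1, 1], 1.262 * 255, tolerance = 1e-12)
  white <- solid_image(2, 2, c(255, 255, 255))
  expect_equal(linear_index(white, ga)[1, 1], (-0.884 + 1.262 - 0.311) * 255,
               tolerance = 1e-12)
  px <- solid_image(1, 1, c(100, 150, 50))
  expect_identical(linear_index(px, coeffs_preset("exg"))[1, 1], 150)
  expect_error(segmentation_coefficients(0, 0, 0),
               class = "phenocloud_parameter_error")
})

test_that("linear index is linear in the coefficients", {
  img <- withr::with_seed(5, rgb_image(array(sample(0:255, 300, TRUE),
                                             c(10, 10, 3))))
  co <- segmentation_coefficients(-0.5, 1.3, -0.2)
  co3 <- segmentation_coefficients(-1.5, 3.9, -0.6)
  expect_equal(linear_index(img, co3), 3 * linear_index(img, co),
               tolerance = 1e-12)
})

test_that("otsu separates a two-valued image exactly", {
  v <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(v)
  expect_gt(t, 0)
  expect_lt(t, 200)
  mask <- binarize(v, t)
  expect_identical(sum(mask), 50L)
  expect_true(all(v[mask] == 200))
})

test_that("otsu equals the exhaustive bin-edge oracle on random images", {
  for (seed in 1:40) {
    v <- withr::with_seed(seed, {
      n <- sample(50:400, 1)
      # bimodal-ish mixtures with occasional uniform junk
      if (seed %% 4 == 0) runif(n, -30, 500) else
        c(rnorm(n, 10, 4), rnorm(n %/% 2, 120, 15))
    })
    m <- matrix(v, nrow = 1)
    expect_identical(otsu_threshold(m), brute_otsu(v),
                     label = paste("seed", seed))
  }
})

test_that("otsu rejects constant images", {
  expect_error(otsu_threshold(matrix(5, 3, 3)),
               class = "phenocloud_degenerate_error")
})

test_that("binarize respects threshold extremes and scaling invariance", {
  v <- matrix(c(0, 200, 50, 130), 2, 2)
  expect_true(all(binarize(v, -1)))
  expect_false(any(binarize(v, 201)))
  expect_identical(which(binarize(v, 100)), which(v > 100))
  for (a in c(0.5, 3)) {
    expect_identical(which(binarize(a * v, a * 100)),
                     which(binarize(v, 100)))
  }
})

test_that("reference square detection: size, absence, and squareness", {
  img <- array(255L, c(300, 400, 3))
  img[51:250, 101:300, ] <- 0L  # 200 x 200 square
  sq <- detect_reference_square(rgb_image(img))
  expect_identical(sq$n_pixels, 40000L)
  expect_identical(sq$px_per_cm2, 400)

  expect_error(detect_reference_square(solid_image(50, 50, c(255, 255, 255))),
               class = "phenocloud_detection_error")

  # add a thin dark scale bar: the square must still win
  img[10:14, 5:395, ] <- 0L
  sq2 <- detect_reference_square(rgb_image(img))
  expect_identical(sq2$n_pixels, 40000L)
  expect_equal(unname(sq2$bbox), c(51, 250, 101, 300))
})

test_that("leaf area formula on constructed pixel counts", {
  # 40,000 px square (400 px/cm^2) + 20,000 green pixels -> 50 cm^2
  img <- array(255L, c(400, 500, 3))
  img[101:300, 51:250, ] <- 0L
  img[1:100, 301:500, 1] <- 60L
  img[1:100, 301:500, 2] <- 160L
  img[1:100, 301:500, 3] <- 50L
  area <- leaf_area_from_image(rgb_image(img))
  expect_equal(as.numeric(area), 50, tolerance = 1e-12)
  expect_identical(attr(area, "foreground_px"), 20000L)
})

test_that("rendered layouts recover generator truth, including the ~116 cm2 regime", {
  m0 <- generate_dicot(12, n_leaves = 6, seed = 7)
  # rescale leaves so the plant sits at the 116.34 cm^2 regime
  scale_leaf <- 0.75 * sqrt(116.34 / m0$truth_leaf_area_cm2)
  m <- generate_dicot(12, n_leaves = 6, leaf_scale = scale_leaf, seed = 7)
  expect_equal(m$truth_leaf_area_cm2, 116.34, tolerance = 0.01)
  img <- render_leaf_layout(m, px_per_cm = 20, seed = 2)
  expect_identical(attr(img, "square_px"), 40000)
  # silhouette pixel count within 1% of truth * px^2
  expect_equal(attr(img, "plant_px") / 400, m$truth_leaf_area_cm2,
               tolerance = 0.01)
  area <- leaf_area_from_image(img)
  expect_equal(as.numeric(area), m$truth_leaf_area_cm2, tolerance = 0.02)
})

test_that("a zero-leaf plant renders a square-only image with zero area", {
  m <- generate_dicot(10, n_leaves = 1, seed = 3)
  m$per_leaf_areas_cm2 <- numeric(0)
  m$params$leaf_length_cm <- numeric(0)
  m$truth_leaf_area_cm2 <- 0
  img <- render_leaf_layout(m, px_per_cm = 10, seed = 1)
  expect_identical(attr(img, "plant_px"), 0L)
  expect_equal(as.numeric(leaf_area_from_image(img)), 0)
})

test_that("recovered area is invariant to translating the layout", {
  m <- generate_dicot(8, n_leaves = 3, seed = 9)
  img <- render_leaf_layout(m, px_per_cm = 12, seed = 4)
  a0 <- leaf_area_from_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  big <- array(255L, c(h + 37, w + 11, 3))
  big[21 + seq_len(h), 6 + seq_len(w), ] <- unclass(img)
  a1 <- leaf_area_from_image(rgb_image(big))
  expect_identical(as.numeric(a1), as.numeric(a0))
})

test_that("doubling the resolution changes recovered area by < 0.5%", {
  m <- generate_dicot(9, n_leaves = 4, seed = 6)
  a20 <- as.numeric(leaf_area_from_image(render_leaf_layout(m, 20, seed = 5)))
  a40 <- as.numeric(leaf_area_from_image(render_leaf_layout(m, 40, seed = 5)))
  expect_lt(abs(a40 - a20) / a20, 0.005)
})

test_that("px_per_cm below 5 and impossible packings are rejected", {
  m <- generate_dicot(10, n_leaves = 4, seed = 2)
  expect_error(render_leaf_layout(m, px_per_cm = 3),
               class = "phenocloud_parameter_error")
  expect_error(render_leaf_layout(m, px_per_cm = 200, canvas_max_px = 300),
               class = "phenocloud_layout_error")
})

test_that("4-connected labelling agrees with an independent labeller", {
  skip_if_not_installed("EBImage")
  for (seed in 1:3) {
    mask <- withr::with_seed(seed, matrix(runif(40 * 30) < 0.35, 40, 30))
    ours <- phenocloud:::cpp_label4(mask)
    ref <- EBImage::bwlabel(ifelse(mask, 1, 0))
    # same partition: component count and a consistent relabelling
    expect_identical(max(ours), as.integer(max(ref)))
    expect_identical(ours > 0, mask)
    key <- paste(ours[mask], ref[mask])
    expect_identical(length(unique(key)), max(ours))
  }
})
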