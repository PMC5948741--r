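# Validation statistics: closed-form micro-examples, oracle agreement,
# distributional properties.

pairs_df <- function(a, e) tibble::tibble(actual = a, estimated = e)

test_that("pearson r on worked micro-examples", {
  expect_equal(pearson_r(pairs_df(c(1, 2, 3), c(1, 2, 3))), 1, tolerance = 1e-12)
  expect_equal(pearson_r(pairs_df(c(1, 2, 3), c(-1, -2, -3))), -1,
               tolerance = 1e-12)
  expect_equal(pearson_r(pairs_df(c(1, 2, 3), c(2, 4, 6))), 1, tolerance = 1e-12)
  expect_error(pearson_r(pairs_df(c(2, 2, 2), c(1, 2, 3))),
               class = "phenocloud_degenerate_error")
})

test_that("linear fit on exact affine data and against the normal equations", {
  f <- linear_fit(pairs_df(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  f2 <- linear_fit(pairs_df(c(1, 2, 4), 2 * c(1, 2, 4) + 3))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 3, tolerance = 1e-12)
  for (seed in 1:100) {
    d <- withr::with_seed(seed, {
      a <- runif(50, 0, 100)
      pairs_df(a, 0.8 * a + rnorm(50, 0, 5))
    })
    got <- linear_fit(d)
    want <- normal_eq_fit(d$actual, d$estimated)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, pearson_r(d)^2, tolerance = 1e-12)
  }
})

test_that("rmse on worked micro-examples and permutation invariance", {
  expect_identical(rmse(pairs_df(c(1, 2), c(1, 2))), 0)
  expect_equal(rmse(pairs_df(c(4, 8, 12), c(5, 7, 13))), 1, tolerance = 1e-12)
  expect_equal(rmse(pairs_df(10, 12)), 2, tolerance = 1e-12)
  d <- withr::with_seed(3, pairs_df(runif(20, 1, 9), runif(20, 1, 9)))
  perm <- withr::with_seed(4, sample(20))
  expect_equal(rmse(d), rmse(d[perm, ]), tolerance = 1e-12)
})

test_that("percentage errors: signed vs absolute", {
  pe <- percentage_errors(pairs_df(c(10, 20), c(11, 18)))
  expect_equal(pe$mpe_pct, 0, tolerance = 1e-12)
  expect_equal(pe$mape_pct, 10, tolerance = 1e-12)
  expect_identical(percentage_errors(pairs_df(c(3, 7), c(3, 7))),
                   list(mpe_pct = 0, mape_pct = 0))
  pe1 <- percentage_errors(pairs_df(100, 95))
  expect_equal(pe1$mpe_pct, -5, tolerance = 1e-12)
  expect_equal(pe1$mape_pct, 5, tolerance = 1e-12)
  err <- expect_error(
    percentage_errors(tibble::tibble(actual = c(1, 0), estimated = c(1, 1),
                                     id = c("ok", "bad")), label = id),
    class = "phenocloud_input_error"
  )
  expect_match(conditionMessage(err), "bad")
})

test_that("mape >= |mpe| and pearson is affine-invariant (property)", {
  for (seed in 1:25) {
    d <- withr::with_seed(seed, pairs_df(runif(30, 5, 50),
                                         runif(30, 5, 50)))
    pe <- percentage_errors(d)
    expect_gte(pe$mape_pct, abs(pe$mpe_pct))
    a <- withr::with_seed(seed + 100, runif(2, 0.1, 4))
    d2 <- pairs_df(a[1] * d$actual + 7, a[2] * d$estimated + 1)
    expect_equal(pearson_r(d2), pearson_r(d), tolerance = 1e-12)
  }
})

test_that("validation report bundles consistent statistics", {
  d <- pairs_df(c(2, 4, 6, 9), c(2, 4, 6, 9))
  rep <- validation_report(d, trait = "height")
  expect_identical(rep$n, 4L)
  expect_equal(rep$pearson_r, 1, tolerance = 1e-12)
  expect_equal(rep$rmse, 0, tolerance = 1e-12)
  expect_equal(rep$mape_pct, 0, tolerance = 1e-12)
  td <- tidy(rep)
  expect_identical(nrow(td), 1L)
  expect_identical(td$trait, "height")
  expect_equal(tidy(rep), glance(rep))
  for (seed in 1:100) {
    d <- withr::with_seed(seed, pairs_df(runif(15, 1, 30),
                                         runif(15, 1, 30)))
    r <- validation_report(d)
    expect_equal(r$r_squared, r$pearson_r^2, tolerance = 1e-12)
    expect_gte(r$mape_pct, abs(r$mpe_pct))
  }
})

test_that("reports round-trip through JSON", {
  d <- withr::with_seed(9, pairs_df(runif(12, 2, 20), runif(12, 2, 20)))
  rep <- validation_report(d, trait = "leaf_area")
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(rep, path)
  back <- read_validation_json(path)
  for (f in c("n", "pearson_r", "r_squared", "slope", "intercept", "rmse",
              "mpe_pct", "mape_pct", "trait")) {
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12, label = f)
  }
  expect_equal(as.data.frame(back$data), as.data.frame(rep$data),
               tolerance = 1e-12)
})

test_that("autoplot returns a ggplot scatter", {
  d <- pairs_df(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  p <- ggplot2::autoplot(validation_report(d))
  expect_s3_class(p, "ggplot")
})
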