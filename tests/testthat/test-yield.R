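# Vine aggregation, area-weight regression, prediction

make_records <- function(areas, yields = NULL, zone = "HV") {
  data.frame(vine_id = paste0("v", seq_along(areas)), vigor_zone = zone,
             condition = "B", total_cluster_area_cm2 = areas,
             detected_count = 1L, adjusted_count = 1L,
             observed_count = NA_integer_, green_count = NA_integer_,
             measured_yield_g = if (is.null(yields)) NA_real_ else yields)
}

test_that("vine aggregation sums retained areas and copies counts", {
  m <- matrix(FALSE, 60, 120)
  m[3:42, 3:52] <- TRUE     # 2000 px = 80 cm2 at 5 px/cm
  m[10:34, 70:109] <- TRUE  # 1000 px = 40 cm2
  lc <- label_components(m, 8)
  ps <- measure_particles(lc, scale_calibration(pixels_per_cm = 5))
  ps <- adjust_double_clusters(ps, 10)  # no doubles at this factor
  rec <- aggregate_vine(ps, "v1", zone = "HV", condition = "B",
                        observed_count = 3L, green_count = 1L)
  expect_equal(rec$total_cluster_area_cm2, 120)
  expect_equal(rec$detected_count, 2L)
  expect_equal(rec$adjusted_count, 2L)
  expect_equal(rec$vigor_zone, "HV")

  empty <- measure_particles(label_components(matrix(FALSE, 4, 4), 8),
                             scale_calibration(pixels_per_cm = 5))
  rec0 <- aggregate_vine(empty, "v2")
  expect_equal(rec0$total_cluster_area_cm2, 0)
  expect_equal(rec0$detected_count, 0L)

  expect_error(aggregate_vine(ps, "v3", observed_count = 2L, green_count = 3L),
               "green_count")
})

test_that("noiseless data are recovered exactly", {
  areas <- seq(10, 100, by = 10)
  fit <- fit_area_weight_regression(make_records(areas, 4 * areas + 10))
  expect_equal(fit$slope, 4, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_train, 10L)
})

test_that("a hand-computed OLS fit matches", {
  fit <- fit_area_weight_regression(make_records(c(0, 1, 2), c(0, 1, 3)))
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -1 / 6, tolerance = 1e-12)
})

test_that("fits agree with the closed-form normal equations", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    x <- runif(n, 0, 300)
    y <- 3 * x + rnorm(n, 0, 40)
    fit <- fit_area_weight_regression(make_records(x, y))
    ref <- oracle_ols(x, y)
    expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-9)
  }
})

test_that("degenerate training sets are refused", {
  expect_error(fit_area_weight_regression(make_records(10, 40)), "at least 2")
  expect_error(fit_area_weight_regression(make_records(c(5, 5, 5), c(1, 2, 3))),
               "degenerate")
})

test_that("simulated slope recovery is unbiased within 5%", {
  slopes <- vapply(1:500, function(s) {
    d <- generate_vine_records(n_per_zone = 5, true_slope = 4,
                               noise_frac = 0.15, seed = s)
    fit_area_weight_regression(d)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 4) / 4, 0.05)
  # the generating slope lies inside the empirical 95% band
  expect_gt(4, quantile(slopes, 0.025))
  expect_lt(4, quantile(slopes, 0.975))
})

test_that("prediction is affine, monotone and clamped at zero", {
  fit <- fit_area_weight_regression(make_records(c(10, 50, 90),
                                                 c(50, 210, 370)))
  # exact line y = 4x + 10
  expect_equal(predict_yield(fit, 100), 410)
  expect_equal(predict_yield(fit, 0), 10)
  est <- predict_yield(fit, c(10, 20, 80))
  expect_true(all(diff(est) > 0))

  neg <- fit_area_weight_regression(make_records(c(10, 20), c(10, 60)))
  expect_warning(out <- predict_yield(neg, 0), "clamped")
  expect_equal(out, 0)
})

test_that("training predictions reproduce fitted values exactly", {
  set.seed(32)
  rec <- make_records(runif(12, 10, 200))
  rec$measured_yield_g <- 4 * rec$total_cluster_area_cm2 + rnorm(12, 0, 30)
  fit <- fit_area_weight_regression(rec)
  est <- predict_yield(fit, rec)
  expect_equal(est, fit$slope * rec$total_cluster_area_cm2 + fit$intercept)
  expect_equal(1 - sum((rec$measured_yield_g - est)^2) /
                 sum((rec$measured_yield_g - mean(rec$measured_yield_g))^2),
               fit$r_squared, tolerance = 1e-12)
})

test_that("models round-trip through JSON", {
  fit <- fit_area_weight_regression(make_records(c(10, 50, 90),
                                                 c(52, 214, 366)),
                                    fit_meta = "season-1 B")
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$fit_meta, "season-1 B")
  expect_equal(predict_yield(back, 70), predict_yield(fit, 70))
})
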