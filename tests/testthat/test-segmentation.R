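# Histogram construction, Otsu thresholding, two-stage segmentation

test_that("histogram puts a two-point distribution in its extreme bins", {
  v <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  h <- build_histogram(scalar_channel(v))
  expect_equal(h$counts[1], 50)
  expect_equal(h$counts[256], 50)
  expect_equal(sum(h$counts), 100)
  expect_false(h$degenerate)
})

test_that("histogram conserves pixel counts and honours exclusions", {
  set.seed(5)
  v <- matrix(runif(1e4, -30, 45), 100, 100)
  h <- build_histogram(scalar_channel(v))
  expect_equal(sum(h$counts), 1e4)

  excl <- v > 0
  h2 <- build_histogram(scalar_channel(v), exclusion = excl)
  expect_equal(sum(h2$counts), sum(!excl))
  expect_lte(h2$bin_min + 256 * h2$bin_width, 0 + 1e-9)
})

test_that("degenerate and empty histograms are signalled", {
  v <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  h <- build_histogram(scalar_channel(v), exclusion = v == 255)
  expect_true(h$degenerate)
  expect_error(otsu_threshold(h), "degenerate")
  expect_error(build_histogram(scalar_channel(v), exclusion = v >= 0),
               "excluded")
})

test_that("a perfectly separable bimodal histogram splits between its modes", {
  v <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  h <- build_histogram(scalar_channel(v))
  t <- otsu_threshold(h)
  low_bin <- 0
  high_bin <- 255
  expect_gte(t$threshold_bin, low_bin)
  expect_lt(t$threshold_bin, high_bin)
  expect_equal(unname(t$class_fractions["low"]), 0.6)
  expect_equal(sum(t$class_fractions), 1, tolerance = 1e-12)
  expect_gt(t$threshold_value, 10)
  expect_lte(t$threshold_value, 200)
})

test_that("Otsu equals exhaustive within-class variance minimisation", {
  set.seed(42)
  for (rep in 1:200) {
    counts <- integer(256)
    k <- sample(2:12, 1)
    bins <- sample(0:255, k)
    counts[bins + 1] <- sample(1:200, k, replace = TRUE)
    h <- structure(list(counts = counts, bin_min = 0, bin_width = 1,
                        n_pixels = sum(counts), degenerate = FALSE),
                   class = "b_histogram")
    expect_identical(otsu_threshold(h)$threshold_bin, oracle_otsu(counts))
  }
})

test_that("Otsu separates two Gaussian pixel populations almost perfectly", {
  set.seed(7)
  vals <- c(rnorm(5000, 60, 10), rnorm(5000, 180, 10))
  truth <- rep(c(0, 1), each = 5000)
  ch <- scalar_channel(matrix(vals, 100, 100))
  h <- build_histogram(ch)
  t <- otsu_threshold(h)
  pred <- as.integer(vals > t$threshold_value)
  expect_lt(mean(pred != truth), 0.01)
})

test_that("threshold value shifts with a constant channel offset", {
  set.seed(9)
  vals <- matrix(c(rnorm(300, 10, 3), rnorm(300, 40, 3)), 20, 30)
  t1 <- otsu_threshold(build_histogram(scalar_channel(vals)))
  t2 <- otsu_threshold(build_histogram(scalar_channel(vals + 100)))
  bw <- (max(vals) - min(vals)) / 256
  expect_identical(t1$threshold_bin, t2$threshold_bin)
  expect_lt(abs((t2$threshold_value - 100) - t1$threshold_value), bw)
})

make_trimodal_channel <- function(seed = 1, n_cluster = 600) {
  set.seed(seed)
  n <- 10000
  n_fol <- 6500
  n_soil <- n - n_fol - n_cluster
  vals <- c(rnorm(n_fol, 30, 3), rnorm(n_soil, 10, 3), rnorm(n_cluster, -15, 3))
  labels <- rep(c("fol", "soil", "clu"), c(n_fol, n_soil, n_cluster))
  ord <- sample(n)
  list(channel = scalar_channel(matrix(vals[ord], 100, 100)),
       labels = matrix(labels[ord], 100, 100))
}

test_that("two-stage segmentation isolates the low-b* population", {
  tri <- make_trimodal_channel(seed = 3)
  m <- two_stage_segmentation(tri$channel)
  expect_identical(m$status, "ok")
  clu <- m$state == 1L
  expect_gte(sum(clu & tri$labels == "clu") / sum(tri$labels == "clu"), 0.99)
  # vegetation must be gone before stage 2
  expect_equal(sum(m$state == 2L & tri$labels == "fol") / sum(tri$labels == "fol"),
               1, tolerance = 0.01)
})

test_that("a scene with no cluster population yields few false positives", {
  sc <- generate_scene(scene_spec(n_clusters = 0, seed = 4))
  b <- gaussian_smooth(extract_b_channel(srgb_to_lab(sc$image)), 2)
  m <- two_stage_segmentation(b)
  expect_lt(sum(m$state == 1L) / length(m$state), 0.01)
})

test_that("the three mask labels partition the raster", {
  tri <- make_trimodal_channel(seed = 5)
  m <- two_stage_segmentation(tri$channel)
  expect_equal(sum(m$state == 0L) + sum(m$state == 1L) + sum(m$state == 2L),
               length(m$state))
  # stage-2 histogram covers exactly the non-vegetation pixels
  h2 <- build_histogram(tri$channel, exclusion = m$state == 2L)
  expect_equal(h2$n_pixels, length(m$state) - sum(m$state == 2L))
})

test_that("segmentation is deterministic", {
  tri <- make_trimodal_channel(seed = 6)
  m1 <- two_stage_segmentation(tri$channel)
  m2 <- two_stage_segmentation(tri$channel)
  expect_identical(m1, m2)
})

test_that("contrast-free images fail soft with a degenerate status", {
  m <- two_stage_segmentation(scalar_channel(matrix(5, 10, 10)))
  expect_identical(m$status, "degenerate_stage1")
  expect_equal(sum(m$state == 1L), 0)
})
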