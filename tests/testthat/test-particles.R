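# Connected components, morphometry, filtering, double-cluster adjustment

square_mask <- function(h, w, squares) {
  m <- matrix(FALSE, h, w)
  for (s in squares) m[s[1]:s[2], s[3]:s[4]] <- TRUE
  m
}

test_that("diagonal contact joins under 8-connectivity, splits under 4", {
  m <- square_mask(10, 10, list(c(1, 3, 1, 3), c(4, 6, 4, 6)))
  expect_equal(label_components(m, 8)$n_components, 1L)
  expect_equal(label_components(m, 4)$n_components, 2L)
})

test_that("separated squares are distinct components", {
  m <- square_mask(10, 12, list(c(1, 3, 1, 3), c(6, 8, 7, 9)))
  expect_equal(label_components(m, 8)$n_components, 2L)
})

test_that("a checkerboard is one component under 8-connectivity", {
  m <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_equal(label_components(m, 8)$n_components,
               oracle_count_components(m, 8))
  expect_equal(label_components(m, 8)$n_components, 1L)
})

test_that("component counts match a flood-fill oracle on random masks", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(runif(144) < 0.4, 12, 12)
    for (conn in c(4, 8)) {
      expect_equal(label_components(m, conn)$n_components,
                   oracle_count_components(m, conn))
    }
  }
})

test_that("labels are assigned in raster-scan order and conserve area", {
  set.seed(22)
  m <- matrix(runif(400) < 0.35, 20, 20)
  lc <- label_components(m, 8)
  expect_equal(sum(lc$labels > 0), sum(m))
  # row-major first occurrences must appear in increasing label order
  rm_order <- as.vector(t(lc$labels))
  firsts <- rm_order[rm_order > 0]
  expect_identical(unique(firsts), seq_len(lc$n_components))
})

test_that("a filled square has boundary-pixel perimeter and known circularity", {
  m <- square_mask(14, 14, list(c(3, 12, 3, 12)))  # 10 x 10 square
  ps <- measure_particles(label_components(m, 8))
  expect_equal(nrow(ps$particles), 1L)
  expect_equal(ps$particles$area_px, 100L)
  expect_equal(ps$particles$perimeter_px, 36)
  expect_equal(ps$particles$circularity, 4 * pi * 100 / 36^2, tolerance = 1e-12)
  expect_equal(ps$particles$centroid_row, 7.5)
  expect_equal(unlist(ps$particles[, c("bbox_min_row", "bbox_min_col",
                                       "bbox_max_row", "bbox_max_col")]),
               c(bbox_min_row = 3L, bbox_min_col = 3L,
                 bbox_max_row = 12L, bbox_max_col = 12L))
})

test_that("a rasterised disc is nearly circular", {
  r <- 30
  m <- outer(-40:40, -40:40, function(i, j) i^2 + j^2 <= r^2)
  ps <- measure_particles(label_components(m, 8))
  expect_gte(ps$particles$circularity, 0.9)
  expect_lte(ps$particles$circularity, 1.0)
})

test_that("calibration converts pixel areas to cm^2 quadratically", {
  cal <- scale_calibration(line_length_px = 100, known_length_cm = 20)
  expect_equal(cal$pixels_per_cm, 5)

  m <- square_mask(45, 45, list(c(3, 42, 18, 42)))  # 40 x 25 = 1000 px
  lc <- label_components(m, 8)
  ps <- measure_particles(lc, cal)
  expect_equal(ps$particles$area_px, 1000L)
  expect_equal(ps$particles$area_cm2, 40)

  ps2 <- measure_particles(lc, scale_calibration(pixels_per_cm = 10))
  expect_equal(ps$particles$area_cm2 / ps2$particles$area_cm2, 4)
})

test_that("uncalibrated sets have NA areas and are refused downstream", {
  m <- square_mask(30, 30, list(c(2, 25, 2, 25)))
  ps <- measure_particles(label_components(m, 8))
  expect_true(is.na(ps$particles$area_cm2))
  expect_error(aggregate_vine(ps, "v1"), "uncalibrated")
  expect_error(scale_calibration(pixels_per_cm = -1), "positive")
})

test_that("the area floor is inclusive at the boundary", {
  # 199 px and 200 px components (rows of a rectangle)
  m <- matrix(FALSE, 40, 60)
  m[3:12, 3:22] <- TRUE              # 200 px
  m[20:29, 30:49] <- TRUE            # 200 px
  m[20, 30] <- FALSE                 # second becomes 199 px
  ps <- measure_particles(label_components(m, 8))
  kept <- filter_particles(ps)
  expect_equal(kept$particles$area_px, 200L)
})

test_that("elongated lines fall outside the circularity window", {
  m <- matrix(FALSE, 10, 300)
  m[5, 3:298] <- TRUE
  ps <- measure_particles(label_components(m, 8))
  expect_lt(ps$particles$circularity, 0.25)
  expect_equal(nrow(filter_particles(ps)$particles), 0L)
})

test_that("filtering is monotone in its parameters and keeps measurements", {
  set.seed(23)
  m <- matrix(runif(120 * 120) < 0.45, 120, 120)
  ps <- measure_particles(label_components(m, 8))
  n_prev <- Inf
  for (floor_px in c(1, 5, 20, 100)) {
    n <- nrow(filter_particles(ps, min_area_px = floor_px,
                               circularity_range = c(0, 1))$particles)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  wide <- filter_particles(ps, min_area_px = 1, circularity_range = c(0.1, 1))
  narrow <- filter_particles(ps, min_area_px = 1, circularity_range = c(0.3, 1))
  expect_lte(nrow(narrow$particles), nrow(wide$particles))
  kept <- filter_particles(ps, min_area_px = 5)
  orig <- ps$particles[ps$particles$id %in% kept$particles$id, ]
  expect_equal(kept$particles, orig)
  expect_error(filter_particles(ps, circularity_range = c(1, 0.25)), "ordered")
  expect_equal(nrow(filter_particles(measure_particles(
    label_components(matrix(FALSE, 5, 5), 8)))$particles), 0L)
})

fake_particle_set <- function(areas_cm2) {
  n <- length(areas_cm2)
  df <- data.frame(id = seq_len(n),
                   area_px = as.integer(areas_cm2 * 25),
                   area_cm2 = areas_cm2, perimeter_px = rep(10, n),
                   circularity = rep(0.9, n), centroid_row = rep(1, n),
                   centroid_col = rep(1, n),
                   bbox_min_row = rep(1L, n), bbox_min_col = rep(1L, n),
                   bbox_max_row = rep(2L, n), bbox_max_col = rep(2L, n),
                   counts_as = rep(1L, n))
  vineyield:::.particle_set(df, "fake", scale_calibration(pixels_per_cm = 5))
}

test_that("oversized particles count as exactly two clusters", {
  ps <- adjust_double_clusters(fake_particle_set(c(10, 12, 11, 25)),
                               split_factor = 1.5)
  expect_equal(ps$adjusted_count, 5L)          # median 11.5; 25 > 17.25
  expect_equal(ps$particles$counts_as, c(1L, 1L, 1L, 2L))

  equal <- adjust_double_clusters(fake_particle_set(rep(8, 6)), 1.2)
  expect_equal(equal$adjusted_count, 6L)

  single <- adjust_double_clusters(fake_particle_set(42), 1.5)
  expect_equal(single$adjusted_count, 1L)

  empty <- adjust_double_clusters(fake_particle_set(numeric(0)), 1.5)
  expect_equal(empty$adjusted_count, 0L)
})

test_that("the count adjustment equals the number of oversized particles", {
  set.seed(24)
  for (rep in 1:25) {
    areas <- rlnorm(sample(1:12, 1), meanlog = 3, sdlog = 0.5)
    sf <- runif(1, 1.1, 2.5)
    ps <- adjust_double_clusters(fake_particle_set(areas), sf)
    n_over <- sum(areas > sf * median(areas))
    expect_equal(ps$adjusted_count - length(areas), n_over)
    expect_gte(ps$adjusted_count, length(areas))
  }
})
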