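# Seeded synthetic vineyard fruiting-zone scenes with per-pixel and
# per-cluster ground truth.  The generator emulates what the detection
# pipeline sees in a canopy photograph taken obliquely at close range:
# a green foliage wall above, brown soil below, and dark blue-purple
# compound cluster blobs in the fruiting band, optionally occluded by
# foliage and darkened by dappled shadow.

.LABEL_LEVELS <- c("cluster", "foliage", "soil",
                   "shadowed-cluster", "shadowed-foliage", "shadowed-soil")

#' Specify a synthetic vineyard scene
#'
#' Defaults describe a 420 x 280 px fruiting-zone view in which 8 clusters
#' of base radius ~16 px cover about 5% of the pixels, foliage about 65%
#' and soil the rest — the pixel-class balance of an oblique fruiting-zone
#' photograph at roughly 2 mm ground sample distance.  Colours are sRGB
#' triplets for dark Sangiovese-like berries, sunlit canopy and dry soil.
#'
#' @param width,height Image size in pixels.
#' @param n_clusters Number of clusters to place.
#' @param cluster_radius_mean,cluster_radius_sd Base blob radius (px).
#' @param cluster_color,foliage_color,soil_color sRGB triplets (0-255).
#' @param color_jitter Per-cluster sRGB jitter standard deviation.
#' @param occlusion_fraction Fraction of each cluster's pixels overdrawn
#'   with foliage (leaf cover), in `[0, 1]`.
#' @param shadow_strength Multiplicative darkening of the scene (flat
#'   shade), in `[0, 1]`.
#' @param noise_sd Additive Gaussian sensor noise (intensity units).
#' @param min_gap_px Minimum clearance between rendered cluster blobs.
#' @param seed Integer seed; the scene is bit-reproducible given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 420, height = 280, n_clusters = 8,
                       cluster_radius_mean = 16, cluster_radius_sd = 0.9,
                       cluster_color = c(62, 48, 78),
                       foliage_color = c(85, 135, 40),
                       soil_color = c(105, 85, 70),
                       color_jitter = 5,
                       occlusion_fraction = 0, shadow_strength = 0,
                       noise_sd = 6, min_gap_px = 5, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_clusters = as.integer(n_clusters),
               cluster_radius_mean = cluster_radius_mean,
               cluster_radius_sd = cluster_radius_sd,
               cluster_color = as.numeric(cluster_color),
               foliage_color = as.numeric(foliage_color),
               soil_color = as.numeric(soil_color),
               color_jitter = color_jitter,
               occlusion_fraction = occlusion_fraction,
               shadow_strength = shadow_strength,
               noise_sd = noise_sd, min_gap_px = min_gap_px,
               seed = as.integer(seed))
  .validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

.validate_scene_spec <- function(s) {
  stopifnot(s$width >= 1, s$height >= 1, s$n_clusters >= 0,
            s$cluster_radius_mean > 0, s$cluster_radius_sd >= 0,
            s$occlusion_fraction >= 0, s$occlusion_fraction <= 1,
            s$shadow_strength >= 0, s$shadow_strength <= 1,
            s$noise_sd >= 0, s$min_gap_px >= 0)
  for (col in list(s$cluster_color, s$foliage_color, s$soil_color))
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      stop("colours must be sRGB triplets in [0, 255]", call. = FALSE)
  invisible(s)
}

#' Best-condition acquisition preset
#'
#' Fruit partially freed of leaves and directly illuminated: occlusion and
#' shadow both 0.05.
#'
#' @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
best_condition_preset <- function(...) {
  scene_spec(occlusion_fraction = 0.05, shadow_strength = 0.05, ...)
}

#' Worst-condition acquisition preset
#'
#' Fruit covered by leaves and in shadow: occlusion 0.6, shadow 0.5.
#'
#' @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
worst_condition_preset <- function(...) {
  scene_spec(occlusion_fraction = 0.6, shadow_strength = 0.5, ...)
}

# run code under a local, fully specified RNG state and restore afterwards
.with_scene_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  force(code)
}

# rasterise a union of rotated ellipses; returns linear pixel indices
.rasterize_blob <- function(ellipses, height, width) {
  ext <- max(vapply(ellipses, function(e)
    abs(e$dr) + abs(e$dc) + max(e$a, e$b), numeric(1)))
  r0 <- max(1L, floor(ellipses[[1]]$cr - ext)); r1 <- min(height, ceiling(ellipses[[1]]$cr + ext))
  c0 <- max(1L, floor(ellipses[[1]]$cc - ext)); c1 <- min(width, ceiling(ellipses[[1]]$cc + ext))
  rr <- r0:r1; cc <- c0:c1
  inside <- matrix(FALSE, length(rr), length(cc))
  for (e in ellipses) {
    dy <- outer(rr - (e$cr + e$dr), rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - (e$cc + e$dc))
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / e$b
    inside <- inside | (u^2 + v^2 <= 1)
  }
  idx <- which(inside)
  (cc[(idx - 1L) %/% length(rr) + 1L] - 1L) * height +
    rr[(idx - 1L) %% length(rr) + 1L]
}

#' Generate a synthetic fruiting-zone scene
#'
#' Deterministic for a fixed spec (including seed).  Clusters are unions of
#' 3-6 jittered rotated ellipses, placed in the fruiting band with a minimum
#' mutual clearance; foliage fills the canopy above, soil the strip below.
#' Occlusion overdraws leaf-shaped foliage ellipses onto each cluster until
#' `occlusion_fraction` of its pixels are covered, fragmenting the visible
#' remainder the way real leaf cover does; shadow darkens the whole scene
#' multiplicatively by `1 - shadow_strength` (flat shade on the canopy side
#' away from the sun), which compresses the colour separations and makes
#' the fixed sensor noise relatively stronger; Gaussian sensor noise is
#' added last.  Per-pixel labels are
#' recorded before noise and reflect what is visible (an occluded cluster
#' pixel is labelled foliage).
#'
#' If a cluster cannot be placed without violating bounds or clearance the
#' scene is generated with fewer clusters and a warning; the ground truth
#' reflects the actual count.
#'
#' @param spec A `scene_spec`.
#' @return A `vine_scene`: `image` (H x W x 3 integer array, 0-255) and
#'   `truth` (list: `cluster_count`, `per_cluster_area_px` (visible pixels),
#'   `rendered_area_px` (before occlusion), `pixel_labels` (H x W factor
#'   codes into `levels`), `cluster_id` (H x W integer matrix), `spec`).
#' @examples
#' sc <- generate_scene(scene_spec(n_clusters = 3, seed = 7))
#' sc$truth$cluster_count
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_scene_rng(spec$seed, {
    h <- spec$height; w <- spec$width
    soil_top <- floor(0.72 * h) + 1L     # soil strip: bottom 28%
    label <- matrix(2L, h, w)            # foliage
    if (soil_top <= h) label[soil_top:h, ] <- 3L

    # --- cluster placement in the fruiting band ---
    band <- c(floor(0.40 * h), floor(0.72 * h))
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    placed <- 0L
    for (i in seq_len(spec$n_clusters)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        r <- max(5, rnorm(1, spec$cluster_radius_mean, spec$cluster_radius_sd))
        ext <- 1.25 * r          # max blob extent: offset 0.30r + axis <= 0.91r
        if (band[1] + ext > band[2] - ext || ext + 1 > w - ext) break
        cr <- runif(1, band[1] + ext, band[2] - ext)
        ccol <- runif(1, 1 + ext, w - ext)
        if (placed == 0L ||
            all(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - ccol)^2) >=
                1.25 * (radii + r) + spec$min_gap_px)) {
          centers <- rbind(centers, c(cr, ccol)); radii <- c(radii, r)
          placed <- placed + 1L; ok <- TRUE; break
        }
      }
      if (!ok) {
        warning(sprintf("placed %d of %d clusters (no room left)",
                        placed, spec$n_clusters))
        break
      }
    }

    # --- render compound blobs ---
    # ellipse axes shrink slightly with the number of ellipses so blob area
    # stays comparable across 3..6 lobes (keeps within-scene size spread
    # realistic for bunches of one vigour zone)
    cluster_id <- matrix(0L, h, w)
    rendered <- integer(placed)
    for (i in seq_len(placed)) {
      r <- radii[i]
      k <- sample(3:6, 1)
      f <- (4.5 / k)^0.25
      ells <- lapply(seq_len(k), function(j) {
        list(cr = centers[i, 1], cc = centers[i, 2],
             dr = runif(1, -0.30, 0.30) * r, dc = runif(1, -0.30, 0.30) * r,
             a = runif(1, 0.65, 0.82) * r * f, b = runif(1, 0.65, 0.82) * r * f,
             theta = runif(1, 0, pi))
      })
      px <- .rasterize_blob(ells, h, w)
      cluster_id[px] <- i
      label[px] <- 1L
      rendered[i] <- length(px)
    }

    # --- occlusion: overdraw leaf-shaped foliage patches on each blob ---
    visible <- rendered
    if (spec$occlusion_fraction > 0 && placed > 0L) {
      for (i in seq_len(placed)) {
        px <- which(cluster_id == i)
        target <- min(length(px), ceiling(spec$occlusion_fraction * length(px)))
        occluded <- 0L
        for (leaf in seq_len(30L)) {
          if (occluded >= target) break
          anchor <- px[sample.int(length(px), 1)]
          ar <- (anchor - 1L) %% h + 1L
          ac <- (anchor - 1L) %/% h + 1L
          e <- list(cr = ar, cc = ac, dr = 0, dc = 0,
                    a = runif(1, 0.45, 0.75) * radii[i],
                    b = runif(1, 0.30, 0.55) * radii[i],
                    theta = runif(1, 0, pi))
          hit <- intersect(.rasterize_blob(list(e), h, w),
                           which(cluster_id == i))
          if (!length(hit)) next
          # keep the leaf compact: take pixels nearest its midrib first,
          # clipped to the remaining occlusion budget
          need <- target - occluded
          if (length(hit) > need) {
            d2 <- ((hit - 1L) %% h + 1L - ar)^2 + ((hit - 1L) %/% h + 1L - ac)^2
            hit <- hit[order(d2)][seq_len(need)]
          }
          cluster_id[hit] <- 0L
          label[hit] <- 2L
          occluded <- occluded + length(hit)
        }
        visible[i] <- rendered[i] - occluded
      }
    }

    # --- colours ---
    img <- array(0, dim = c(h, w, 3))
    base <- list(spec$cluster_color, spec$foliage_color, spec$soil_color)
    for (cls in 1:3) {
      sel <- label == cls
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- base[[cls]][ch]
        img[, , ch] <- plane
      }
    }
    if (spec$color_jitter > 0 && placed > 0L) {
      jit <- matrix(rnorm(placed * 3, 0, spec$color_jitter), placed, 3)
      for (i in seq_len(placed)) {
        sel <- cluster_id == i
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[sel] <- plane[sel] + jit[i, ch]
          img[, , ch] <- plane
        }
      }
    }

    # --- flat shade (scene on the side away from the sun) ---
    # uniform multiplicative darkening: colour separations shrink and the
    # fixed sensor noise becomes relatively stronger, as in morning imagery
    if (spec$shadow_strength > 0) {
      img <- img * (1 - spec$shadow_strength)
      label <- label + 3L                   # shadowed-* codes 4:6
    }

    # --- sensor noise, quantisation ---
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    truth <- list(cluster_count = placed,
                  per_cluster_area_px = visible,
                  rendered_area_px = rendered,
                  pixel_labels = label,
                  levels = .LABEL_LEVELS,
                  cluster_id = cluster_id,
                  spec = spec)
    structure(list(image = img, truth = truth), class = "vine_scene")
  })
}

#' @export
print.vine_scene <- function(x, ...) {
  cat(sprintf("<vine_scene %d x %d> %d cluster(s), %.1f%% cluster pixels\n",
              dim(x$image)[1], dim(x$image)[2], x$truth$cluster_count,
              100 * sum(x$truth$cluster_id > 0) / prod(dim(x$image)[1:2])))
  invisible(x)
}

#' Serialize / restore a scene spec as plain-text JSON
#'
#' @param spec A `scene_spec`.
#' @param path File path.
#' @return `path` (write) or the `scene_spec` (read).
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scene_spec, x)
}

#' Write a scene to disk
#'
#' Writes the RGB image as PNG, the ground-truth labels as an indexed
#' grayscale PNG (label code / 6), and a JSON truth manifest.
#'
#' @param scene A `vine_scene`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  stopifnot(inherits(scene, "vine_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  lab_path <- file.path(dir, paste0(stem, "_labels.png"))
  man_path <- file.path(dir, paste0(stem, "_truth.json"))
  png::writePNG(scene$image / 255, img_path)
  png::writePNG(scene$truth$pixel_labels / length(.LABEL_LEVELS), lab_path)
  tr <- scene$truth
  jsonlite::write_json(
    list(cluster_count = tr$cluster_count,
         per_cluster_area_px = tr$per_cluster_area_px,
         rendered_area_px = tr$rendered_area_px,
         levels = tr$levels,
         rng = "Mersenne-Twister/Inversion/Rejection",
         spec = unclass(tr$spec)),
    man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, labels = lab_path, manifest = man_path))
}

#' Generate synthetic per-vine yield records
#'
#' Companion generator for regression parameter-recovery studies: draws
#' per-vine total cluster areas per vigour zone and produces measured yields
#' from a known linear law `yield = slope * area + intercept + noise`, with
#' noise standard deviation a fraction of each zone's mean yield.  Default
#' zone area distributions (HV 168.6 +/- 84.0 cm^2, LV 69.2 +/- 35.6 cm^2)
#' and slope 4 g/cm^2 reflect typical high/low-vigour Sangiovese vines.
#'
#' @param n_per_zone Vines per zone.
#' @param zones Zone labels.
#' @param area_mean,area_sd Named (per-zone) or recycled area parameters (cm^2).
#' @param true_slope,true_intercept The generating line (g/cm^2, g).
#' @param noise_frac Noise sd as a fraction of the zone's mean yield.
#' @param condition Acquisition condition label stored on the records.
#' @param seed Integer seed.
#' @return Vine-record data frame with `total_cluster_area_cm2` and
#'   `measured_yield_g` filled in.
#' @export
generate_vine_records <- function(n_per_zone = 8, zones = c("HV", "LV"),
                                  area_mean = c(HV = 168.6, LV = 69.2),
                                  area_sd = c(HV = 84.0, LV = 35.6),
                                  true_slope = 4, true_intercept = 0,
                                  noise_frac = 0.15, condition = "B",
                                  seed = 1L) {
  .with_scene_rng(seed, {
    out <- lapply(seq_along(zones), function(zi) {
      z <- zones[zi]
      am <- if (!is.null(names(area_mean))) area_mean[[z]] else area_mean[[min(zi, length(area_mean))]]
      asd <- if (!is.null(names(area_sd))) area_sd[[z]] else area_sd[[min(zi, length(area_sd))]]
      area <- pmax(5, rnorm(n_per_zone, am, asd))
      mu <- true_slope * area + true_intercept
      yield <- pmax(0, mu + rnorm(n_per_zone, 0, noise_frac * mean(mu)))
      data.frame(vine_id = sprintf("%s_%02d", z, seq_len(n_per_zone)),
                 vigor_zone = z, condition = condition,
                 total_cluster_area_cm2 = area,
                 detected_count = NA_integer_, adjusted_count = NA_integer_,
                 observed_count = NA_integer_, green_count = NA_integer_,
                 measured_yield_g = yield, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
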