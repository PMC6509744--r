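# Orchestration: configuration, the single-image detection chain, and the
# batch detect / yield / cost runners.

#' Pipeline configuration
#'
#' Collects every tunable of the detection chain with the workflow's
#' standard defaults: Gaussian radius 2 px, particle area floor 200 px,
#' circularity window 0.25-1.00, 8-connectivity, double-cluster split
#' factor 1.5, vegetation = high-b* class, cluster = low-b* class.
#'
#' @param gaussian_radius Smoothing radius (px) for the b* channel.
#' @param min_area_px Particle area floor (px), inclusive.
#' @param circularity_range Closed circularity window.
#' @param connectivity 8 or 4.
#' @param split_factor Double-cluster threshold as a multiple of the median
#'   particle area.
#' @param vegetation_class,cluster_class Threshold polarities, see
#'   [two_stage_segmentation()].
#' @param pixels_per_cm Spatial scale; alternatively give `line_length_px`
#'   and `known_length_cm`.
#' @param line_length_px,known_length_cm Calibration line, see
#'   [scale_calibration()].
#' @param seed Seed recorded in run reports (used by simulation paths).
#' @param output_dir If set, [run_detect()] writes particle CSVs, mask PNGs
#'   and a JSON report there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gaussian_radius = 2, min_area_px = 200,
                            circularity_range = c(0.25, 1.00),
                            connectivity = 8, split_factor = 1.5,
                            vegetation_class = "high", cluster_class = "low",
                            pixels_per_cm = NULL, line_length_px = NULL,
                            known_length_cm = NULL, seed = NULL,
                            output_dir = NULL) {
  if (gaussian_radius <= 0) stop("gaussian_radius must be positive", call. = FALSE)
  if (min_area_px < 0) stop("min_area_px must be non-negative", call. = FALSE)
  if (length(circularity_range) != 2L || circularity_range[1] > circularity_range[2])
    stop("circularity_range must be an ordered pair", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (split_factor <= 0) stop("split_factor must be positive", call. = FALSE)
  calibration <- if (!is.null(pixels_per_cm) || !is.null(line_length_px))
    scale_calibration(line_length_px, known_length_cm, pixels_per_cm)
  else NULL
  structure(list(gaussian_radius = gaussian_radius,
                 min_area_px = min_area_px,
                 circularity_range = circularity_range,
                 connectivity = connectivity, split_factor = split_factor,
                 vegetation_class = vegetation_class,
                 cluster_class = cluster_class,
                 calibration = calibration, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Detect clusters in a single image
#'
#' Runs the full chain on one image: sRGB -> CIELAB -> b* channel ->
#' Gaussian smoothing -> two-stage Otsu segmentation -> connected
#' components -> calibrated morphometry -> area/circularity filter ->
#' double-cluster adjustment.
#'
#' @param image An `H x W x 3` array (0-255), a file path (PNG/TIFF), or a
#'   `vine_scene`.
#' @param config A `pipeline_config`.
#' @param image_id Label for reports; defaults to the file name when `image`
#'   is a path.
#' @return A `cluster_detection`: `particles` (final `particle_set`),
#'   `mask` (`cluster_mask`), `raw_count`, `adjusted_count`,
#'   `total_cluster_area_cm2` (`NA` if uncalibrated), `status`.
#' @examples
#' sc <- generate_scene(best_condition_preset(seed = 42))
#' det <- detect_clusters(sc, pipeline_config(pixels_per_cm = 5))
#' det$adjusted_count
#' @export
detect_clusters <- function(image, config = pipeline_config(),
                            image_id = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_rgb_image(image)
  } else if (inherits(image, "vine_scene")) {
    image <- image$image
  }
  if (is.null(image_id)) image_id <- "image"
  lab <- srgb_to_lab(image)
  b <- gaussian_smooth(extract_b_channel(lab), radius = config$gaussian_radius)
  mask <- two_stage_segmentation(b,
                                 vegetation_class = config$vegetation_class,
                                 cluster_class = config$cluster_class)
  comp <- label_components(mask, connectivity = config$connectivity)
  ps <- measure_particles(comp, calibration = config$calibration,
                          image_id = image_id)
  ps <- filter_particles(ps, min_area_px = config$min_area_px,
                         circularity_range = config$circularity_range)
  ps <- adjust_double_clusters(ps, split_factor = config$split_factor)
  structure(list(
    particles = ps, mask = mask,
    raw_count = nrow(ps$particles),
    adjusted_count = ps$adjusted_count,
    total_cluster_area_cm2 =
      if (is.null(config$calibration)) NA_real_ else sum(ps$particles$area_cm2),
    status = mask$status, image_id = image_id
  ), class = "cluster_detection")
}

#' @export
print.cluster_detection <- function(x, ...) {
  cat(sprintf("<cluster_detection '%s'> %d particle(s), adjusted %d, status %s\n",
              x$image_id, x$raw_count, x$adjusted_count, x$status))
  invisible(x)
}

#' Batch cluster detection
#'
#' Runs [detect_clusters()] over a set of images.  Per-image failures
#' (unreadable files, degenerate segmentations) are recorded and the batch
#' continues.  With `config$output_dir` set, writes per-image particle CSVs
#' and mask PNGs plus a machine-readable JSON run report.
#'
#' @param images Character vector of file paths, or a list of image arrays /
#'   `vine_scene`s (optionally named).
#' @param config A `pipeline_config`.
#' @return A `run_report`: `summary` data frame (one row per image: counts,
#'   area, status), `detections` (list of `cluster_detection` or `NULL` on
#'   error), `config`, `version`, `timestamp`.
#' @export
run_detect <- function(images, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(images)) images <- as.list(images)
  ids <- names(images)
  if (is.null(ids)) ids <- rep(NA_character_, length(images))
  detections <- vector("list", length(images))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    id <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i]
          else if (is.character(images[[i]])) basename(images[[i]])
          else sprintf("image_%03d", i)
    det <- tryCatch(detect_clusters(images[[i]], config, image_id = id),
                    error = function(e) e)
    if (inherits(det, "error")) {
      rows[[i]] <- data.frame(image_id = id, raw_count = NA_integer_,
                              adjusted_count = NA_integer_,
                              total_cluster_area_cm2 = NA_real_,
                              status = paste("error:", conditionMessage(det)),
                              stringsAsFactors = FALSE)
    } else {
      detections[[i]] <- det
      rows[[i]] <- data.frame(image_id = id, raw_count = det$raw_count,
                              adjusted_count = det$adjusted_count,
                              total_cluster_area_cm2 = det$total_cluster_area_cm2,
                              status = det$status, stringsAsFactors = FALSE)
    }
  }
  report <- structure(list(
    summary = do.call(rbind, rows),
    detections = detections,
    config = config,
    version = as.character(utils::packageVersion("vineyield")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")
  if (!is.null(config$output_dir)) .write_detect_outputs(report)
  report
}

.write_detect_outputs <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (det in report$detections) {
    if (is.null(det)) next
    stem <- gsub("[^A-Za-z0-9_.-]", "_", det$image_id)
    write_particle_csv(det$particles, file.path(dir, paste0(stem, "_particles.csv")))
    write_mask_png(det$mask, file.path(dir, paste0(stem, "_mask.png")))
  }
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  cfg <- report$config
  cfg$calibration <- if (is.null(cfg$calibration)) NULL
                     else unclass(cfg$calibration)
  jsonlite::write_json(
    list(summary = report$summary, config = unclass(cfg),
         version = report$version, timestamp = report$timestamp),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d image(s), vineyield %s\n",
              nrow(x$summary), x$version))
  print(x$summary)
  invisible(x)
}

#' Fit on one season's vines, predict another's
#'
#' The season-transfer workflow: fits the area-to-weight regression on the
#' training table, applies it to the target table, and reports per-vine and
#' per-zone accuracy where measured yields are available.  Zone accuracy
#' compares zone-mean measured against zone-mean estimated yield.
#'
#' @param train Vine-record data frame (or CSV path) with
#'   `total_cluster_area_cm2` and `measured_yield_g`.
#' @param apply Vine-record data frame (or CSV path) with
#'   `total_cluster_area_cm2`; `measured_yield_g` and `vigor_zone` enable
#'   the accuracy blocks.
#' @param through_origin Passed to [fit_area_weight_regression()].
#' @param fit_meta Label stored with the fit.
#' @return A `yield_report`: `model`, `predictions` (apply table plus
#'   `estimated_yield_g` and `accuracy_pct`), `zone_summary` (per-zone mean
#'   measured/estimated and accuracy), `overall_accuracy_pct`.
#' @export
run_yield <- function(train, apply, through_origin = FALSE, fit_meta = NULL) {
  if (is.character(train)) train <- read.csv(train, stringsAsFactors = FALSE)
  if (is.character(apply)) apply <- read.csv(apply, stringsAsFactors = FALSE)
  for (d in list(train)) {
    miss <- setdiff(c("total_cluster_area_cm2", "measured_yield_g"), names(d))
    if (length(miss))
      stop("training table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  if (!"total_cluster_area_cm2" %in% names(apply))
    stop("apply table lacks column: total_cluster_area_cm2", call. = FALSE)
  model <- fit_area_weight_regression(train, through_origin = through_origin,
                                      fit_meta = fit_meta)
  pred <- apply
  if (nrow(pred) > 0L) {
    pred$estimated_yield_g <- predict_yield(model, pred)
    if ("measured_yield_g" %in% names(pred)) {
      pred$accuracy_pct <- NA_real_
      ok <- !is.na(pred$measured_yield_g) & pred$measured_yield_g > 0
      pred$accuracy_pct[ok] <- accuracy_pct(pred$measured_yield_g[ok],
                                            pred$estimated_yield_g[ok])
    }
  } else {
    pred$estimated_yield_g <- numeric(0)
  }
  zone_summary <- NULL
  overall <- NA_real_
  if (nrow(pred) > 0L && all(c("measured_yield_g", "vigor_zone") %in% names(pred))) {
    ok <- !is.na(pred$measured_yield_g) & pred$measured_yield_g > 0
    if (any(ok)) {
      zs <- aggregate(pred[ok, c("measured_yield_g", "estimated_yield_g")],
                      by = list(vigor_zone = pred$vigor_zone[ok]), FUN = mean)
      zs$accuracy_pct <- accuracy_pct(zs$measured_yield_g, zs$estimated_yield_g)
      zone_summary <- zs
      overall <- accuracy_pct(mean(pred$measured_yield_g[ok]),
                              mean(pred$estimated_yield_g[ok]))
    }
  }
  structure(list(model = model, predictions = pred,
                 zone_summary = zone_summary,
                 overall_accuracy_pct = overall),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  print(x$model)
  if (!is.null(x$zone_summary)) {
    cat("Zone-mean accuracy:\n")
    print(x$zone_summary)
  }
  invisible(x)
}

#' Cost report for one or more vineyard sizes
#'
#' @param areas_ha Vector of vineyard areas (ha).
#' @param ... Rate/timing overrides passed to [cost_scenario()].
#' @return List of `mode_comparison` objects (one per area) plus the
#'   combined [cost_table()].
#' @export
run_cost <- function(areas_ha = c(5, 10, 50), ...) {
  if (any(areas_ha <= 0)) stop("areas must be positive", call. = FALSE)
  comparisons <- lapply(areas_ha, compare_modes, ...)
  names(comparisons) <- paste0(areas_ha, "_ha")
  list(comparisons = comparisons, table = cost_table(areas_ha, ...))
}

#' @importFrom stats aggregate complete.cases fitted var
NULL
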