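# Connected-component labelling and calibrated particle morphometry:
# the "analyze particles" stage of the workflow.

#' Spatial scale calibration
#'
#' Calibration from a line of known physical length drawn on the image
#' (e.g. a reference target placed in the fruiting zone), or directly from
#' a pixels-per-centimetre value.
#'
#' @param line_length_px Length of the drawn line in pixels.
#' @param known_length_cm Physical length of the target in cm.
#' @param pixels_per_cm Alternatively, the scale itself.
#' @return A `scale_calibration` with `pixels_per_cm` and its provenance.
#' @examples
#' scale_calibration(line_length_px = 100, known_length_cm = 20)  # 5 px/cm
#' @export
scale_calibration <- function(line_length_px = NULL, known_length_cm = NULL,
                              pixels_per_cm = NULL) {
  if (is.null(pixels_per_cm)) {
    if (is.null(line_length_px) || is.null(known_length_cm))
      stop("give either pixels_per_cm or line_length_px + known_length_cm",
           call. = FALSE)
    if (line_length_px <= 0 || known_length_cm <= 0)
      stop("calibration lengths must be positive", call. = FALSE)
    pixels_per_cm <- line_length_px / known_length_cm
  } else if (pixels_per_cm <= 0) {
    stop("pixels_per_cm must be positive", call. = FALSE)
  }
  structure(list(pixels_per_cm = pixels_per_cm,
                 source = list(line_length_px = line_length_px,
                               known_length_cm = known_length_cm)),
            class = "scale_calibration")
}

# shift a matrix by (dr, dc), filling vacated cells
.shift_mat <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Label connected components of cluster pixels
#'
#' Components are extracted under 8-connectivity by default (diagonal
#' contact joins), the convention of standard particle-analysis tools;
#' 4-connectivity is available.  Labels are assigned 1..n in raster-scan
#' (row-major) order of each component's first pixel, so the output is
#' deterministic.
#'
#' @param mask A `cluster_mask` from [two_stage_segmentation()], or a logical
#'   matrix of foreground pixels.
#' @param connectivity 8 (default) or 4.
#' @return List with integer matrix `labels` (0 = background) and `n_components`.
#' @export
label_components <- function(mask, connectivity = 8) {
  fg <- if (inherits(mask, "cluster_mask")) mask$state == MASK_CLUSTER
        else if (is.logical(mask) && is.matrix(mask)) mask
        else stop("`mask` must be a cluster_mask or logical matrix", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  h <- nrow(fg); w <- ncol(fg)
  if (!any(fg))
    return(list(labels = matrix(0L, h, w), n_components = 0L))
  # iterative minimum-label propagation: seed each foreground pixel with a
  # unique id, repeatedly replace by the minimum over its neighbourhood
  cur <- matrix(Inf, h, w)
  cur[fg] <- which(fg)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    nxt <- cur
    for (o in offs)
      nxt <- pmin(nxt, .shift_mat(cur, o[1], o[2], Inf))
    nxt[!fg] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  # relabel 1..n by raster-scan first occurrence (row-major)
  ids_rowmajor <- as.vector(t(cur))
  ids <- unique(ids_rowmajor[is.finite(ids_rowmajor)])
  labels <- matrix(0L, h, w)
  labels[fg] <- match(cur[fg], ids)
  list(labels = labels, n_components = length(ids))
}

#' Measure labelled particles
#'
#' Computes per-component pixel area, perimeter, circularity, centroid and
#' bounding box, plus calibrated area in cm^2 when a calibration is given.
#' Perimeter is the count of boundary pixels (pixels with at least one
#' exposed 4-neighbour); this differs slightly from corner-smoothed
#' perimeter conventions of some tools.  Circularity is
#' `4 * pi * area / perimeter^2`, capped at 1.
#'
#' @param labeling Output of [label_components()].
#' @param calibration Optional `scale_calibration`; without it `area_cm2` is
#'   `NA` and yield operations downstream will refuse the set.
#' @param image_id Label carried into the particle table.
#' @return A `particle_set`: data frame `particles` (one row per component,
#'   with `counts_as` initialised to 1), `image_id`, `calibration`,
#'   `adjusted_count` (initially the raw count).
#' @export
measure_particles <- function(labeling, calibration = NULL, image_id = "image") {
  stopifnot(is.list(labeling), is.matrix(labeling$labels))
  if (!is.null(calibration) && !inherits(calibration, "scale_calibration"))
    stop("`calibration` must come from scale_calibration()", call. = FALSE)
  lab <- labeling$labels
  n <- labeling$n_components
  if (n == 0L) {
    df <- data.frame(id = integer(), area_px = integer(), area_cm2 = numeric(),
                     perimeter_px = numeric(), circularity = numeric(),
                     centroid_row = numeric(), centroid_col = numeric(),
                     bbox_min_row = integer(), bbox_min_col = integer(),
                     bbox_max_row = integer(), bbox_max_col = integer(),
                     counts_as = integer())
    return(.particle_set(df, image_id, calibration))
  }
  fg <- lab > 0L
  area <- tabulate(lab[fg], nbins = n)
  # boundary pixels: any 4-neighbour outside the same component
  boundary <- fg & (
    .shift_mat(lab, 1, 0, 0L) != lab | .shift_mat(lab, -1, 0, 0L) != lab |
    .shift_mat(lab, 0, 1, 0L) != lab | .shift_mat(lab, 0, -1, 0L) != lab)
  perim <- tabulate(lab[boundary], nbins = n)
  rows <- row(lab)[fg]; cols <- col(lab)[fg]; ids <- lab[fg]
  centroid_row <- as.numeric(rowsum(rows, ids)) / area
  centroid_col <- as.numeric(rowsum(cols, ids)) / area
  bbox <- vapply(seq_len(n), function(i) {
    r <- rows[ids == i]; cc <- cols[ids == i]
    c(min(r), min(cc), max(r), max(cc))
  }, integer(4))
  ppcm <- if (is.null(calibration)) NA_real_ else calibration$pixels_per_cm
  df <- data.frame(
    id = seq_len(n),
    area_px = area,
    area_cm2 = area / ppcm^2,
    perimeter_px = as.numeric(perim),
    circularity = pmin(1, 4 * pi * area / perim^2),
    centroid_row = centroid_row,
    centroid_col = centroid_col,
    bbox_min_row = bbox[1, ], bbox_min_col = bbox[2, ],
    bbox_max_row = bbox[3, ], bbox_max_col = bbox[4, ],
    counts_as = 1L
  )
  .particle_set(df, image_id, calibration)
}

.particle_set <- function(particles, image_id, calibration,
                          adjusted_count = nrow(particles)) {
  structure(list(particles = particles, image_id = image_id,
                 calibration = calibration, adjusted_count = adjusted_count),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set '%s'> %d particle(s), adjusted count %d%s\n",
              x$image_id, nrow(x$particles), x$adjusted_count,
              if (is.null(x$calibration)) " (uncalibrated)" else ""))
  invisible(x)
}

#' Filter particles on area and circularity
#'
#' Retains particles whose pixel area is at least `min_area_px` and whose
#' circularity lies inside the closed `circularity_range`.  Defaults are the
#' workflow's standard settings (area 200 px to infinity, circularity
#' 0.25-1.00), which drop noise specks and elongated canopy fragments while
#' keeping compact bunch shapes.  Measurements of retained particles are
#' unchanged.
#'
#' @param set A `particle_set`.
#' @param min_area_px Minimum pixel area (inclusive); default 200.
#' @param circularity_range Closed interval; default `c(0.25, 1)`.
#' @return The filtered `particle_set`.
#' @export
filter_particles <- function(set, min_area_px = 200,
                             circularity_range = c(0.25, 1.00)) {
  stopifnot(inherits(set, "particle_set"))
  if (length(circularity_range) != 2L ||
      circularity_range[1] > circularity_range[2])
    stop("`circularity_range` must be an ordered pair", call. = FALSE)
  p <- set$particles
  keep <- p$area_px >= min_area_px &
    p$circularity >= circularity_range[1] &
    p$circularity <= circularity_range[2]
  .particle_set(p[keep, , drop = FALSE], set$image_id, set$calibration)
}

#' Double-cluster count adjustment
#'
#' Two touching bunches segment as one oversized particle.  Any particle
#' whose area exceeds `split_factor` times the median particle area is
#' counted as two clusters (never more); `adjusted_count` is the raw count
#' plus the number of such oversized particles.  The reference size is
#' data-driven (the median of the set), so the rule adapts to bunch size
#' differences between vigour zones.
#'
#' @param set A measured (and typically filtered) `particle_set`.
#' @param split_factor Multiple of the median area above which a particle is
#'   treated as a double cluster; default 1.5.
#' @return The `particle_set` with `counts_as` set per particle and
#'   `adjusted_count` updated.
#' @export
adjust_double_clusters <- function(set, split_factor = 1.5) {
  stopifnot(inherits(set, "particle_set"))
  if (!is.numeric(split_factor) || split_factor <= 0)
    stop("`split_factor` must be positive", call. = FALSE)
  p <- set$particles
  if (nrow(p) == 0L)
    return(.particle_set(p, set$image_id, set$calibration, adjusted_count = 0L))
  sizes <- if (all(is.na(p$area_cm2))) p$area_px else p$area_cm2
  p$counts_as <- ifelse(sizes > split_factor * median(sizes), 2L, 1L)
  .particle_set(p, set$image_id, set$calibration,
                adjusted_count = sum(p$counts_as))
}

#' Write a particle table to CSV
#'
#' @param set A `particle_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_csv <- function(set, path) {
  stopifnot(inherits(set, "particle_set"))
  df <- cbind(image_id = set$image_id, set$particles)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
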