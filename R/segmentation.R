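# Histogramming, Otsu thresholding and the two-stage vegetation/cluster
# segmentation of the smoothed b* channel.

#' Build a 256-bin histogram of a scalar channel
#'
#' Bins span the min-max range of the included pixels linearly (an
#' 8-bit-equivalent histogram regardless of the channel's physical range).
#' A channel that is constant over the included pixels yields a degenerate
#' histogram (all counts in bin 0, `degenerate = TRUE`), on which Otsu is
#' undefined.
#'
#' @param channel A `scalar_channel`.
#' @param exclusion Optional logical matrix, same shape; `TRUE` pixels are
#'   excluded from the histogram.
#' @return A `b_histogram` object: `counts` (256 integers), `bin_min`,
#'   `bin_width`, `n_pixels`, `degenerate`.
#' @export
build_histogram <- function(channel, exclusion = NULL) {
  if (!inherits(channel, "scalar_channel"))
    stop("`channel` must be a scalar_channel", call. = FALSE)
  v <- channel$values
  if (!is.null(exclusion)) {
    stopifnot(is.logical(exclusion), all(dim(exclusion) == dim(v)))
    v <- v[!exclusion]
  }
  if (length(v) == 0L)
    stop("all pixels excluded: histogram undefined", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    out <- list(counts = c(length(v), integer(255L)), bin_min = rng[1],
                bin_width = 0, n_pixels = length(v), degenerate = TRUE)
    class(out) <- "b_histogram"
    return(out)
  }
  width <- (rng[2] - rng[1]) / 256
  idx <- .bin_index(v, rng[1], width)
  out <- list(counts = tabulate(idx + 1L, nbins = 256L), bin_min = rng[1],
              bin_width = width, n_pixels = length(v),
              degenerate = FALSE)
  class(out) <- "b_histogram"
  out
}

# map values to bin indices 0..255 under a histogram's binning
.bin_index <- function(v, bin_min, bin_width) {
  pmin(pmax(floor((v - bin_min) / bin_width), 0), 255)
}

#' Otsu's threshold on a 256-bin histogram
#'
#' Selects the split that maximises the between-class variance (equivalently
#' minimises the weighted within-class variance) over all 255 candidate
#' splits.  The low class is bins `0..threshold_bin`; ties are broken towards
#' the lowest bin.
#'
#' @param hist A `b_histogram` from [build_histogram()].
#' @return A `threshold_result`: `threshold_bin` (0-254), `threshold_value`
#'   (upper edge of the threshold bin, in channel units),
#'   `interclass_variance` (in squared bin units) and `class_fractions`
#'   (low, high; sums to 1).
#' @export
otsu_threshold <- function(hist) {
  if (!inherits(hist, "b_histogram"))
    stop("`hist` must come from build_histogram()", call. = FALSE)
  counts <- as.numeric(hist$counts)
  if (hist$degenerate || sum(counts > 0) < 2L)
    stop("degenerate histogram: threshold undefined", call. = FALSE)
  n <- sum(counts)
  i <- 0:255
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * i)
  mt <- m0[256]
  t <- 1:255                       # split after bin t-1: low class = 0..t-1
  w0t <- w0[t]; w1t <- n - w0t
  sb <- numeric(255)
  ok <- w0t > 0 & w1t > 0
  sb[ok] <- w0t[ok] * w1t[ok] * (m0[t][ok] / w0t[ok] - (mt - m0[t][ok]) / w1t[ok])^2
  sb[!ok] <- -Inf
  best <- which.max(sb)            # lowest index on ties
  tb <- best - 1L                  # low class = bins 0..tb
  structure(list(
    threshold_bin = tb,
    threshold_value = hist$bin_min + (tb + 1) * hist$bin_width,
    interclass_variance = sb[best] / n^2,
    class_fractions = c(low = w0[best] / n, high = 1 - w0[best] / n)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<otsu threshold: bin %d (value %.3f), class fractions %.3f/%.3f>\n",
              x$threshold_bin, x$threshold_value,
              x$class_fractions[1], x$class_fractions[2]))
  invisible(x)
}

# label codes used throughout
MASK_BACKGROUND <- 0L
MASK_CLUSTER <- 1L
MASK_VEGETATION <- 2L

#' Two-stage Otsu segmentation of the smoothed b* channel
#'
#' Stage 1 thresholds the full histogram and removes the high-b*
#' (yellow-green vegetation) class.  Stage 2 rebuilds the histogram on the
#' remaining pixels, thresholds again, and labels the low-b* (blue) class as
#' cluster; the rest is background (soil and residual canopy).  Polarities
#' are configurable for other crop/background colour regimes.
#'
#' If either stage is degenerate, the function fails soft: it returns an
#' empty cluster set with a `status` naming the stage, so batch runs
#' continue.  A stage is degenerate when its histogram has no contrast left,
#' or - for stage 2 - when the split assigns the majority of non-vegetation
#' pixels to the cluster class: fruit is always a minority of the remaining
#' scene, so such a split has separated soil from residual canopy (as in an
#' image with no fruit at all) rather than found clusters.
#'
#' @param b_smoothed A smoothed b* `scalar_channel` (see [gaussian_smooth()]).
#' @param vegetation_class Which side of the stage-1 threshold is removed as
#'   vegetation: `"high"` (default; yellow-green foliage has high b*).
#' @param cluster_class Which side of the stage-2 threshold is kept as
#'   cluster: `"low"` (default; dark blue-purple berries have low b*).
#' @return A `cluster_mask`: integer matrix `state` with codes 0 background,
#'   1 cluster, 2 excluded vegetation; `veg_threshold` and
#'   `cluster_threshold` (`threshold_result` or `NULL`); `status` one of
#'   `"ok"`, `"degenerate_stage1"`, `"degenerate_stage2"`.
#' @export
two_stage_segmentation <- function(b_smoothed,
                                   vegetation_class = c("high", "low"),
                                   cluster_class = c("low", "high")) {
  if (!inherits(b_smoothed, "scalar_channel"))
    stop("`b_smoothed` must be a scalar_channel", call. = FALSE)
  vegetation_class <- match.arg(vegetation_class)
  cluster_class <- match.arg(cluster_class)
  v <- b_smoothed$values
  state <- matrix(MASK_BACKGROUND, nrow(v), ncol(v))

  h1 <- build_histogram(b_smoothed)
  if (h1$degenerate || sum(h1$counts > 0) < 2L) {
    return(.cluster_mask(state, NULL, NULL, "degenerate_stage1"))
  }
  t1 <- otsu_threshold(h1)
  bin1 <- .bin_index(v, h1$bin_min, h1$bin_width)
  veg <- if (vegetation_class == "high") bin1 > t1$threshold_bin
         else bin1 <= t1$threshold_bin
  state[veg] <- MASK_VEGETATION

  h2 <- tryCatch(build_histogram(b_smoothed, exclusion = veg),
                 error = function(e) NULL)
  if (is.null(h2) || h2$degenerate || sum(h2$counts > 0) < 2L) {
    return(.cluster_mask(state, t1, NULL, "degenerate_stage2"))
  }
  t2 <- otsu_threshold(h2)
  bin2 <- .bin_index(v, h2$bin_min, h2$bin_width)
  clu <- if (cluster_class == "low") bin2 <= t2$threshold_bin
         else bin2 > t2$threshold_bin
  # fruit is always a minority of the non-vegetation pixels; a stage-2 split
  # that puts most remaining pixels in the cluster class has separated soil
  # from residual canopy instead (e.g. a scene without fruit) and is
  # rejected as degenerate rather than reported as a giant detection
  if (sum(clu & !veg) > 0.5 * sum(!veg)) {
    return(.cluster_mask(state, t1, t2, "degenerate_stage2"))
  }
  state[!veg & clu] <- MASK_CLUSTER
  .cluster_mask(state, t1, t2, "ok")
}

.cluster_mask <- function(state, veg_threshold, cluster_threshold, status) {
  structure(list(state = state, veg_threshold = veg_threshold,
                 cluster_threshold = cluster_threshold, status = status),
            class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  n <- length(x$state)
  cat(sprintf(
    "<cluster_mask %d x %d> status: %s | cluster %.1f%%, vegetation %.1f%%, background %.1f%%\n",
    nrow(x$state), ncol(x$state), x$status,
    100 * sum(x$state == MASK_CLUSTER) / n,
    100 * sum(x$state == MASK_VEGETATION) / n,
    100 * sum(x$state == MASK_BACKGROUND) / n))
  invisible(x)
}
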