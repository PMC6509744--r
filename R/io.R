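# Image file I/O: 8-bit RGB PNG/TIFF in, mask PNG out.

#' Read an 8-bit RGB image
#'
#' Reads PNG or TIFF (by file extension), drops any alpha channel, and
#' returns intensities on the 0-255 integer scale.
#'
#' @param path Image file path.
#' @return An `H x W x 3` integer array in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE))
  if (length(dim(img)) == 2L)
    stop("grayscale image: an RGB image is required", call. = FALSE)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L)
    stop("image must have 3 colour channels", call. = FALSE)
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a cluster mask as a PNG
#'
#' Encodes background as 0, excluded vegetation as 128 and cluster pixels as
#' 255 in a grayscale PNG, for visual inspection of a segmentation.
#'
#' @param mask A `cluster_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "cluster_mask"))
  gray <- matrix(0, nrow(mask$state), ncol(mask$state))
  gray[mask$state == MASK_VEGETATION] <- 128 / 255
  gray[mask$state == MASK_CLUSTER] <- 1
  png::writePNG(gray, path)
  invisible(path)
}

#' Write per-stage histograms of a segmentation to CSV
#'
#' Debug output: bin index, bin lower edge (channel units) and count for the
#' stage-1 (full) and stage-2 (vegetation-excluded) histograms.
#'
#' @param channel The smoothed b* `scalar_channel` that was segmented.
#' @param mask The resulting `cluster_mask`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(channel, mask, path) {
  stopifnot(inherits(channel, "scalar_channel"), inherits(mask, "cluster_mask"))
  h1 <- build_histogram(channel)
  rows <- data.frame(stage = 1L, bin = 0:255,
                     bin_lower = h1$bin_min + (0:255) * h1$bin_width,
                     count = h1$counts)
  if (mask$status != "degenerate_stage1") {
    h2 <- build_histogram(channel, exclusion = mask$state == MASK_VEGETATION)
    rows <- rbind(rows, data.frame(stage = 2L, bin = 0:255,
                                   bin_lower = h2$bin_min + (0:255) * h2$bin_width,
                                   count = h2$counts))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
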