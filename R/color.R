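# sRGB -> CIELAB conversion and b* channel extraction.
#
# Conversion follows IEC 61966-2-1 sRGB: inverse transfer function (de-gamma),
# linear RGB -> XYZ with the D65 matrix, then CIE L*a*b*.  The reference white
# is taken as the row sums of the RGB->XYZ matrix (numerically D65), which
# guarantees that exact grays map to a* = b* = 0 and (255,255,255) to L* = 100
# with no residual from the matrix constants.

.srgb_xyz_matrix <- matrix(
  c(0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041),
  nrow = 3, byrow = TRUE
)

# de-gamma lookup for the 256 8-bit levels; computed once at load
.srgb_linear_lut <- local({
  v <- (0:255) / 255
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
})

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' Convert an 8-bit sRGB image to a CIELAB raster
#'
#' Applies the standard sRGB inverse transfer function, the sRGB-to-XYZ (D65)
#' matrix and the CIE L*a*b* formulas to every pixel.  Neutral inputs
#' (r = g = b) map exactly onto the L* axis (a* = b* = 0).
#'
#' @param image An `H x W x 3` array of integer intensities in `[0, 255]`
#'   (as returned by [read_rgb_image()]).
#' @return A `lab_raster` object: list with `H x W` matrices `L` (in
#'   `[0, 100]`), `a_star` and `b_star` (blue negative, yellow positive).
#' @examples
#' img <- array(rep(c(62L, 48L, 78L), each = 4), dim = c(2, 2, 3))
#' lab <- srgb_to_lab(img)
#' lab$b_star[1, 1]  # negative: blue-purple
#' @export
srgb_to_lab <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an H x W x 3 array (8-bit RGB)", call. = FALSE)
  if (min(image) < 0 || max(image) > 255)
    stop("RGB intensities must lie in [0, 255]", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  # de-gamma via LUT (values may be non-integer, e.g. after synthetic noise:
  # fall back to the closed form then)
  if (all(image == round(image))) {
    lin <- .srgb_linear_lut[as.integer(image) + 1L]
  } else {
    v <- as.numeric(image) / 255
    lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  }
  dim(lin) <- c(h * w, 3L)
  xyz <- lin %*% t(.srgb_xyz_matrix)
  white <- rowSums(.srgb_xyz_matrix)
  fx <- .lab_f(xyz[, 1] / white[1])
  fy <- .lab_f(xyz[, 2] / white[2])
  fz <- .lab_f(xyz[, 3] / white[3])
  out <- list(
    L      = matrix(116 * fy - 16, h, w),
    a_star = matrix(500 * (fx - fy), h, w),
    b_star = matrix(200 * (fy - fz), h, w)
  )
  class(out) <- "lab_raster"
  out
}

#' @export
print.lab_raster <- function(x, ...) {
  cat(sprintf("<lab_raster %d x %d>  L* [%.1f, %.1f]  b* [%.1f, %.1f]\n",
              nrow(x$L), ncol(x$L), min(x$L), max(x$L),
              min(x$b_star), max(x$b_star)))
  invisible(x)
}

#' Extract the b* (blue-yellow opponent) channel
#'
#' Returns the b* plane of a CIELAB raster as a named scalar channel.  Dark
#' blue-purple berries have low/negative b*; green-yellow foliage has high
#' positive b*, which is what makes b* the discriminating channel for
#' cluster segmentation.
#'
#' @param lab A `lab_raster` from [srgb_to_lab()].
#' @return A `scalar_channel` object: list with matrix `values`, `name`
#'   (`"b*"`) and `smoothing_radius` (`NA` until smoothed).
#' @export
extract_b_channel <- function(lab) {
  if (!inherits(lab, "lab_raster"))
    stop("`lab` must be a lab_raster", call. = FALSE)
  scalar_channel(lab$b_star, name = "b*")
}

#' Construct a scalar channel
#'
#' @param values Numeric matrix of per-pixel values.
#' @param name Channel label (e.g. `"b*"`).
#' @param smoothing_radius Radius of any smoothing already applied (px), or
#'   `NA` for an unsmoothed channel.
#' @return A `scalar_channel` object.
#' @export
scalar_channel <- function(values, name = "channel", smoothing_radius = NA_real_) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(values = values, name = name,
                 smoothing_radius = smoothing_radius),
            class = "scalar_channel")
}

#' @export
print.scalar_channel <- function(x, ...) {
  cat(sprintf("<scalar_channel '%s' %d x %d>  range [%.2f, %.2f]%s\n",
              x$name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (is.na(x$smoothing_radius)) ""
              else sprintf("  smoothed (radius %g)", x$smoothing_radius)))
  invisible(x)
}

# 1-D Gaussian weights for sigma, truncated at ceiling(3.5 sigma), normalised
.gauss_kernel <- function(sigma) {
  k <- max(1L, as.integer(ceiling(3.5 * sigma)))
  w <- dnorm(-k:k, sd = sigma)
  w / sum(w)
}

# reflect indices 1..n to length n + 2k with half-sample symmetry
# (edge pixel duplicated); symmetric boundary keeps the smoothing operator
# self-adjoint, hence exactly mean-preserving
.reflect_idx <- function(n, k) {
  idx <- c(rev(seq_len(min(k, n))), seq_len(n), rev(seq_len(n))[seq_len(min(k, n))])
  if (k > n) stop("smoothing kernel wider than image", call. = FALSE)
  idx
}

#' Gaussian smoothing of a scalar channel
#'
#' Separable Gaussian convolution with reflective (mirrored) borders.  The
#' kernel is truncated at 3.5 standard deviations and renormalised, so a
#' constant channel is returned unchanged and the channel mean is conserved
#' to machine precision.  `radius` follows the convention of common image
#' analysis tools where the "radius" parameter is the Gaussian sigma in
#' pixels; pass `sigma` explicitly to use another interpretation.
#'
#' @param channel A `scalar_channel`.
#' @param radius Smoothing radius in pixels (> 0); default 2, the standard
#'   setting of this workflow.
#' @param sigma Gaussian standard deviation in pixels; defaults to `radius`.
#' @return The smoothed `scalar_channel` with `smoothing_radius` recorded.
#' @export
gaussian_smooth <- function(channel, radius = 2, sigma = radius) {
  if (!inherits(channel, "scalar_channel"))
    stop("`channel` must be a scalar_channel", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number", call. = FALSE)
  w <- .gauss_kernel(sigma)
  k <- (length(w) - 1L) %/% 2L
  x <- channel$values
  h <- nrow(x); wd <- ncol(x)
  # rows (vertical pass)
  xp <- x[.reflect_idx(h, k), , drop = FALSE]
  out <- matrix(0, h, wd)
  for (d in seq_along(w))
    out <- out + w[d] * xp[(d - 1L) + seq_len(h), , drop = FALSE]
  # columns (horizontal pass)
  xp <- out[, .reflect_idx(wd, k), drop = FALSE]
  out <- matrix(0, h, wd)
  for (d in seq_along(w))
    out <- out + w[d] * xp[, (d - 1L) + seq_len(wd), drop = FALSE]
  scalar_channel(out, name = channel$name, smoothing_radius = radius)
}
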