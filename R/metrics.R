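# Detection and yield evaluation metrics, plus the NDVI formula used for
# vigour zoning.

#' True positive rate of cluster detection
#'
#' Percentage of observed clusters that the automatic method detects:
#' `detected / observed * 100`.  `detected` is normally the (per-vine mean)
#' adjusted UAV count and `observed` the ground-observed cluster count.  Not
#' clamped: over-detection can exceed 100.
#'
#' @param detected Detected (adjusted) cluster count; scalar or vector.
#' @param observed Observed total cluster count (> 0).
#' @return TPR in percent.
#' @examples
#' tpr(5.2, 6.0)  # 86.7
#' @export
tpr <- function(detected, observed) {
  if (any(observed <= 0)) stop("`observed` must be positive", call. = FALSE)
  if (any(detected < 0)) stop("`detected` must be non-negative", call. = FALSE)
  detected / observed * 100
}

#' True positive rate restricted to ripe clusters
#'
#' As [tpr()] but with the denominator reduced by the green (unripe) cluster
#' count: `detected / (observed - green) * 100`.  The segmentation targets
#' coloured ripe bunches, so this is the fairer sensitivity measure.
#'
#' @param detected Detected (adjusted) cluster count.
#' @param observed Observed total cluster count.
#' @param green Observed green (unripe) cluster count; `observed - green`
#'   must be positive.
#' @return TPR on ripe clusters, in percent.
#' @examples
#' tpr_ripe(5.2, 6.0, 0.8)  # 100
#' @export
tpr_ripe <- function(detected, observed, green) {
  if (any(green < 0) || any(green > observed))
    stop("`green` must lie in [0, observed]", call. = FALSE)
  ripe <- observed - green
  if (any(ripe <= 0)) stop("no ripe clusters: TPR_ripe undefined", call. = FALSE)
  detected / ripe * 100
}

#' Signed percent error of a yield estimate
#'
#' `(measured - estimated) / measured * 100`; positive for under-estimation.
#'
#' @param measured Measured (ground-truth) yield, > 0.
#' @param estimated Estimated yield, >= 0.
#' @return Signed percent error.
#' @export
percent_error <- function(measured, estimated) {
  if (any(measured <= 0)) stop("`measured` must be positive", call. = FALSE)
  (measured - estimated) / measured * 100
}

#' Percent accuracy of a yield estimate
#'
#' `(1 - |measured - estimated| / measured) * 100`.  The absolute error makes
#' over- and under-estimation symmetric; gross over-estimation can drive the
#' value negative.  Satisfies `accuracy_pct + |percent_error| = 100`.
#'
#' @inheritParams percent_error
#' @return Percent accuracy.
#' @examples
#' accuracy_pct(803.7, 682.7)  # 84.9
#' @export
accuracy_pct <- function(measured, estimated) {
  if (any(measured <= 0)) stop("`measured` must be positive", call. = FALSE)
  (1 - abs(measured - estimated) / measured) * 100
}

#' Normalized difference vegetation index
#'
#' `NDVI = (Rnir - Rred) / (Rnir + Rred)` from near-infrared and red
#' reflectance in `[0, 1]`; bounded in `[-1, 1]`.
#'
#' @param r_nir Near-infrared reflectance in `[0, 1]`.
#' @param r_red Red reflectance in `[0, 1]`.
#' @return NDVI value(s) in `[-1, 1]`.
#' @examples
#' ndvi(0.8, 0.2)  # 0.6
#' @export
ndvi <- function(r_nir, r_red) {
  if (any(r_nir < 0 | r_nir > 1) || any(r_red < 0 | r_red > 1))
    stop("reflectances must lie in [0, 1]", call. = FALSE)
  if (any(r_nir + r_red == 0))
    stop("NDVI undefined when both reflectances are zero", call. = FALSE)
  (r_nir - r_red) / (r_nir + r_red)
}
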