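# Per-vine aggregation, the cluster-area -> cluster-weight regression, and
# season-transfer yield prediction.

#' Aggregate a vine's detected particles into a vine record
#'
#' Sums the retained, calibrated cluster areas of one vine's particle set and
#' carries the raw and adjusted counts.  Ground-truth fields (observed
#' cluster count, green-cluster count, measured yield) can be attached when
#' available.
#'
#' @param particles A measured, filtered and adjusted `particle_set` with a
#'   calibration (yield work is in cm^2).
#' @param vine_id Vine label.
#' @param zone Vigour zone, `"HV"` or `"LV"` (or other label).
#' @param condition Acquisition condition, `"B"` (best) or `"W"` (worst).
#' @param observed_count,green_count,measured_yield_g Optional ground truth.
#' @return A one-row data frame (a vine record).
#' @export
aggregate_vine <- function(particles, vine_id, zone = NA_character_,
                           condition = NA_character_,
                           observed_count = NA_integer_,
                           green_count = NA_integer_,
                           measured_yield_g = NA_real_) {
  stopifnot(inherits(particles, "particle_set"))
  p <- particles$particles
  if (nrow(p) > 0L && anyNA(p$area_cm2))
    stop("particle set is uncalibrated: cannot aggregate areas in cm^2",
         call. = FALSE)
  if (!is.na(green_count) && !is.na(observed_count) &&
      green_count > observed_count)
    stop("green_count cannot exceed observed_count", call. = FALSE)
  data.frame(
    vine_id = as.character(vine_id),
    vigor_zone = zone,
    condition = condition,
    total_cluster_area_cm2 = if (nrow(p)) sum(p$area_cm2) else 0,
    detected_count = nrow(p),
    adjusted_count = particles$adjusted_count,
    observed_count = observed_count,
    green_count = green_count,
    measured_yield_g = measured_yield_g,
    stringsAsFactors = FALSE
  )
}

#' Fit the cluster-area to yield regression
#'
#' Ordinary least squares of measured yield per vine (g) on total detected
#' cluster area per vine (cm^2), with intercept by default.  A
#' through-origin variant is available since zero detected area should imply
#' zero yield, but the intercept form is the default reporting convention.
#'
#' @param records Data frame of vine records with columns
#'   `total_cluster_area_cm2` and `measured_yield_g` (rows with either
#'   missing are dropped).
#' @param through_origin If `TRUE`, fit without intercept.
#' @param fit_meta Optional label (e.g. season/condition) stored with the fit.
#' @return An `area_weight_model`: `slope` (g per cm^2), `intercept` (g),
#'   `r_squared`, `n_train`, `fit_meta`.
#' @examples
#' rec <- data.frame(total_cluster_area_cm2 = c(10, 20, 30),
#'                   measured_yield_g = c(50, 90, 130))
#' fit_area_weight_regression(rec)  # slope 4, intercept 10, R^2 = 1
#' @export
fit_area_weight_regression <- function(records, through_origin = FALSE,
                                       fit_meta = NULL) {
  need <- c("total_cluster_area_cm2", "measured_yield_g")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  d <- records[stats::complete.cases(records[need]), need]
  if (nrow(d) < 2L)
    stop("need at least 2 complete records to fit", call. = FALSE)
  x <- d$total_cluster_area_cm2
  y <- d$measured_yield_g
  if (!through_origin && stats::var(x) == 0)
    stop("zero variance in cluster area: degenerate fit", call. = FALSE)
  fit <- if (through_origin) lm(y ~ x + 0) else lm(y ~ x)
  cf <- coef(fit)
  yhat <- stats::fitted(fit)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(
    slope = unname(if (through_origin) cf["x"] else cf["x"]),
    intercept = unname(if (through_origin) 0 else cf["(Intercept)"]),
    r_squared = max(0, min(1, r2)),
    n_train = nrow(d),
    through_origin = through_origin,
    fit_meta = fit_meta
  ), class = "area_weight_model")
}

#' @export
print.area_weight_model <- function(x, ...) {
  cat(sprintf(
    "<area_weight_model> yield[g] = %.4g * area[cm^2] %+.4g  (R^2 = %.3f, n = %d%s)\n",
    x$slope, x$intercept, x$r_squared, x$n_train,
    if (is.null(x$fit_meta)) "" else paste0(", ", x$fit_meta)))
  invisible(x)
}

#' Predict yield from detected cluster area
#'
#' Evaluates the fitted line on each record's total cluster area.  Negative
#' predictions (possible with a negative intercept at very small areas) are
#' clamped to zero with a warning.
#'
#' @param model An `area_weight_model`.
#' @param records Vine-record data frame with `total_cluster_area_cm2`, or a
#'   numeric vector of areas (cm^2).
#' @return Numeric vector of estimated yields in grams.
#' @export
predict_yield <- function(model, records) {
  if (!inherits(model, "area_weight_model"))
    stop("`model` must be a fitted area_weight_model", call. = FALSE)
  area <- if (is.data.frame(records)) {
    if (!"total_cluster_area_cm2" %in% names(records))
      stop("records need column total_cluster_area_cm2", call. = FALSE)
    records$total_cluster_area_cm2
  } else {
    as.numeric(records)
  }
  est <- model$slope * area + model$intercept
  if (any(est < 0)) {
    warning("negative yield prediction(s) clamped to 0")
    est <- pmax(0, est)
  }
  est
}

#' Save / load an area-weight model as JSON
#'
#' @param model An `area_weight_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "area_weight_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("slope", "intercept", "r_squared", "n_train",
                "through_origin", "fit_meta")],
            class = "area_weight_model")
}
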