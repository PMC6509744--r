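# Ground-vs-UAV survey cost calculator.
#
# Conventions: all times are rounded half-up to 0.1 h *before* multiplying by
# hourly rates (this is the convention that reproduces the published
# reference figures for survey costs and all UAV cells); UAV survey time is
# the decomposition 1 min fixed (take-off/landing) + 2 min per hectare.
# Equipment depreciation is annual: purchase cost / depreciation years,
# rounded to $0.1, and is charged to the UAV mode only.

# round half-up to 1 decimal (R's round() is round-half-even); the 1e-9
# guards against binary representation of exact halves like 0.35
.round_tenth <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Define a survey cost scenario
#'
#' Default rates and timings: ground survey 25 min/ha at $16/h (skilled
#' worker), ground data digitisation 2 min/ha at $16/h; UAV survey 1 min
#' fixed + 2 min/ha at $24/h (trained pilot), image elaboration 10 min/ha at
#' $20/h; UAV + camera purchase $620 depreciated over 3 years.
#'
#' @param area_ha Vineyard area in hectares (> 0).
#' @param mode `"ground"` or `"uav"`.
#' @param survey_rate,elaboration_rate Hourly rates in $/h (defaults depend
#'   on mode).
#' @param ground_survey_min_per_ha,ground_elab_min_per_ha Ground timings.
#' @param uav_fixed_min,uav_min_per_ha,uav_elab_min_per_ha UAV timings.
#' @param equipment_cost,depreciation_years UAV equipment purchase cost ($)
#'   and depreciation cycle (years).
#' @return A `cost_scenario` list.
#' @export
cost_scenario <- function(area_ha, mode = c("ground", "uav"),
                          survey_rate = NULL, elaboration_rate = NULL,
                          ground_survey_min_per_ha = 25,
                          ground_elab_min_per_ha = 2,
                          uav_fixed_min = 1, uav_min_per_ha = 2,
                          uav_elab_min_per_ha = 10,
                          equipment_cost = 620, depreciation_years = 3) {
  mode <- match.arg(mode)
  if (!is.numeric(area_ha) || length(area_ha) != 1L || area_ha <= 0)
    stop("`area_ha` must be a single positive number", call. = FALSE)
  if (is.null(survey_rate)) survey_rate <- if (mode == "ground") 16 else 24
  if (is.null(elaboration_rate)) elaboration_rate <- if (mode == "ground") 16 else 20
  s <- list(area_ha = area_ha, mode = mode, survey_rate = survey_rate,
            elaboration_rate = elaboration_rate,
            ground_survey_min_per_ha = ground_survey_min_per_ha,
            ground_elab_min_per_ha = ground_elab_min_per_ha,
            uav_fixed_min = uav_fixed_min, uav_min_per_ha = uav_min_per_ha,
            uav_elab_min_per_ha = uav_elab_min_per_ha,
            equipment_cost = equipment_cost,
            depreciation_years = depreciation_years)
  if (any(unlist(s[-2]) <= 0)) stop("all rates and times must be positive", call. = FALSE)
  structure(s, class = "cost_scenario")
}

#' Survey time for a scenario
#'
#' Ground: 25 min/ha.  UAV: 1 min take-off/landing + 2 min/ha image
#' acquisition.  Converted to hours and rounded half-up to 0.1 h.
#'
#' @param s A `cost_scenario`.
#' @return Survey time in hours (0.1 h resolution).
#' @examples
#' survey_time_h(cost_scenario(5, "ground"))  # 2.1
#' survey_time_h(cost_scenario(50, "uav"))    # 1.7
#' @export
survey_time_h <- function(s) {
  stopifnot(inherits(s, "cost_scenario"))
  minutes <- if (s$mode == "ground") s$ground_survey_min_per_ha * s$area_ha
             else s$uav_fixed_min + s$uav_min_per_ha * s$area_ha
  .round_tenth(minutes / 60)
}

#' Full cost breakdown for a scenario
#'
#' @param s A `cost_scenario`.
#' @return A `cost_breakdown` list: `survey_time_h`, `survey_cost`,
#'   `elaboration_time_h`, `elaboration_cost`, `total_time_h`,
#'   `equipment_cost_annual` (0 for ground), `total_cost`,
#'   `total_cost_excl_equipment`.
#' @examples
#' cost_breakdown(cost_scenario(5, "uav"))$total_cost  # 227.5
#' @export
cost_breakdown <- function(s) {
  stopifnot(inherits(s, "cost_scenario"))
  st <- survey_time_h(s)
  elab_min <- if (s$mode == "ground") s$ground_elab_min_per_ha * s$area_ha
              else s$uav_elab_min_per_ha * s$area_ha
  et <- .round_tenth(elab_min / 60)
  equip <- if (s$mode == "uav")
    .round_tenth(s$equipment_cost / s$depreciation_years) else 0
  survey_cost <- st * s$survey_rate
  elab_cost <- et * s$elaboration_rate
  structure(list(
    mode = s$mode, area_ha = s$area_ha,
    survey_time_h = st, survey_cost = survey_cost,
    elaboration_time_h = et, elaboration_cost = elab_cost,
    total_time_h = st + et,
    equipment_cost_annual = equip,
    total_cost = survey_cost + elab_cost + equip,
    total_cost_excl_equipment = survey_cost + elab_cost
  ), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<%s, %g ha> survey %.1f h ($%.1f) + elaboration %.1f h ($%.1f)%s = $%.1f (excl. equipment $%.1f)\n",
    x$mode, x$area_ha, x$survey_time_h, x$survey_cost,
    x$elaboration_time_h, x$elaboration_cost,
    if (x$equipment_cost_annual > 0)
      sprintf(" + equipment $%.1f", x$equipment_cost_annual) else "",
    x$total_cost, x$total_cost_excl_equipment))
  invisible(x)
}

#' Compare ground and UAV survey costs for one vineyard size
#'
#' @param area_ha Vineyard area in hectares.
#' @param ... Passed to [cost_scenario()] for both modes (rate/timing
#'   overrides).
#' @return A `mode_comparison`: both `cost_breakdown`s plus absolute and
#'   relative savings of the UAV mode, with and without the equipment cost.
#' @export
compare_modes <- function(area_ha, ...) {
  g <- cost_breakdown(cost_scenario(area_ha, "ground", ...))
  u <- cost_breakdown(cost_scenario(area_ha, "uav", ...))
  structure(list(
    area_ha = area_ha, ground = g, uav = u,
    savings_abs = g$total_cost - u$total_cost,
    savings_pct = (g$total_cost - u$total_cost) / g$total_cost * 100,
    savings_abs_excl_equipment = g$total_cost - u$total_cost_excl_equipment,
    savings_pct_excl_equipment =
      (g$total_cost - u$total_cost_excl_equipment) / g$total_cost * 100,
    time_saved_h = g$total_time_h - u$total_time_h
  ), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf("Survey cost comparison at %g ha\n", x$area_ha))
  print(x$ground); print(x$uav)
  cat(sprintf("UAV saves $%.1f (%.1f%%) excluding equipment; %+.1f h of work\n",
              x$savings_abs_excl_equipment, x$savings_pct_excl_equipment,
              x$time_saved_h))
  invisible(x)
}

#' Cost table over several vineyard sizes
#'
#' @param areas_ha Vector of areas (default the reference sizes 5, 10, 50).
#' @param ... Overrides passed to [cost_scenario()].
#' @return Data frame, one row per mode x area, mirroring the calculator's
#'   column layout.
#' @export
cost_table <- function(areas_ha = c(5, 10, 50), ...) {
  rows <- lapply(areas_ha, function(a) {
    lapply(c("ground", "uav"), function(m) {
      b <- cost_breakdown(cost_scenario(a, m, ...))
      data.frame(mode = m, area_ha = a, survey_time_h = b$survey_time_h,
                 survey_cost = b$survey_cost,
                 elaboration_time_h = b$elaboration_time_h,
                 elaboration_cost = b$elaboration_cost,
                 total_time_h = b$total_time_h,
                 equipment_cost = b$equipment_cost_annual,
                 total_cost = b$total_cost,
                 cost_excl_equipment = b$total_cost_excl_equipment)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out[order(out$mode, out$area_ha), , drop = FALSE]
}
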