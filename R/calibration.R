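#' Off-take calibration configuration
#'
#' The district off-take rate is found by sweeping a grid of uniform rates
#' (10% to 60% of total pixel energy, in 5% steps — eleven rates) and, per
#' district, selecting the lowest rate at which the median maximum grazing
#' distance of household cattle falls below 10 km. Household cattle are the
#' reference because they are the group most tethered to the settlement;
#' districts without household cattle fall back to household sheep+goats.
#'
#' @param rate_grid increasing vector of candidate uniform rates.
#' @param distance_threshold_km the median-distance criterion (strict `<`).
#' @param reference_species,reference_farm_type the defining group.
#' @param fallback_species,fallback_farm_type used where the reference group
#'   has no animals in a district.
#' @param default_rate rate given, in the final run, to settlements of
#'   districts with neither group (provenance `"none"`).
#' @return list of class `calibration_config`.
#' @export
calibration_config <- function(rate_grid = seq(0.10, 0.60, by = 0.05),
                               distance_threshold_km = 10,
                               reference_species = "cattle",
                               reference_farm_type = "HH",
                               fallback_species = "sheep_goats",
                               fallback_farm_type = "HH",
                               default_rate = 0.10) {
  if (is.unsorted(rate_grid, strictly = TRUE)) {
    rlang::abort("`rate_grid` must be strictly increasing.",
                 class = "grazemap_error_config")
  }
  if (distance_threshold_km <= 0) {
    rlang::abort("`distance_threshold_km` must be positive.",
                 class = "grazemap_error_config")
  }
  structure(list(rate_grid = rate_grid,
                 distance_threshold_km = distance_threshold_km,
                 reference_species = reference_species,
                 reference_farm_type = reference_farm_type,
                 fallback_species = fallback_species,
                 fallback_farm_type = fallback_farm_type,
                 default_rate = default_rate),
            class = "calibration_config")
}

# Per-district median of reference-group max distances for one uniform run.
# Settlements with zero demand in the group do not enter the median (the
# statistic is over settlements that actually graze the group).
district_reference_medians <- function(summary, settlements, config) {
  ref <- summary |>
    dplyr::filter(.data$species == config$reference_species,
                  .data$farm_type == config$reference_farm_type,
                  .data$demand_mj > 0)
  fb <- summary |>
    dplyr::filter(.data$species == config$fallback_species,
                  .data$farm_type == config$fallback_farm_type,
                  .data$demand_mj > 0)
  dist_of <- function(df) {
    df |>
      dplyr::left_join(settlements |>
                         dplyr::select("settlement_id", "district_id"),
                       by = "settlement_id") |>
      dplyr::group_by(.data$district_id) |>
      dplyr::summarise(median_km = stats::median(.data$max_distance_km),
                       .groups = "drop")
  }
  list(reference = dist_of(ref), fallback = dist_of(fb))
}

#' Calibrate district off-take rates
#'
#' Runs the full nine-group allocation once per candidate rate, measures per
#' district the median maximum grazing distance of the reference group
#' (household cattle; household sheep+goats where there are none), and
#' assigns each district the lowest rate whose median is strictly below the
#' threshold. Districts that fail even at the highest rate receive that rate
#' with provenance `"ceiling"`; districts with neither reference nor fallback
#' animals receive `NA` with provenance `"none"`.
#'
#' @param supply a `graze_supply`.
#' @param demand settlement-level demand ([settlement_demand()]).
#' @param settlements settlement table (with `district_id`).
#' @param config a [calibration_config()].
#' @param specs group table, defaults to [group_specs()].
#' @return tibble of class `graze_offtake`: `district_id`, `rate`,
#'   `provenance`, `median_km` (median distance at the assigned rate). The
#'   full rate-by-district median matrix is kept in the `"sweep"` attribute
#'   and each run's glance in `"sweep_glance"`.
#' @export
calibrate_offtake <- function(supply, demand, settlements,
                              config = calibration_config(),
                              specs = group_specs()) {
  districts_all <- sort(unique(settlements$district_id))
  has_ref <- demand |>
    dplyr::filter(.data$species == config$reference_species,
                  .data$farm_type == config$reference_farm_type,
                  .data$grazing_demand_mj > 0) |>
    dplyr::distinct(.data$district_id)
  has_fb <- demand |>
    dplyr::filter(.data$species == config$fallback_species,
                  .data$farm_type == config$fallback_farm_type,
                  .data$grazing_demand_mj > 0) |>
    dplyr::distinct(.data$district_id)

  sweep <- purrr::map(config$rate_grid, function(rate) {
    run <- run_allocation(supply, demand, settlements, rate, specs = specs,
                          quiet = TRUE)
    med <- district_reference_medians(run$summary, settlements, config)
    list(medians = med, glance = glance(run))
  })
  names(sweep) <- sprintf("%.2f", config$rate_grid)

  med_at <- function(i, district, which) {
    tab <- sweep[[i]]$medians[[which]]
    m <- tab$median_km[match(district, tab$district_id)]
    ifelse(is.na(m), 0, m)  # no grazing settlements -> trivially satisfied
  }

  rows <- purrr::map(districts_all, function(d) {
    use <- if (d %in% has_ref$district_id) "reference"
           else if (d %in% has_fb$district_id) "fallback"
           else return(tibble::tibble(district_id = d, rate = NA_real_,
                                      provenance = "none",
                                      median_km = NA_real_))
    meds <- vapply(seq_along(config$rate_grid), med_at, numeric(1),
                   district = d, which = use)
    ok <- meds < config$distance_threshold_km
    if (any(ok)) {
      i <- which(ok)[1]
      tibble::tibble(district_id = d, rate = config$rate_grid[i],
                     provenance = use, median_km = meds[i])
    } else {
      i <- length(config$rate_grid)
      tibble::tibble(district_id = d, rate = config$rate_grid[i],
                     provenance = "ceiling", median_km = meds[i])
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sweep") <- purrr::map(sweep, "medians")
  attr(out, "sweep_glance") <- dplyr::bind_rows(
    purrr::map(sweep, "glance"), .id = "rate")
  attr(out, "config") <- config
  class(out) <- c("graze_offtake", class(out))
  out
}

#' Re-run the allocation with calibrated district rates
#'
#' Every settlement grazes at its district's calibrated rate wherever it
#' claims pixels (rates follow the herd, not the district boundary).
#' Settlements in districts with provenance `"none"` use the configured
#' default rate.
#'
#' @param supply a `graze_supply`.
#' @param demand settlement-level demand.
#' @param settlements settlement table with `district_id`.
#' @param assignment a [calibrate_offtake()] result.
#' @param specs group table.
#' @param quiet suppress unmet-demand warnings.
#' @return a `graze_allocation` (the variable-rate intensity map).
#' @export
run_calibrated <- function(supply, demand, settlements, assignment,
                           specs = group_specs(), quiet = FALSE) {
  config <- attr(assignment, "config")
  default_rate <- if (!is.null(config)) config$default_rate else 0.10
  rate <- assignment$rate[match(settlements$district_id,
                                assignment$district_id)]
  if (any(is.na(rate) & !settlements$district_id %in% assignment$district_id)) {
    rlang::abort("Assignment does not cover all districts.",
                 class = "grazemap_error_validation")
  }
  rate[is.na(rate)] <- default_rate
  run_allocation(supply, demand, settlements,
                 tibble::tibble(settlement_id = settlements$settlement_id,
                                rate = rate),
                 specs = specs, quiet = quiet)
}
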