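#' Scenario configuration for production-expansion estimates
#'
#' @param radius_km settlements are assumed able to use land within this
#'   distance (10 km conservative, 20 km optimistic).
#' @param max_rate the maximum sustainable off-take rate of total pixel
#'   energy (default 0.30, i.e. 40% of the ~77% aboveground share).
#' @param dairy_fractions named fractions of cattle classified as dairy per
#'   farm type; used to pro-rate cattle pasture between meat and milk.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(radius_km = 10, max_rate = 0.30,
                            dairy_fractions = c(AE = 0.40, PF = 0.50,
                                                HH = 0.85)) {
  if (radius_km <= 0) {
    rlang::abort("`radius_km` must be positive.",
                 class = "grazemap_error_config")
  }
  if (any(dairy_fractions < 0 | dairy_fractions > 1)) {
    rlang::abort("`dairy_fractions` must lie in [0, 1].",
                 class = "grazemap_error_config")
  }
  structure(list(radius_km = radius_km, max_rate = max_rate,
                 dairy_fractions = dairy_fractions),
            class = "scenario_config")
}

#' Meat and milk productivity of utilized pasture
#'
#' Divides reported production by the pasture area the model allocated to
#' each species and farm type. Cattle pasture is pro-rated by the dairy
#' fraction before computing milk productivity (dairy animals use that share
#' of the land), so meat and milk yields are not additive for cattle.
#'
#' @param production tibble `species`, `farm_type`, `meat_t`, `milk_t`
#'   (annual production, tonnes).
#' @param area output of [utilized_area()] (or any tibble `species`,
#'   `farm_type`, `area_km2`).
#' @param dairy_fractions named vector as in [scenario_config()].
#' @return tibble with areas, production and `meat_t_per_km2`,
#'   `milk_t_per_km2` yields.
#' @export
productivity_table <- function(production, area,
                               dairy_fractions = c(AE = 0.40, PF = 0.50,
                                                   HH = 0.85)) {
  out <- production |>
    dplyr::left_join(area |> dplyr::select("species", "farm_type", "area_km2"),
                     by = c("species", "farm_type"))
  bad <- out |>
    dplyr::filter((.data$meat_t > 0 | .data$milk_t > 0) &
                    (is.na(.data$area_km2) | .data$area_km2 == 0))
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "Zero utilized area for %s/%s with non-zero production.",
      bad$species[1], bad$farm_type[1]),
      class = "grazemap_error_validation")
  }
  out |>
    dplyr::mutate(
      dairy_fraction = ifelse(.data$species == "cattle",
                              unname(dairy_fractions[.data$farm_type]), 1),
      meat_t_per_km2 = ifelse(.data$area_km2 > 0,
                              .data$meat_t / .data$area_km2, 0),
      milk_area_km2 = .data$area_km2 * .data$dairy_fraction,
      milk_t_per_km2 = ifelse(.data$milk_area_km2 > 0,
                              .data$milk_t / .data$milk_area_km2, 0))
}

pixel_rate_raster <- function(supply, districts, assignment, default_rate) {
  rate <- assignment$rate[match(districts$values, assignment$district_id)]
  rate[is.na(rate)] <- default_rate
  matrix(rate, nrow(districts$values), ncol(districts$values))
}

#' Production-expansion potential of unutilized pasture
#'
#' Considers land within `radius_km` of any settlement as currently usable.
#' Under business-as-usual (`BAU`) the unclaimed grazeable pixels inside
#' that radius yield energy at their district's calibrated off-take rate;
#' under `max` the allocation is re-run at the uniform maximum sustainable
#' rate and the then-unclaimed pixels yield at that rate. Additional energy
#' is converted to additional beef or milk (an either/or use of the same
#' land) by two labelled paths reported side by side: `area` (additional
#' area times the baseline per-km2 productivity of enterprise cattle) and
#' `energy` (additional energy divided by per-head demand times per-head
#' product).
#'
#' @param result the calibrated `graze_allocation` (BAU baseline run).
#' @param supply the `graze_supply` used for the run.
#' @param settlements settlement table.
#' @param districts `graze_raster` of district ids.
#' @param assignment a [calibrate_offtake()] result.
#' @param baseline_production tibble `species`, `farm_type`, `meat_t`,
#'   `milk_t` — 2015-style production statistics, used for the baseline and
#'   the area-path productivity.
#' @param per_head optional list with `mj_per_head` (annual energy demand of
#'   an enterprise cow), `beef_kg_per_head`, `milk_kg_per_head`; enables the
#'   energy conversion path.
#' @param config a [scenario_config()].
#' @param demand,specs inputs needed to re-run the allocation in `max` mode.
#' @return one-row tibble per mode with additional area, energy and
#'   production under both conversion paths, plus percent increases over the
#'   baseline.
#' @export
expansion_potential <- function(result, supply, settlements, districts,
                                assignment, baseline_production,
                                demand, per_head = NULL,
                                config = scenario_config(),
                                specs = group_specs()) {
  stopifnot(inherits(result, "graze_allocation"))
  if (is.null(assignment)) {
    rlang::abort("An off-take assignment is required.",
                 class = "grazemap_error_validation")
  }
  er <- supply$energy
  nr <- nrow(er$values); nc <- ncol(er$values)
  y0top <- er$yll + nr * er$cell_size
  dist <- matrix(cpp_nearest_settlement(nr, nc, er$cell_size, er$xll, y0top,
                                        settlements$x, settlements$y),
                 nr, nc, byrow = TRUE)
  within <- dist <= config$radius_km * 1000
  usable <- supply$usable$values > 0
  energy_px <- er$values * cell_area(er)
  cfg <- attr(assignment, "config")
  default_rate <- if (!is.null(cfg)) cfg$default_rate else 0.10
  rate_px <- pixel_rate_raster(supply, districts, assignment, default_rate)

  area_of <- function(mask) sum(mask) * cell_area(er) / 1e6

  # baseline productivity of enterprise cattle (the expansion carrier);
  # NA-yield (and so an NA area path) when they have no claims footprint
  ua <- utilized_area(result)
  ae_area <- ua$area_km2[ua$species == "cattle" & ua$farm_type == "AE"]
  ae_meat <- sum(baseline_production$meat_t[
    baseline_production$species == "cattle" &
      baseline_production$farm_type == "AE"])
  ae_milk <- sum(baseline_production$milk_t[
    baseline_production$species == "cattle" &
      baseline_production$farm_type == "AE"])
  daf <- unname(config$dairy_fractions["AE"])
  ae <- tibble::tibble(
    meat_t_per_km2 = if (length(ae_area) && ae_area > 0)
      ae_meat / ae_area else NA_real_,
    milk_t_per_km2 = if (length(ae_area) && ae_area > 0 && daf > 0)
      ae_milk / (ae_area * daf) else NA_real_)
  baseline_beef <- sum(baseline_production$meat_t[
    baseline_production$species == "cattle"])
  baseline_milk <- sum(baseline_production$milk_t[
    baseline_production$species == "cattle"])

  scen_row <- function(mode, mask, rate_mat) {
    add_area <- area_of(mask)
    add_energy <- sum(rate_mat[mask] * energy_px[mask])
    beef_area <- add_area * ae$meat_t_per_km2[1]
    milk_area <- add_area * unname(config$dairy_fractions["AE"]) *
      ae$milk_t_per_km2[1]
    if (!is.null(per_head)) {
      heads <- add_energy / per_head$mj_per_head
      beef_energy <- heads * per_head$beef_kg_per_head / 1000
      milk_energy <- heads * per_head$milk_kg_per_head / 1000
    } else {
      beef_energy <- NA_real_
      milk_energy <- NA_real_
    }
    tibble::tibble(
      mode = mode, radius_km = config$radius_km,
      additional_area_km2 = add_area,
      additional_energy_pj = add_energy / 1e9,
      beef_t_area_path = beef_area, milk_t_area_path = milk_area,
      beef_t_energy_path = beef_energy, milk_t_energy_path = milk_energy,
      beef_pct_area_path = 100 * beef_area / baseline_beef,
      milk_pct_area_path = 100 * milk_area / baseline_milk,
      beef_pct_energy_path = 100 * beef_energy / baseline_beef,
      milk_pct_energy_path = 100 * milk_energy / baseline_milk
    )
  }

  unclaimed_bau <- is.na(result$claim$values) & usable & within
  rows <- scen_row("BAU", unclaimed_bau, rate_px)

  max_run <- run_allocation(supply, demand, settlements, config$max_rate,
                            specs = specs, quiet = TRUE)
  unclaimed_max <- is.na(max_run$claim$values) & usable & within
  rate_max <- matrix(config$max_rate, nr, nc)
  rows <- dplyr::bind_rows(rows, scen_row("max", unclaimed_max, rate_max))
  rows
}

#' Partition of the landscape by allocation outcome
#'
#' Every pixel is exactly one of: claimed, unclaimed-but-within-radius
#' (expansion candidate), unclaimed-out-of-range, or excluded cover.
#'
#' @param result a `graze_allocation`.
#' @param supply the matching `graze_supply`.
#' @param settlements settlement table.
#' @param radius_km reachability radius.
#' @return tibble with one row per category: `n_pixels` and `area_km2`.
#' @export
landscape_partition <- function(result, supply, settlements, radius_km = 10) {
  er <- supply$energy
  nr <- nrow(er$values); nc <- ncol(er$values)
  y0top <- er$yll + nr * er$cell_size
  dist <- matrix(cpp_nearest_settlement(nr, nc, er$cell_size, er$xll, y0top,
                                        settlements$x, settlements$y),
                 nr, nc, byrow = TRUE)
  usable <- supply$usable$values > 0
  claimed <- !is.na(result$claim$values)
  within <- dist <= radius_km * 1000
  cat_mat <- ifelse(!usable, "excluded",
                    ifelse(claimed, "claimed",
                           ifelse(within, "expansion_candidate",
                                  "out_of_range")))
  tibble::tibble(category = c("claimed", "expansion_candidate",
                              "out_of_range", "excluded")) |>
    dplyr::mutate(n_pixels = vapply(.data$category,
                                    function(k) sum(cat_mat == k), integer(1)),
                  area_km2 = .data$n_pixels * cell_area(er) / 1e6)
}
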