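#' @importFrom rlang .data
NULL

GRAZING_SPECIES <- c("cattle", "sheep_goats", "horses")
FARM_TYPES <- c("HH", "PF", "AE")

#' Disaggregate district herd counts into age/function groups
#'
#' District livestock totals are reported without age structure; the herd
#' composition is only known at the province level from an older agricultural
#' census. Each district's count for a species and farm type is split across
#' age groups in proportion to the province-level census composition:
#' `head(group, district) = head(district) * census(group, province) /
#' census(species total, province)`. Group counts therefore sum exactly back
#' to the district totals.
#'
#' @param district_counts tibble with columns `district_id`, `province_id`,
#'   `species`, `farm_type`, `head`.
#' @param census tibble with columns `province_id`, `species`, `age_group`,
#'   `head` (census-year counts defining the composition).
#' @return tibble with columns `district_id`, `province_id`, `species`,
#'   `farm_type`, `age_group`, `head`.
#' @export
disaggregate_herd_ages <- function(district_counts, census) {
  check_nonneg(district_counts$head, "district livestock counts")
  check_nonneg(census$head, "census counts")
  totals <- census |>
    dplyr::group_by(.data$province_id, .data$species) |>
    dplyr::summarise(census_total = sum(.data$head), .groups = "drop")
  joined <- district_counts |>
    dplyr::left_join(totals, by = c("province_id", "species"))
  bad <- joined |>
    dplyr::filter(.data$head > 0 &
                    (is.na(.data$census_total) | .data$census_total == 0))
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "No census composition for species '%s' in province of district '%s' (count %g > 0).",
      bad$species[1], bad$district_id[1], bad$head[1]),
      class = "grazemap_error_validation")
  }
  joined |>
    dplyr::left_join(census, by = c("province_id", "species"),
                     suffix = c("", "_census"),
                     relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$age_group) | .data$head == 0) |>
    dplyr::mutate(head = ifelse(.data$head == 0, 0,
                                .data$head * .data$head_census / .data$census_total)) |>
    dplyr::select("district_id", "province_id", "species", "farm_type",
                  "age_group", "head")
}

#' Total annual energy demand of the herd
#'
#' Multiplies age-group head counts by the annual metabolisable-energy
#' requirement of that group (MJ/head/yr) and sums within district, species
#' and farm type. Requirements differ by farm type because animal growth
#' rates (and hence feeding levels) differ across farm structures.
#'
#' @param age_counts output of [disaggregate_herd_ages()].
#' @param nutritive tibble with columns `species`, `age_group`, `farm_type`,
#'   `mj_per_head` (annual requirement, > 0).
#' @return tibble `district_id`, `province_id`, `species`, `farm_type`,
#'   `total_demand_mj`.
#' @export
herd_energy_demand <- function(age_counts, nutritive) {
  if (any(nutritive$mj_per_head <= 0)) {
    rlang::abort("Nutritive requirements must be positive.",
                 class = "grazemap_error_config")
  }
  missing <- age_counts |>
    dplyr::filter(.data$head > 0) |>
    dplyr::anti_join(nutritive, by = c("species", "age_group", "farm_type"))
  if (nrow(missing) > 0) {
    rlang::abort(sprintf(
      "No nutritive requirement for (%s, %s, %s).",
      missing$species[1], missing$age_group[1], missing$farm_type[1]),
      class = "grazemap_error_config")
  }
  age_counts |>
    dplyr::left_join(nutritive, by = c("species", "age_group", "farm_type")) |>
    dplyr::group_by(.data$district_id, .data$province_id, .data$species,
                    .data$farm_type) |>
    dplyr::summarise(
      total_demand_mj = sum(.data$head * dplyr::coalesce(.data$mj_per_head, 0)),
      .groups = "drop")
}

#' Allocate district fodder production to livestock species
#'
#' Converts the harvested mass of each fodder type to energy (via per-type
#' MJ/kg ratios expressed through feed units) and assigns it to species using
#' province-level consumption shares. Only the grazing species (cattle,
#' sheep+goats, horses) are retained; shares for pigs, poultry and camels
#' merely reduce what grazers receive.
#'
#' @param production tibble `district_id`, `province_id`, `farm_type`,
#'   `fodder_type`, `kg`.
#' @param tables list with `conversion` (tibble `fodder_type`, `mj_per_kg`)
#'   and `shares` (tibble `province_id`, `species`, `share`; shares over all
#'   consuming species sum to at most 1).
#' @return tibble `district_id`, `province_id`, `species`, `farm_type`,
#'   `fodder_mj`.
#' @export
allocate_fodder <- function(production, tables) {
  check_nonneg(production$kg, "fodder production")
  unknown <- setdiff(unique(production$fodder_type),
                     tables$conversion$fodder_type)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("No energy conversion for fodder type '%s'.",
                         unknown[1]),
                 class = "grazemap_error_config")
  }
  bad_share <- tables$shares |>
    dplyr::group_by(.data$province_id) |>
    dplyr::summarise(s = sum(.data$share), .groups = "drop") |>
    dplyr::filter(.data$s > 1 + 1e-9)
  if (nrow(bad_share) > 0 || any(tables$shares$share < 0)) {
    rlang::abort("Consumption shares must be in [0,1] and sum to at most 1 per province.",
                 class = "grazemap_error_config")
  }
  grazers <- tables$shares |> dplyr::filter(.data$species %in% GRAZING_SPECIES)
  production |>
    dplyr::left_join(tables$conversion, by = "fodder_type") |>
    dplyr::left_join(grazers, by = "province_id",
                     relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::group_by(.data$district_id, .data$province_id, .data$species,
                    .data$farm_type) |>
    dplyr::summarise(fodder_mj = sum(.data$kg * .data$mj_per_kg * .data$share),
                     .groups = "drop")
}

#' Combine demand and fodder into the grazing-demand ledger
#'
#' The energy livestock must obtain from pasture is total demand minus the
#' energy supplied as fodder, floored at zero (surplus fodder does not create
#' negative grazing). The *grazing gap* is grazing demand over total demand —
#' the fraction of the herd's energy budget that pasture must cover.
#'
#' @param total_demand output of [herd_energy_demand()].
#' @param fodder_energy output of [allocate_fodder()] (missing keys count as
#'   zero fodder).
#' @return tibble of class `graze_ledger` with columns `district_id`,
#'   `province_id`, `species`, `farm_type`, `total_demand_mj`, `fodder_mj`,
#'   `grazing_demand_mj`, `grazing_gap`.
#' @export
build_demand_ledger <- function(total_demand, fodder_energy = NULL) {
  check_nonneg(total_demand$total_demand_mj, "total demand")
  if (is.null(fodder_energy)) {
    fodder_energy <- total_demand |>
      dplyr::select("district_id", "province_id", "species", "farm_type") |>
      dplyr::mutate(fodder_mj = 0)
  }
  check_nonneg(fodder_energy$fodder_mj, "fodder energy")
  out <- total_demand |>
    dplyr::full_join(fodder_energy,
                     by = c("district_id", "province_id", "species",
                            "farm_type")) |>
    dplyr::mutate(
      total_demand_mj = dplyr::coalesce(.data$total_demand_mj, 0),
      fodder_mj = dplyr::coalesce(.data$fodder_mj, 0),
      grazing_demand_mj = pmax(.data$total_demand_mj - .data$fodder_mj, 0),
      grazing_gap = ifelse(.data$total_demand_mj > 0,
                           .data$grazing_demand_mj / .data$total_demand_mj, 0))
  class(out) <- c("graze_ledger", class(out))
  out
}

#' National totals of a demand ledger
#'
#' @param ledger a [build_demand_ledger()] result.
#' @return one-row tibble with total demand, fodder and grazing demand in PJ
#'   and the overall grazing gap.
#' @export
ledger_totals <- function(ledger) {
  tot <- sum(ledger$total_demand_mj)
  graz <- sum(ledger$grazing_demand_mj)
  tibble::tibble(
    total_demand_pj = tot / 1e9,
    fodder_pj = sum(ledger$fodder_mj) / 1e9,
    grazing_demand_pj = graz / 1e9,
    grazing_gap = if (tot > 0) graz / tot else 0
  )
}

#' Fraction of residents owning livestock, by settlement size
#'
#' Piecewise-linear relationship between settlement population and the share
#' of residents that keep livestock: 95% up to 1,000 residents, 80% at 5,000,
#' 30% at 10,000, 10% at 50,000 and 0.5% at 1 million, linearly interpolated
#' between knots and constant beyond 1 million. Small villages are almost
#' universally livestock-keeping while cities are not; this drives the
#' population weighting used to split district demand across settlements.
#'
#' @param population numeric vector of settlement populations (>= 0).
#' @return numeric vector of owner fractions in (0, 1).
#' @export
owner_fraction <- function(population) {
  if (any(population < 0, na.rm = TRUE)) {
    rlang::abort("Population must be non-negative.",
                 class = "grazemap_error_validation")
  }
  knots_x <- c(0, 1000, 5000, 10000, 50000, 1e6)
  knots_y <- c(0.95, 0.95, 0.80, 0.30, 0.10, 0.005)
  stats::approx(knots_x, knots_y, xout = pmin(population, 1e6),
                method = "linear", rule = 2)$y
}

#' Split district grazing demand across its settlements
#'
#' Each settlement's weight is `population * owner_fraction(population)` — an
#' estimate of its livestock-owning residents. District grazing demand for
#' every species and farm type is divided proportionally to these weights, so
#' settlement demands sum exactly to the district total.
#'
#' @param ledger a [build_demand_ledger()] result.
#' @param settlements tibble with `settlement_id`, `x`, `y`, `population`,
#'   `district_id`.
#' @return tibble `settlement_id`, `district_id`, `species`, `farm_type`,
#'   `grazing_demand_mj`.
#' @export
settlement_demand <- function(ledger, settlements) {
  w <- settlements |>
    dplyr::mutate(weight = .data$population * owner_fraction(.data$population))
  wtot <- w |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(w_district = sum(.data$weight), .groups = "drop")
  with_demand <- ledger |>
    dplyr::filter(.data$grazing_demand_mj > 0) |>
    dplyr::left_join(wtot, by = "district_id")
  orphan <- with_demand |>
    dplyr::filter(is.na(.data$w_district) | .data$w_district == 0)
  if (nrow(orphan) > 0) {
    rlang::abort(sprintf(
      "District '%s' has grazing demand but no settlement weight.",
      orphan$district_id[1]),
      class = "grazemap_error_validation")
  }
  w |>
    dplyr::select("settlement_id", "district_id", "weight") |>
    dplyr::inner_join(with_demand, by = "district_id",
                      relationship = "many-to-many") |>
    dplyr::mutate(grazing_demand_mj =
                    .data$grazing_demand_mj * .data$weight / .data$w_district) |>
    dplyr::select("settlement_id", "district_id", "species", "farm_type",
                  "grazing_demand_mj") |>
    dplyr::arrange(.data$settlement_id, .data$species, .data$farm_type)
}

check_nonneg <- function(x, what) {
  if (any(x < 0, na.rm = TRUE)) {
    rlang::abort(sprintf("%s must be non-negative.", what),
                 class = "grazemap_error_validation")
  }
  invisible(TRUE)
}
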