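#' The nine allocation groups and their base search radii
#'
#' Demand is distributed group by group in a fixed order reflecting herd
#' mobility: small stock and cattle kept in households move first (they are
#' the most tethered to the settlement), then private farms, then
#' agricultural enterprises, and horses of all farm types last because they
#' stay on pasture overnight and range farthest. Base search radii encode the
#' same mobility: 2 km for household/private-farm cattle and sheep+goats,
#' 5 km for enterprise cattle and sheep+goats, 10 km for horses.
#'
#' @return tibble with columns `order`, `species`, `farm_type`, `radius_km`.
#' @export
group_specs <- function() {
  tibble::tibble(
    order = 1:9,
    species = c("sheep_goats", "cattle", "sheep_goats", "cattle",
                "sheep_goats", "cattle", "horses", "horses", "horses"),
    farm_type = c("HH", "HH", "PF", "PF", "AE", "AE", "HH", "PF", "AE"),
    radius_km = c(2, 2, 2, 2, 5, 5, 10, 10, 10)
  )
}

normalise_offtake <- function(offtake, settlements) {
  if (is.numeric(offtake) && length(offtake) == 1L) {
    rate <- rep(offtake, nrow(settlements))
  } else {
    stopifnot(is.data.frame(offtake),
              all(c("settlement_id", "rate") %in% names(offtake)))
    m <- match(settlements$settlement_id, offtake$settlement_id)
    if (anyNA(m)) {
      rlang::abort("Every settlement needs an off-take rate.",
                   class = "grazemap_error_validation")
    }
    rate <- offtake$rate[m]
  }
  if (any(rate <= 0 | rate > 1)) {
    rlang::abort("Off-take rates must lie in (0, 1].",
                 class = "grazemap_error_validation")
  }
  rate
}

demand_matrix <- function(demand, settlements, specs) {
  if (any(demand$grazing_demand_mj < 0)) {
    rlang::abort("Grazing demand must be non-negative.",
                 class = "grazemap_error_validation")
  }
  m <- matrix(0, nrow(settlements), nrow(specs))
  si <- match(demand$settlement_id, settlements$settlement_id)
  if (anyNA(si)) {
    rlang::abort("Demand refers to settlements not in the settlement table.",
                 class = "grazemap_error_validation")
  }
  gi <- match(paste(demand$species, demand$farm_type),
              paste(specs$species, specs$farm_type))
  keep <- !is.na(gi)
  for (r in which(keep)) {
    m[si[r], gi[r]] <- m[si[r], gi[r]] + demand$grazing_demand_mj[r]
  }
  m
}

#' Distribute settlement grazing demand onto the supply raster
#'
#' Runs the competitive radius-expanding greedy allocation for all nine
#' species-by-farm-type groups in their fixed order over a shared claim mask,
#' so a pixel is claimed by at most one settlement and group across the whole
#' run. Within a group, settlements compete simultaneously: the cumulative
#' search disk grows in integer multiples of the group's base radius, and
#' inside each ring settlements take round-robin turns (ascending settlement
#' id), each claiming its single best unclaimed pixel — highest energy
#' density first, ties broken by distance then row-major index. A claimed
#' pixel yields `offtake * pixel energy`; the final pixel a settlement needs
#' is claimed exclusively but only its residual demand is consumed, so
#' consumed energy balances demand exactly. If the landscape is exhausted
#' before demand is met the settlement is flagged unmet with a warning.
#'
#' @param supply a [build_supply()] result.
#' @param demand settlement-level grazing demand, as returned by
#'   [settlement_demand()].
#' @param settlements tibble `settlement_id`, `x`, `y` (and typically
#'   `district_id`, `population`).
#' @param offtake either a single rate in (0, 1] applied uniformly or a
#'   tibble `settlement_id`, `rate` (settlements use their own rate wherever
#'   they graze, so rates need not follow district boundaries on the map).
#' @param specs group definition table, defaults to [group_specs()].
#' @param claims optional previous `graze_allocation` whose claims are
#'   honoured (used to allocate additional groups onto a partial run).
#' @param quiet suppress the unmet-demand warning.
#' @return an object of class `graze_allocation`; see [tidy.graze_allocation()]
#'   and [glance.graze_allocation()].
#' @export
run_allocation <- function(supply, demand, settlements, offtake,
                           specs = group_specs(), claims = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(supply, "graze_supply"))
  settlements <- dplyr::arrange(settlements, .data$settlement_id)
  rate <- normalise_offtake(offtake, settlements)
  dm <- demand_matrix(demand, settlements, specs)

  er <- supply$energy
  nr <- nrow(er$values); nc <- ncol(er$values)
  energy_total <- as.vector(t(er$values)) * cell_area(er)  # MJ per pixel
  y0top <- er$yll + nr * er$cell_size

  if (is.null(claims)) {
    claim0 <- integer(nr * nc)
    group0 <- integer(nr * nc)
    cons0 <- numeric(nr * nc)
    goff <- 0L
  } else {
    stopifnot(inherits(claims, "graze_allocation"))
    claim0 <- as.integer(t(claims$claim$values))
    claim0[is.na(claim0)] <- 0L
    group0 <- as.integer(t(claims$group$values))
    group0[is.na(group0)] <- 0L
    cons0 <- as.vector(t(claims$consumed$values))
    cons0[is.na(cons0)] <- 0
    goff <- max(group0)
  }

  res <- cpp_allocate(energy_total, nr, nc, er$cell_size, er$xll, y0top,
                      settlements$x, settlements$y, dm,
                      specs$radius_km * 1000, rate,
                      claim0, group0, cons0, goff)

  idx <- tidyr::expand_grid(
    si = seq_len(nrow(settlements)),
    gi = seq_len(nrow(specs))
  )
  summary <- tibble::tibble(
    settlement_id = settlements$settlement_id[idx$si],
    order = specs$order[idx$gi],
    species = specs$species[idx$gi],
    farm_type = specs$farm_type[idx$gi],
    radius_km = specs$radius_km[idx$gi],
    demand_mj = dm[cbind(idx$si, idx$gi)],
    consumed_mj = res$consumed_sg[cbind(idx$si, idx$gi)],
    demand_met = res$met[cbind(idx$si, idx$gi)],
    n_pixels = res$n_pixels[cbind(idx$si, idx$gi)],
    max_distance_km = sqrt(res$max_d2[cbind(idx$si, idx$gi)]) / 1000,
    final_ring = res$final_ring[cbind(idx$si, idx$gi)]
  ) |>
    dplyr::arrange(.data$settlement_id, .data$order)

  unmet <- sum(!summary$demand_met & summary$demand_mj > 0)
  if (unmet > 0 && !quiet) {
    rlang::warn(sprintf(
      "%d settlement-group demand(s) could not be met before the landscape was exhausted.",
      unmet))
  }

  to_raster <- function(v, na_zero = TRUE) {
    m <- matrix(v, nr, nc, byrow = TRUE)
    if (na_zero) m[m == 0] <- NA
    graze_raster(m, er$cell_size, er$xll, er$yll, er$crs_label)
  }
  consumed_r <- to_raster(res$consumed, na_zero = FALSE)
  intensity <- res$consumed / energy_total
  intensity[energy_total <= 0] <- NA_real_

  structure(
    list(
      claim = to_raster(as.numeric(res$claim)),
      group = to_raster(as.numeric(res$group)),
      consumed = consumed_r,
      intensity = to_raster(intensity, na_zero = FALSE),
      summary = summary,
      settlements = settlements,
      offtake = tibble::tibble(settlement_id = settlements$settlement_id,
                               rate = rate),
      specs = specs,
      cell_size = er$cell_size
    ),
    class = "graze_allocation"
  )
}

#' Allocate a single group on top of existing claims
#'
#' Thin wrapper around [run_allocation()] for one species-by-farm-type group,
#' honouring claims from a previous (partial) run.
#'
#' @param supply a `graze_supply`.
#' @param demand per-settlement demand tibble for this group (columns as in
#'   [settlement_demand()]).
#' @param settlements settlement table.
#' @param offtake uniform rate or per-settlement tibble.
#' @param spec one row of [group_specs()].
#' @param claims optional previous `graze_allocation`.
#' @inheritParams run_allocation
#' @export
allocate_group <- function(supply, demand, settlements, offtake, spec,
                           claims = NULL, quiet = FALSE) {
  stopifnot(nrow(spec) == 1L)
  run_allocation(supply, demand, settlements, offtake, specs = spec,
                 claims = claims, quiet = quiet)
}

#' Maximum grazing distance of a settlement's group
#'
#' Euclidean distance (km) from the settlement to the farthest pixel centre
#' it claimed for the given group; 0 if it claimed none.
#'
#' @param result a `graze_allocation`.
#' @param settlement_id settlement identifier.
#' @param species,farm_type group selector.
#' @export
max_grazing_distance <- function(result, settlement_id, species, farm_type) {
  row <- result$summary |>
    dplyr::filter(.data$settlement_id == !!settlement_id,
                  .data$species == !!species,
                  .data$farm_type == !!farm_type)
  if (nrow(row) == 0) return(0)
  row$max_distance_km[1]
}

#' Utilized pasture area by species and farm type
#'
#' @param result a `graze_allocation`.
#' @return tibble `species`, `farm_type`, `n_pixels`, `area_km2`.
#' @export
utilized_area <- function(result) {
  a <- result$cell_size^2 / 1e6
  result$summary |>
    dplyr::group_by(.data$species, .data$farm_type) |>
    dplyr::summarise(n_pixels = sum(.data$n_pixels), .groups = "drop") |>
    dplyr::mutate(area_km2 = .data$n_pixels * a)
}

#' @export
print.graze_allocation <- function(x, ...) {
  g <- glance(x)
  cat("<graze_allocation>\n")
  cat(sprintf("  %d settlements, %d groups; %.4g PJ demand, %.4g PJ consumed\n",
              nrow(x$settlements), nrow(x$specs),
              g$total_demand_pj, g$total_consumed_pj))
  cat(sprintf("  %d pixels claimed (%.0f km2); %.1f%% of demands met\n",
              g$n_pixels, g$utilized_area_km2, 100 * g$frac_groups_met))
  invisible(x)
}

#' Tidy per-settlement allocation summary
#'
#' One row per settlement and group: demand, consumed energy, whether demand
#' was met, claimed pixel count, maximum grazing distance (km) and the final
#' search ring.
#'
#' @param x a `graze_allocation`.
#' @param ... unused.
#' @importFrom generics tidy
#' @export
tidy.graze_allocation <- function(x, ...) x$summary

#' One-row allocation overview
#'
#' @param x a `graze_allocation`.
#' @param ... unused.
#' @importFrom generics glance
#' @export
glance.graze_allocation <- function(x, ...) {
  s <- x$summary
  active <- s$demand_mj > 0
  tibble::tibble(
    total_demand_pj = sum(s$demand_mj) / 1e9,
    total_consumed_pj = sum(s$consumed_mj) / 1e9,
    n_pixels = sum(s$n_pixels),
    utilized_area_km2 = sum(s$n_pixels) * x$cell_size^2 / 1e6,
    frac_groups_met = if (any(active)) mean(s$demand_met[active]) else 1,
    mean_intensity = mean(x$intensity$values, na.rm = TRUE)
  )
}

#' @export
autoplot.graze_allocation <- function(object, ...) {
  autoplot(object$intensity) +
    ggplot2::labs(fill = "off-take\n(fraction of\npixel energy)")
}
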