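#' Read and write settlement points as GeoJSON
#'
#' Settlements travel as a GeoJSON FeatureCollection of Point features in a
#' projected metric CRS, with `settlement_id`, `population` and
#' `district_id` as feature properties. CSV (via [utils::read.csv()]) is
#' equally supported everywhere a settlement table is consumed; GeoJSON is
#' provided for interoperability with GIS tools.
#'
#' @param path file path.
#' @param settlements tibble `settlement_id`, `x`, `y`, `population`,
#'   `district_id`.
#' @return `read_settlements_geojson()` returns the settlements tibble.
#' @export
write_settlements_geojson <- function(settlements, path) {
  features <- purrr::pmap(settlements, function(settlement_id, x, y,
                                                population, district_id,
                                                ...) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = list(settlement_id = settlement_id,
                           population = population,
                           district_id = district_id))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_settlements_geojson
#' @export
read_settlements_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  purrr::map_dfr(fc$features, function(f) {
    tibble::tibble(
      settlement_id = f$properties$settlement_id,
      x = f$geometry$coordinates[[1]],
      y = f$geometry$coordinates[[2]],
      population = f$properties$population,
      district_id = f$properties$district_id)
  })
}

#' Write a synthetic bundle to disk in the pipeline's file formats
#'
#' Rasters as ESRI ASCII grids, tables as CSV, settlements as GeoJSON, and
#' the run configuration as YAML — exactly the formats the pipeline readers
#' and the command-line interface consume.
#'
#' @param bundle a [generate_landscape()] bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_raster_asc(bundle$npp, p("npp.asc"))
  write_raster_asc(bundle$cover, p("cover.asc"))
  write_raster_asc(bundle$districts, p("districts.asc"))
  write_settlements_geojson(bundle$settlements, p("settlements.geojson"))
  utils::write.csv(bundle$district_table, p("districts.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$livestock, p("livestock.csv"), row.names = FALSE)
  utils::write.csv(bundle$census, p("census.csv"), row.names = FALSE)
  utils::write.csv(bundle$nutritive, p("nutritive.csv"), row.names = FALSE)
  utils::write.csv(bundle$fodder, p("fodder.csv"), row.names = FALSE)
  utils::write.csv(bundle$fodder_tables$conversion, p("fodder_conversion.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$fodder_tables$shares, p("fodder_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$production, p("production.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(supply_params = unclass(supply_params()),
         per_head = bundle$per_head,
         calibration = list(rate_grid = seq(0.10, 0.60, by = 0.05),
                            distance_threshold_km = 10,
                            default_rate = 0.10),
         scenario = list(radius_km = c(10, 20), max_rate = 0.30,
                         dairy_fractions = list(AE = 0.40, PF = 0.50,
                                                HH = 0.85))),
    p("config.yaml"))
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory holding the pipeline input files.
#' @return a `graze_bundle`-like list (without the generator config).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- yaml::read_yaml(p("config.yaml"))
  structure(
    list(
      npp = read_raster_asc(p("npp.asc")),
      cover = read_raster_asc(p("cover.asc")),
      districts = read_raster_asc(p("districts.asc")),
      settlements = read_settlements_geojson(p("settlements.geojson")),
      district_table = tibble::as_tibble(utils::read.csv(p("districts.csv"))),
      livestock = tibble::as_tibble(utils::read.csv(p("livestock.csv"))),
      census = tibble::as_tibble(utils::read.csv(p("census.csv"))),
      nutritive = tibble::as_tibble(utils::read.csv(p("nutritive.csv"))),
      fodder = tibble::as_tibble(utils::read.csv(p("fodder.csv"))),
      fodder_tables = list(
        conversion = tibble::as_tibble(utils::read.csv(p("fodder_conversion.csv"))),
        shares = tibble::as_tibble(utils::read.csv(p("fodder_shares.csv")))),
      production = tibble::as_tibble(utils::read.csv(p("production.csv"))),
      per_head = cfg$per_head,
      run_config = cfg),
    class = "graze_bundle")
}

#' Run the full modelling pipeline on an input bundle
#'
#' Supply map, demand ledger, settlement demand, eleven-rate off-take
#' calibration, calibrated allocation and both expansion scenarios, in
#' order. This is the programmatic equivalent of the command-line
#' `run-all`.
#'
#' @param bundle a [generate_landscape()] or [read_bundle()] bundle.
#' @param params a [supply_params()].
#' @param calib a [calibration_config()].
#' @param scenario_radii radii (km) to evaluate expansion scenarios at.
#' @param out_dir optional directory; when given, all result artifacts and a
#'   JSON run manifest are written there.
#' @param quiet suppress progress messages.
#' @return list with `supply`, `ledger`, `demand`, `assignment`, `result`
#'   (the calibrated allocation), `productivity`, `scenarios` and
#'   `partition`.
#' @export
run_pipeline <- function(bundle, params = supply_params(),
                         calib = calibration_config(),
                         scenario_radii = c(10, 20), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("Building supply raster ...")
  supply <- build_supply(bundle$npp, bundle$cover, params)

  say("Computing demand ledger ...")
  ages <- disaggregate_herd_ages(bundle$livestock, bundle$census)
  total <- herd_energy_demand(ages, bundle$nutritive)
  fodder <- allocate_fodder(bundle$fodder, bundle$fodder_tables)
  ledger <- build_demand_ledger(total, fodder)
  n_clamped <- sum(ledger$fodder_mj > ledger$total_demand_mj)
  if (n_clamped > 0) {
    say("Fodder exceeded demand for %d district-species-farm cells (clamped).",
        n_clamped)
  }
  demand <- settlement_demand(ledger, bundle$settlements)

  say("Calibrating off-take rates (%d uniform runs) ...",
      length(calib$rate_grid))
  assignment <- calibrate_offtake(supply, demand, bundle$settlements, calib)

  say("Final allocation at calibrated rates ...")
  result <- run_calibrated(supply, demand, bundle$settlements, assignment,
                           quiet = quiet)

  say("Scenario analysis ...")
  ua <- utilized_area(result)
  grazed <- ua |> dplyr::filter(.data$area_km2 > 0) |>
    dplyr::select("species", "farm_type")
  prod_grazed <- dplyr::semi_join(bundle$production, grazed,
                                  by = c("species", "farm_type"))
  if (nrow(prod_grazed) < nrow(bundle$production)) {
    say("Dropping %d production group(s) with no grazing footprint from the productivity table.",
        nrow(bundle$production) - nrow(prod_grazed))
  }
  productivity <- productivity_table(prod_grazed, ua)
  scenarios <- purrr::map_dfr(scenario_radii, function(r) {
    expansion_potential(result, supply, bundle$settlements, bundle$districts,
                        assignment, bundle$production, demand,
                        per_head = bundle$per_head,
                        config = scenario_config(radius_km = r))
  })
  partition <- landscape_partition(result, supply, bundle$settlements)

  out <- list(supply = supply, ledger = ledger, demand = demand,
              assignment = assignment, result = result,
              productivity = productivity, scenarios = scenarios,
              partition = partition)
  if (!is.null(out_dir)) write_results(out, bundle, out_dir)
  out
}

write_results <- function(out, bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_raster_asc(out$result$claim, p("claims.asc"))
  write_raster_asc(out$result$group, p("groups.asc"))
  write_raster_asc(out$result$intensity, p("intensity.asc"))
  utils::write.csv(out$ledger, p("demand_ledger.csv"), row.names = FALSE)
  utils::write.csv(out$demand, p("settlement_demand.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(out$assignment), p("offtake_assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(out$result), p("allocation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(out$productivity, p("productivity.csv"), row.names = FALSE)
  utils::write.csv(out$scenarios, p("scenarios.csv"), row.names = FALSE)
  utils::write.csv(out$partition, p("partition.csv"), row.names = FALSE)
  artifacts <- list.files(dir, full.names = TRUE)
  manifest <- list(
    package = "grazemap",
    version = as.character(utils::packageVersion("grazemap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (inherits(bundle$config, "synth_config")) bundle$config$seed
           else NULL,
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(artifacts))), basename(artifacts)),
    totals = as.list(ledger_totals(out$ledger)),
    glance = as.list(glance(out$result)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
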