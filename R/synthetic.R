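#' Configuration for the synthetic landscape generator
#'
#' The generator produces a fully self-contained input bundle with the broad
#' statistical structure the model assumes: a northeast-to-southwest
#' productivity gradient with multiplicative lognormal noise, a
#' grassland/bare/cropland/excluded cover mosaic with spatially blocked
#' cropland, a rectangular district partition grouped into provinces,
#' clustered settlements with heavy-tailed (lognormal) populations, district
#' livestock statistics proportional to population, province-level herd
#' compositions, nutritive-requirement and fodder tables. All numbers are
#' driven by one seed through per-component sub-streams, so regenerating
#' with the same seed is bit-identical.
#'
#' Default sizes (400 x 400 cells of 500 m, 12 districts, 150 settlements)
#' give a country of about 40,000 km2 that runs the full pipeline in
#' minutes. The stock and feeding defaults are stylised from steppe
#' rangeland systems: roughly 0.36 cattle, 1.05 sheep+goats and 0.12 horses
#' per resident, 60/25/15% held in households/private farms/enterprises, and
#' fodder covering about 22% of total herd energy demand (a grazing gap near
#' 78%).
#'
#' @param seed integer master seed.
#' @param n_rows,n_cols,cell_size grid geometry (cells, metres).
#' @param npp_range NPP (gC/m2/yr) at the northeast and southwest corners.
#' @param noise_sd lognormal sigma of multiplicative NPP noise.
#' @param cover_fractions named fractions over grassland, bare, cropland and
#'   excluded cover; must sum to 1.
#' @param crop_block edge (cells) of the square blocks cropland is placed in.
#' @param n_district_rows,n_district_cols rectangular district partition.
#' @param n_provinces provinces the districts are grouped into.
#' @param n_settlements number of settlements.
#' @param cluster_frac fraction of settlements placed around cluster parents
#'   (the rest are uniform).
#' @param n_cluster_parents,cluster_sd_km clustering parameters.
#' @param pop_meanlog,pop_sdlog lognormal settlement-population law.
#' @param livestock_per_capita head per resident by species.
#' @param farm_type_shares share of each species held per farm type.
#' @param fodder_fraction fodder energy as a share of total herd demand.
#' @param fodder_jitter_sd lognormal sigma of district fodder jitter.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_rows = 400L, n_cols = 400L, cell_size = 500,
                         npp_range = c(ne = 250, sw = 60),
                         noise_sd = 0.25,
                         cover_fractions = c(grassland = 0.72, bare = 0.10,
                                             cropland = 0.12,
                                             excluded = 0.06),
                         crop_block = 8L,
                         n_district_rows = 3L, n_district_cols = 4L,
                         n_provinces = 4L,
                         n_settlements = 150L,
                         cluster_frac = 0.5, n_cluster_parents = 12L,
                         cluster_sd_km = 8,
                         pop_meanlog = log(1000), pop_sdlog = 1.2,
                         livestock_per_capita = c(cattle = 0.36,
                                                  sheep_goats = 1.05,
                                                  horses = 0.12),
                         farm_type_shares = c(HH = 0.60, PF = 0.25,
                                              AE = 0.15),
                         fodder_fraction = 0.22,
                         fodder_jitter_sd = 0.3) {
  if (abs(sum(cover_fractions) - 1) > 1e-9) {
    rlang::abort("`cover_fractions` must sum to 1.",
                 class = "grazemap_error_config")
  }
  structure(as.list(environment()), class = "synth_config")
}

sub_seed <- function(config, k) {
  (as.integer(config$seed) * 97L + k * 1013L) %% 2000000011L
}

#' Default nutritive-requirement table (synthetic)
#'
#' Plausible annual metabolisable-energy requirements (MJ/head/yr) by
#' species, age/function group and farm type. These are synthetic stand-ins
#' for a national feeding handbook: adult females and males of cattle,
#' sheep+goats and horses with lighter requirements for young stock, and a
#' farm-type multiplier reflecting the higher growth rates targeted on
#' private farms and especially agricultural enterprises. Real applications
#' should supply the handbook values as data.
#'
#' @return tibble `species`, `age_group`, `farm_type`, `mj_per_head`.
#' @export
synthetic_nutritive_table <- function() {
  base <- tibble::tribble(
    ~species, ~age_group, ~mj,
    "cattle", "adult_female", 26000,
    "cattle", "adult_male", 30000,
    "cattle", "young", 16000,
    "sheep_goats", "adult_female", 4200,
    "sheep_goats", "adult_male", 4800,
    "sheep_goats", "young", 2800,
    "horses", "adult_female", 30000,
    "horses", "adult_male", 33000,
    "horses", "young", 20000
  )
  mult <- c(HH = 1.0, PF = 1.05, AE = 1.15)
  tidyr::expand_grid(base, farm_type = names(mult)) |>
    dplyr::mutate(mj_per_head = .data$mj * mult[.data$farm_type]) |>
    dplyr::select("species", "age_group", "farm_type", "mj_per_head")
}

synthetic_fodder_tables <- function(provinces) {
  list(
    conversion = tibble::tibble(
      fodder_type = c("hay", "silage", "concentrate"),
      mj_per_kg = c(5.2, 2.3, 10.5)),
    shares = tidyr::expand_grid(
      province_id = provinces,
      tibble::tibble(species = c("cattle", "sheep_goats", "horses", "pigs",
                                 "poultry"),
                     share = c(0.55, 0.12, 0.08, 0.15, 0.10)))
  )
}

#' Generate a complete synthetic model input bundle
#'
#' See [synth_config()] for what is emulated. The bundle contains every
#' input the pipeline needs: `npp` and `cover` rasters, a `districts` raster
#' plus `district_table`, `settlements`, district `livestock` counts,
#' province `census` compositions, `nutritive` requirements, `fodder`
#' production with `fodder_tables`, baseline `production` statistics and a
#' `per_head` conversion list for the expansion scenarios.
#'
#' @param config a [synth_config()].
#' @return list of class `graze_bundle`.
#' @export
generate_landscape <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size

  # --- NPP: NE-SW gradient x lognormal noise -------------------------------
  set.seed(sub_seed(config, 1L))
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  # t = 0 at the NE corner (row 1, col nc), 1 at the SW corner
  t_ne <- ((nc - col) + (row - 1)) / (nr + nc - 2)
  grad <- config$npp_range[["ne"]] +
    t_ne * (config$npp_range[["sw"]] - config$npp_range[["ne"]])
  sd <- config$noise_sd
  noise <- if (sd > 0) {
    matrix(stats::rlnorm(nr * nc, meanlog = -sd^2 / 2, sdlog = sd), nr, nc)
  } else matrix(1, nr, nc)
  npp <- graze_raster(pmax(grad * noise, 0), cs)

  # --- cover: blocked cropland, iid mosaic elsewhere -----------------------
  set.seed(sub_seed(config, 2L))
  cc <- cover_classes()
  b <- config$crop_block
  nbr <- ceiling(nr / b); nbc <- ceiling(nc / b)
  n_blocks <- nbr * nbc
  n_crop <- round(config$cover_fractions[["cropland"]] * n_blocks)
  crop_blocks <- sample.int(n_blocks, n_crop)
  block_id <- (ceiling(row / b) - 1L) * nbc + ceiling(col / b)
  is_crop <- matrix(block_id %in% crop_blocks, nr, nc)
  other <- config$cover_fractions[c("grassland", "bare", "excluded")]
  other <- other / sum(other)
  n_other <- sum(!is_crop)
  draw <- sample(c("grassland", "bare", "excluded"), n_other, replace = TRUE,
                 prob = other)
  excl_codes <- c(cc[["forest"]], cc[["water"]], cc[["artificial"]],
                  cc[["preserve"]])
  codes <- ifelse(draw == "grassland", cc[["grassland"]],
                  ifelse(draw == "bare", cc[["bare"]],
                         sample(excl_codes, n_other, replace = TRUE)))
  cover_m <- matrix(NA_real_, nr, nc)
  cover_m[is_crop] <- cc[["cropland"]]
  cover_m[!is_crop] <- codes
  cover <- graze_raster(cover_m, cs)

  # --- districts and provinces ---------------------------------------------
  dr <- pmin(ceiling(row / (nr / config$n_district_rows)),
             config$n_district_rows)
  dc <- pmin(ceiling(col / (nc / config$n_district_cols)),
             config$n_district_cols)
  district_m <- (dr - 1) * config$n_district_cols + dc
  districts <- graze_raster(district_m, cs)
  n_districts <- config$n_district_rows * config$n_district_cols
  province_of <- ceiling(seq_len(n_districts) /
                           (n_districts / config$n_provinces))
  district_table <- tibble::tibble(
    district_id = seq_len(n_districts),
    province_id = pmin(province_of, config$n_provinces))

  # --- settlements ----------------------------------------------------------
  set.seed(sub_seed(config, 3L))
  n <- config$n_settlements
  n_clu <- round(config$cluster_frac * n)
  width <- nc * cs; height <- nr * cs
  px <- stats::runif(config$n_cluster_parents, 0, width)
  py <- stats::runif(config$n_cluster_parents, 0, height)
  parent <- sample.int(config$n_cluster_parents, n_clu, replace = TRUE)
  sx <- c(stats::runif(n - n_clu, 0, width),
          px[parent] + stats::rnorm(n_clu, 0, config$cluster_sd_km * 1000))
  sy <- c(stats::runif(n - n_clu, 0, height),
          py[parent] + stats::rnorm(n_clu, 0, config$cluster_sd_km * 1000))
  sx <- pmin(pmax(sx, cs / 2), width - cs / 2)
  sy <- pmin(pmax(sy, cs / 2), height - cs / 2)
  pop <- pmax(round(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog)), 5)
  # district of the containing pixel
  si <- pmin(pmax(ceiling((height - sy) / cs), 1L), nr)
  sj <- pmin(pmax(ceiling(sx / cs), 1L), nc)
  sdist <- district_m[cbind(si, sj)]
  settlements <- tibble::tibble(
    settlement_id = seq_len(n), x = sx, y = sy, population = as.numeric(pop),
    district_id = as.integer(sdist))

  # --- livestock statistics -------------------------------------------------
  set.seed(sub_seed(config, 4L))
  dpop <- settlements |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  livestock <- tidyr::expand_grid(
    district_id = district_table$district_id,
    species = names(config$livestock_per_capita),
    farm_type = names(config$farm_type_shares)) |>
    dplyr::left_join(district_table, by = "district_id") |>
    dplyr::left_join(dpop, by = "district_id") |>
    dplyr::mutate(
      population = dplyr::coalesce(.data$population, 0),
      head = round(.data$population *
                     unname(config$livestock_per_capita[.data$species]) *
                     unname(config$farm_type_shares[.data$farm_type]) *
                     stats::rlnorm(dplyr::n(), -0.02, 0.2))) |>
    dplyr::select("district_id", "province_id", "species", "farm_type",
                  "head")

  usable_any <- any(cover_m %in% c(cc[["grassland"]], cc[["bare"]],
                                   cc[["cropland"]]))
  if (!usable_any && sum(livestock$head) > 0) {
    rlang::abort("Infeasible configuration: livestock present but no grazeable pixels.",
                 class = "grazemap_error_validation")
  }

  # --- census herd composition (province level) ----------------------------
  set.seed(sub_seed(config, 5L))
  base_prop <- list(
    cattle = c(adult_female = 0.50, adult_male = 0.10, young = 0.40),
    sheep_goats = c(adult_female = 0.55, adult_male = 0.10, young = 0.35),
    horses = c(adult_female = 0.45, adult_male = 0.15, young = 0.40))
  census <- purrr::map_dfr(district_table$province_id |> unique(), function(p) {
    purrr::map_dfr(names(base_prop), function(sp) {
      w <- base_prop[[sp]] * stats::rlnorm(3, 0, 0.15)
      w <- w / sum(w)
      tibble::tibble(province_id = p, species = sp,
                     age_group = names(w),
                     head = round(w * 100000))
    })
  })

  nutritive <- synthetic_nutritive_table()
  fodder_tables <- synthetic_fodder_tables(unique(district_table$province_id))

  # --- fodder production sized to the target fodder fraction ---------------
  set.seed(sub_seed(config, 6L))
  demand <- herd_energy_demand(disaggregate_herd_ages(livestock, census),
                               nutritive)
  ddem <- demand |>
    dplyr::group_by(.data$district_id, .data$province_id) |>
    dplyr::summarise(total = sum(.data$total_demand_mj), .groups = "drop")
  ftw <- demand |>
    dplyr::group_by(.data$district_id, .data$farm_type) |>
    dplyr::summarise(d = sum(.data$total_demand_mj), .groups = "drop") |>
    dplyr::mutate(w = .data$d * c(HH = 0.8, PF = 1.0, AE = 1.8)[.data$farm_type]) |>
    dplyr::group_by(.data$district_id) |>
    dplyr::mutate(w = ifelse(sum(.data$w) > 0, .data$w / sum(.data$w), 0)) |>
    dplyr::ungroup()
  share_grazers <- fodder_tables$shares |>
    dplyr::filter(.data$species %in% GRAZING_SPECIES) |>
    dplyr::pull(.data$share) |> unique() |> sum()
  mix <- c(hay = 0.7, silage = 0.2, concentrate = 0.1)
  conv <- stats::setNames(fodder_tables$conversion$mj_per_kg,
                          fodder_tables$conversion$fodder_type)
  fodder <- ddem |>
    dplyr::left_join(ftw, by = "district_id") |>
    tidyr::expand_grid(fodder_type = names(mix)) |>
    dplyr::mutate(
      target_mj = config$fodder_fraction * .data$total * .data$w *
        unname(mix[.data$fodder_type]) *
        stats::rlnorm(dplyr::n(), 0, config$fodder_jitter_sd),
      kg = .data$target_mj / unname(conv[.data$fodder_type]) /
        share_grazers) |>
    dplyr::select("district_id", "province_id", "farm_type", "fodder_type",
                  "kg")

  # --- baseline production statistics for the scenario module --------------
  meat_per_head <- c(cattle = 67, sheep_goats = 9, horses = 48)    # kg/head/yr
  milk_per_head <- c(cattle = 820, sheep_goats = 0.1, horses = 12)
  ft_prod <- c(HH = 1.0, PF = 0.9, AE = 1.3)
  production <- livestock |>
    dplyr::group_by(.data$species, .data$farm_type) |>
    dplyr::summarise(head = sum(.data$head), .groups = "drop") |>
    dplyr::mutate(
      meat_t = .data$head * meat_per_head[.data$species] *
        ft_prod[.data$farm_type] / 1000,
      milk_t = .data$head * milk_per_head[.data$species] / 1000) |>
    dplyr::select("species", "farm_type", "meat_t", "milk_t")

  per_head <- list(mj_per_head = 26000 * 1.15, beef_kg_per_head = 90,
                   milk_kg_per_head = 2000)

  structure(
    list(npp = npp, cover = cover, districts = districts,
         district_table = district_table, settlements = settlements,
         livestock = livestock, census = census, nutritive = nutritive,
         fodder = fodder, fodder_tables = fodder_tables,
         production = production, per_head = per_head, config = config),
    class = "graze_bundle")
}

#' @export
print.graze_bundle <- function(x, ...) {
  cat("<graze_bundle>\n")
  cat(sprintf("  grid %d x %d @ %g m; %d districts, %d settlements\n",
              x$config$n_rows, x$config$n_cols, x$config$cell_size,
              nrow(x$district_table), nrow(x$settlements)))
  cat(sprintf("  livestock: %s head\n",
              format(sum(x$livestock$head), big.mark = ",")))
  invisible(x)
}

#' Build a calibration parameter-recovery fixture
#'
#' Constructs a single-district landscape whose household-cattle demand is
#' scaled (by bisection, verified by actually running the relevant uniform
#' sweeps) so that at `target_rate` the district median maximum grazing
#' distance is just under the 10 km criterion while at the next-lower grid
#' rate it is not. Calibration run on the fixture should therefore return
#' `target_rate`.
#'
#' @param target_rate a rate from the calibration grid.
#' @param config a [synth_config()]; districts are forced to one.
#' @param calib a [calibration_config()].
#' @param max_iter bisection iterations before giving up.
#' @return list with `bundle`, `supply`, `demand` (settlement-level,
#'   household cattle only), `scale` and `target_rate`.
#' @export
make_recovery_fixture <- function(target_rate,
                                  config = synth_config(
                                    n_rows = 120L, n_cols = 120L,
                                    n_settlements = 25L,
                                    n_district_rows = 1L,
                                    n_district_cols = 1L, n_provinces = 1L),
                                  calib = calibration_config(),
                                  max_iter = 40L) {
  grid <- calib$rate_grid
  ti <- match(TRUE, abs(grid - target_rate) < 1e-9)
  if (is.na(ti)) {
    rlang::abort("`target_rate` must be on the calibration rate grid.",
                 class = "grazemap_error_config")
  }
  config$n_district_rows <- 1L; config$n_district_cols <- 1L
  config$n_provinces <- 1L
  bundle <- generate_landscape(config)
  supply <- build_supply(bundle$npp, bundle$cover)
  sett <- bundle$settlements
  w <- sett$population * owner_fraction(sett$population)
  base_total <- 0.02 * total_supply(supply)
  base <- tibble::tibble(
    settlement_id = sett$settlement_id, district_id = sett$district_id,
    species = calib$reference_species, farm_type = calib$reference_farm_type,
    grazing_demand_mj = base_total * w / sum(w))
  spec <- group_specs() |>
    dplyr::filter(.data$species == calib$reference_species,
                  .data$farm_type == calib$reference_farm_type)

  med_at <- function(scale, rate) {
    d <- base |> dplyr::mutate(grazing_demand_mj = .data$grazing_demand_mj * scale)
    run <- allocate_group(supply, d, sett, rate, spec, quiet = TRUE)
    stats::median(run$summary$max_distance_km[run$summary$demand_mj > 0])
  }
  assigned <- function(scale) {
    for (i in seq_along(grid)) {
      if (med_at(scale, grid[i]) < calib$distance_threshold_km) return(i)
    }
    length(grid)
  }

  if (ti == 1L) {
    s <- 1
    for (it in seq_len(max_iter)) {
      if (assigned(s) == 1L) break
      s <- s / 2
    }
    if (assigned(s) != 1L) {
      rlang::abort("Could not scale demand down to the minimum grid rate.",
                   class = "grazemap_error_fixture")
    }
    return(list(bundle = bundle, supply = supply,
                demand = base |>
                  dplyr::mutate(grazing_demand_mj = .data$grazing_demand_mj * s),
                scale = s, target_rate = target_rate))
  }

  # exponential search for a bracket, then bisection on the demand scale
  s_lo <- NULL; s_hi <- NULL; s <- 1
  for (it in seq_len(max_iter)) {
    a <- assigned(s)
    if (a < ti) { s_lo <- s; s <- s * 2 } else { s_hi <- s; s <- s / 2 }
    if (!is.null(s_lo) && !is.null(s_hi)) break
  }
  if (is.null(s_lo) || is.null(s_hi)) {
    rlang::abort("Demand scaling failed to bracket the target rate.",
                 class = "grazemap_error_fixture")
  }
  lo <- min(s_lo, s_hi); hi <- max(s_lo, s_hi)
  s_star <- NULL
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    a <- assigned(mid)
    if (a == ti) { s_star <- mid; break }
    if (a < ti) lo <- mid else hi <- mid
  }
  if (is.null(s_star)) {
    rlang::abort("Demand scaling failed to bracket the target rate (grid rate skipped).",
                 class = "grazemap_error_fixture")
  }
  list(bundle = bundle, supply = supply,
       demand = base |>
         dplyr::mutate(grazing_demand_mj = .data$grazing_demand_mj * s_star),
       scale = s_star, target_rate = target_rate)
}
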