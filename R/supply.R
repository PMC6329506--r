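#' Energy-conversion parameters for the grazing supply map
#'
#' Coefficients that turn net primary productivity (gC/m\eqn{^2}/yr) into
#' annually grazeable metabolisable energy (MJ/m\eqn{^2}):
#'
#' * `carbon_to_dm` — grams carbon per gram dry matter (default 0.47), so
#'   dry-matter production is NPP / 0.47.
#' * `grass_energy` — energy content of rangeland herbage, MJ per kg dry
#'   matter (default 8.6).
#' * `residue_energy` — energy content of post-harvest crop residues, MJ per
#'   kg dry matter (default 6.0, wheat as reference crop).
#' * `harvest_index` — grain mass over total aboveground crop biomass
#'   (default 0.48), so residues are the (1 - HI) remainder.
#' * `crop_aboveground_frac` — share of total wheat biomass that is
#'   aboveground at harvest (default 0.90).
#' * `grass_aboveground_npp_frac` — aboveground share of total grassland NPP
#'   (default 0.77).
#' * `max_aboveground_offtake` — maximum sustainable consumption as a share
#'   of aboveground NPP (default 0.40); together with the previous value this
#'   yields the ~30% maximum sustainable off-take of *total* NPP.
#'
#' @param carbon_to_dm,grass_energy,residue_energy,harvest_index,crop_aboveground_frac,grass_aboveground_npp_frac,max_aboveground_offtake
#'   see Details.
#' @return a named list of class `supply_params`.
#' @export
supply_params <- function(carbon_to_dm = 0.47,
                          grass_energy = 8.6,
                          residue_energy = 6.0,
                          harvest_index = 0.48,
                          crop_aboveground_frac = 0.90,
                          grass_aboveground_npp_frac = 0.77,
                          max_aboveground_offtake = 0.40) {
  p <- list(carbon_to_dm = carbon_to_dm, grass_energy = grass_energy,
            residue_energy = residue_energy, harvest_index = harvest_index,
            crop_aboveground_frac = crop_aboveground_frac,
            grass_aboveground_npp_frac = grass_aboveground_npp_frac,
            max_aboveground_offtake = max_aboveground_offtake)
  frac <- c("carbon_to_dm", "harvest_index", "crop_aboveground_frac",
            "grass_aboveground_npp_frac", "max_aboveground_offtake")
  for (nm in frac) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1) {
      rlang::abort(sprintf("`%s` must lie in (0, 1].", nm),
                   class = "grazemap_error_validation")
    }
  }
  for (nm in c("grass_energy", "residue_energy")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      rlang::abort(sprintf("`%s` must be a positive energy content (MJ/kgDM).", nm),
                   class = "grazemap_error_validation")
    }
  }
  structure(p, class = c("supply_params", "list"))
}

#' Maximum sustainable off-take rate implied by supply parameters
#'
#' Fraction of *total* NPP that can be consumed sustainably:
#' `max_aboveground_offtake * grass_aboveground_npp_frac` (0.308 with the
#' defaults, conventionally rounded to 30%).
#'
#' @param params a [supply_params()] object.
#' @export
max_sustainable_offtake <- function(params = supply_params()) {
  params$max_aboveground_offtake * params$grass_aboveground_npp_frac
}

#' Build the annual grazing-energy supply raster
#'
#' Converts an NPP composite and a categorical land-cover raster into the
#' per-pixel annually grazeable energy density (MJ/m\eqn{^2}):
#'
#' * grassland and bare-soil pixels: `npp / carbon_to_dm / 1000 * grass_energy`
#'   (bare soils are treated as low-NPP grassland since grazing occurs there);
#' * cropland pixels carry only post-harvest residues:
#'   `npp / carbon_to_dm / 1000 * crop_aboveground_frac * (1 - harvest_index)
#'   * residue_energy`;
#' * forest, water, ice, artificial surfaces and strictly protected preserves
#'   are excluded with zero energy.
#'
#' Missing NPP on grazeable cover is treated as zero energy with a warning
#' (map edges stay usable); negative NPP is an error.
#'
#' @param npp `graze_raster` of annual total NPP in gC/m\eqn{^2}/yr.
#' @param cover `graze_raster` of [cover_classes()] codes on the same grid.
#' @param params a [supply_params()] object.
#' @return an object of class `graze_supply`: list with `energy`
#'   (MJ/m\eqn{^2} `graze_raster`), `usable` (`graze_raster`; 0 excluded,
#'   1 grassland, 2 cropland) and `params`.
#' @export
build_supply <- function(npp, cover, params = supply_params()) {
  stopifnot(inherits(npp, "graze_raster"), inherits(cover, "graze_raster"))
  check_same_grid(npp, cover, "NPP and cover rasters")
  v <- npp$values
  if (any(v < 0, na.rm = TRUE)) {
    rlang::abort("NPP raster contains negative values.",
                 class = "grazemap_error_validation")
  }
  cls <- cover$values
  cc <- cover_classes()
  grass <- cls %in% c(cc[["grassland"]], cc[["bare"]])
  crop <- cls == cc[["cropland"]]
  usable <- matrix(0, nrow(cls), ncol(cls))
  usable[grass] <- 1
  usable[crop] <- 2

  n_missing <- sum(is.na(v) & usable > 0)
  if (n_missing > 0) {
    rlang::warn(sprintf(
      "%d grazeable pixel(s) have missing NPP; treated as zero energy.",
      n_missing))
    v[is.na(v)] <- 0
  }

  dm_kg <- v / params$carbon_to_dm / 1000      # kg dry matter per m^2
  energy <- matrix(0, nrow(v), ncol(v))
  energy[grass] <- dm_kg[grass] * params$grass_energy
  energy[crop] <- dm_kg[crop] * params$crop_aboveground_frac *
    (1 - params$harvest_index) * params$residue_energy

  structure(
    list(
      energy = graze_raster(energy, npp$cell_size, npp$xll, npp$yll,
                            npp$crs_label),
      usable = graze_raster(usable, npp$cell_size, npp$xll, npp$yll,
                            npp$crs_label),
      params = params
    ),
    class = "graze_supply"
  )
}

#' @export
print.graze_supply <- function(x, ...) {
  u <- x$usable$values
  a <- cell_area(x$energy) / 1e6
  cat("<graze_supply>\n")
  cat(sprintf("  grassland: %.0f km2, cropland: %.0f km2, excluded: %.0f km2\n",
              sum(u == 1) * a, sum(u == 2) * a, sum(u == 0) * a))
  cat(sprintf("  total grazeable energy: %.4g PJ\n",
              total_supply(x) / 1e9))
  invisible(x)
}

#' Total grazeable energy of a supply raster
#'
#' Sums energy density times cell area over all non-excluded pixels,
#' optionally restricted to one usable class.
#'
#' @param supply a `graze_supply` object.
#' @param class_filter `NULL` (all), `"grassland"` or `"cropland"`.
#' @return total energy in MJ.
#' @export
total_supply <- function(supply, class_filter = NULL) {
  stopifnot(inherits(supply, "graze_supply"))
  u <- supply$usable$values
  keep <- u > 0
  if (!is.null(class_filter)) {
    code <- switch(class_filter, grassland = 1, cropland = 2,
                   rlang::abort("`class_filter` must be 'grassland' or 'cropland'.",
                                class = "grazemap_error_validation"))
    keep <- u == code
  }
  sum(supply$energy$values[keep]) * cell_area(supply$energy)
}
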