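scenario_setup <- function(seed = 17) {
  b <- generate_landscape(synth_config(seed = seed, n_rows = 80L,
                                       n_cols = 80L, n_settlements = 12L,
                                       n_district_rows = 2L,
                                       n_district_cols = 2L,
                                       n_provinces = 1L))
  sup <- build_supply(b$npp, b$cover)
  ages <- disaggregate_herd_ages(b$livestock, b$census)
  led <- build_demand_ledger(herd_energy_demand(ages, b$nutritive),
                             allocate_fodder(b$fodder, b$fodder_tables))
  dem <- settlement_demand(led, b$settlements)
  asg <- calibrate_offtake(sup, dem, b$settlements)
  res <- run_calibrated(sup, dem, b$settlements, asg, quiet = TRUE)
  list(b = b, sup = sup, dem = dem, asg = asg, res = res)
}

test_that("productivity is production over allocated area, dairy-adjusted", {
  prod <- tibble::tibble(species = c("cattle", "cattle"),
                         farm_type = c("AE", "HH"),
                         meat_t = c(28440, 0), milk_t = c(100000, 0))
  area <- tibble::tibble(species = c("cattle", "cattle"),
                         farm_type = c("AE", "HH"),
                         area_km2 = c(296000, 1000))
  out <- productivity_table(prod, area, c(AE = 0.40, PF = 0.50, HH = 0.85))
  expect_equal(out$meat_t_per_km2[1], 28440 / 296000)
  # milk denominator is the dairy-adjusted area
  expect_equal(out$milk_t_per_km2[1], 100000 / (296000 * 0.40))
  expect_equal(out$meat_t_per_km2[2], 0)
  # zero area with production is an error
  area0 <- dplyr::mutate(area, area_km2 = c(0, 1000))
  expect_error(productivity_table(prod, area0, c(AE = 0.4, PF = .5, HH = .85)),
               class = "grazemap_error_validation")
})

test_that("expansion arithmetic on a fixture: BAU 8 MJ vs max-rate 12 MJ", {
  # 2x2 grid of 10 MJ pixels, nothing claimed, all within 10 km
  sup <- make_uniform_supply(2, 2, 10)
  sett <- one_settlement(500, 500)
  dem0 <- demand_row(1L, 0)
  res <- run_allocation(sup, dem0, sett, 0.2, quiet = TRUE)
  districts <- graze_raster(matrix(1, 2, 2), 500)
  asg <- tibble::tibble(district_id = 1L, rate = 0.20,
                        provenance = "reference", median_km = 0)
  attr(asg, "config") <- calibration_config(default_rate = 0.20)
  class(asg) <- c("graze_offtake", class(asg))
  prod <- tibble::tibble(species = "cattle", farm_type = "AE",
                         meat_t = 10, milk_t = 10)
  # give AE cattle a claims footprint so productivity_table has area
  dem_ae <- demand_row(1L, 1, "cattle", "AE")
  res1 <- run_allocation(sup, dem_ae, sett, 0.2, quiet = TRUE)
  out <- expansion_potential(res1, sup, sett, districts, asg, prod, dem_ae,
                             per_head = list(mj_per_head = 1,
                                             beef_kg_per_head = 1000,
                                             milk_kg_per_head = 1000),
                             config = scenario_config(radius_km = 10,
                                                      max_rate = 0.30))
  bau <- out[out$mode == "BAU", ]
  mx <- out[out$mode == "max", ]
  # 3 unclaimed pixels (one claimed by the baseline run) at 10 MJ
  expect_equal(bau$additional_energy_pj * 1e9, 3 * 10 * 0.20)
  expect_equal(mx$additional_energy_pj * 1e9, 3 * 10 * 0.30)
  # energy path: heads = energy / 1, 1000 kg each -> tonnes = energy
  expect_equal(bau$beef_t_energy_path, 6 / 1000 * 1000)
})

test_that("all-claimed landscapes have zero expansion potential", {
  sup <- make_uniform_supply(2, 2, 10)
  sett <- one_settlement(500, 500)
  dem <- demand_row(1L, 40, "cattle", "AE")
  res <- run_allocation(sup, dem, sett, 1.0, quiet = TRUE)
  districts <- graze_raster(matrix(1, 2, 2), 500)
  asg <- tibble::tibble(district_id = 1L, rate = 0.60,
                        provenance = "reference", median_km = 0)
  attr(asg, "config") <- calibration_config()
  class(asg) <- c("graze_offtake", class(asg))
  prod <- tibble::tibble(species = "cattle", farm_type = "AE",
                         meat_t = 5, milk_t = 5)
  out <- expansion_potential(res, sup, sett, districts, asg, prod, dem,
                             config = scenario_config(radius_km = 10,
                                                      max_rate = 1.0))
  expect_equal(out$additional_area_km2[out$mode == "BAU"], 0)
  expect_equal(out$additional_energy_pj[out$mode == "BAU"], 0)
})

test_that("percent increase is additional over baseline production", {
  # 130 kt additional on a 417 kt baseline is a 31% increase
  expect_equal(round(100 * 130 / 417), 31)
})

test_that("scenario invariants: radius monotonicity, max >= BAU, partition", {
  ss <- scenario_setup()
  out <- purrr::map_dfr(c(10, 20), function(r) {
    expansion_potential(ss$res, ss$sup, ss$b$settlements, ss$b$districts,
                        ss$asg, ss$b$production, ss$dem,
                        per_head = ss$b$per_head,
                        config = scenario_config(radius_km = r))
  })
  a10 <- out |> dplyr::filter(radius_km == 10)
  a20 <- out |> dplyr::filter(radius_km == 20)
  expect_true(all(a20$additional_area_km2 >= a10$additional_area_km2 - 1e-9))
  # district rates are all <= 0.30 here, so max-mode energy dominates BAU
  expect_true(all(ss$asg$rate <= 0.30 + 1e-9, na.rm = TRUE))
  for (r in list(a10, a20)) {
    expect_gte(r$additional_energy_pj[r$mode == "max"],
               r$additional_energy_pj[r$mode == "BAU"])
  }
  # the landscape partition is exhaustive and disjoint
  part <- landscape_partition(ss$res, ss$sup, ss$b$settlements, 10)
  expect_equal(sum(part$n_pixels), 80 * 80)
  # claimed + candidate pixel counts agree with the BAU accounting
  expect_equal(unname(part$n_pixels[part$category == "expansion_candidate"]) *
                 cell_area(ss$sup$energy) / 1e6,
               a10$additional_area_km2[a10$mode == "BAU"], tolerance = 1e-9)
})
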