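test_that("age disaggregation applies census proportions and conserves totals", {
  out <- disaggregate_herd_ages(toy_counts(), toy_census())
  # district 1 HH cattle, 1000 head; census A share 400/2000
  a <- out |> dplyr::filter(district_id == 1, farm_type == "HH",
                            age_group == "A")
  expect_equal(a$head, 200)
  sums <- out |>
    dplyr::group_by(district_id, species, farm_type) |>
    dplyr::summarise(head = sum(head), .groups = "drop") |>
    dplyr::arrange(district_id, farm_type)
  expect_equal(sums$head, c(1000, 500, 0), tolerance = 1e-12)
  # explicit proportion case: (0.2, 0.3, 0.5) on 100 head
  census <- tibble::tibble(province_id = 1L, species = "cattle",
                           age_group = c("A", "B", "C"),
                           head = c(20, 30, 50))
  counts <- tibble::tibble(district_id = 1L, province_id = 1L,
                           species = "cattle", farm_type = "HH", head = 100)
  out2 <- disaggregate_herd_ages(counts, census)
  expect_equal(sort(out2$head), c(20, 30, 50))
  expect_equal(sum(out2$head), 100)
})

test_that("zero census denominator with livestock present is an error", {
  counts <- tibble::tibble(district_id = 9L, province_id = 1L,
                           species = "horses", farm_type = "HH", head = 10)
  census <- tibble::tibble(province_id = 1L, species = "horses",
                           age_group = "A", head = 0)
  expect_error(disaggregate_herd_ages(counts, census),
               class = "grazemap_error_validation")
})

test_that("herd energy demand is count times requirement, additive and linear", {
  ages <- tibble::tibble(district_id = 1L, province_id = 1L,
                         species = "cattle", farm_type = "HH",
                         age_group = c("A", "B"), head = c(5, 0))
  nut <- tibble::tibble(species = "cattle", age_group = c("A", "B"),
                        farm_type = "HH", mj_per_head = c(20000, 9999))
  d <- herd_energy_demand(ages, nut)
  expect_equal(d$total_demand_mj, 100000)
  d2 <- herd_energy_demand(dplyr::mutate(ages, head = head * 2), nut)
  expect_equal(d2$total_demand_mj, 200000)
  # missing table entry for a present group
  expect_error(
    herd_energy_demand(dplyr::mutate(ages, head = 1),
                       nut[nut$age_group == "A", ]),
    class = "grazemap_error_config")
})

test_that("fodder allocation converts mass to energy and applies shares", {
  prod <- tibble::tibble(district_id = 1L, province_id = 1L,
                         farm_type = "HH", fodder_type = "hay", kg = 100000)
  tables <- list(
    conversion = tibble::tibble(fodder_type = "hay", mj_per_kg = 6),
    shares = tibble::tibble(province_id = 1L,
                            species = c("cattle", "pigs"),
                            share = c(0.60, 0.10)))
  out <- allocate_fodder(prod, tables)
  expect_equal(out$fodder_mj[out$species == "cattle"], 360000)
  # non-grazing species are dropped, and the share bound holds
  expect_false("pigs" %in% out$species)
  expect_lte(sum(out$fodder_mj), 100000 * 6)
  # zero shares -> zero energy
  tables0 <- tables
  tables0$shares$share <- 0
  expect_equal(sum(allocate_fodder(prod, tables0)$fodder_mj), 0)
  expect_error(allocate_fodder(
    dplyr::mutate(prod, fodder_type = "unobtainium"), tables),
    class = "grazemap_error_config")
})

test_that("ledger reproduces national identities and clamps surplus fodder", {
  # 368 PJ total demand and 82 PJ fodder leave 286 PJ grazing demand (gap 0.78)
  total <- tibble::tibble(district_id = 1L, province_id = 1L,
                          species = "cattle", farm_type = "HH",
                          total_demand_mj = 368e9)
  fodder <- dplyr::mutate(total, fodder_mj = 82e9,
                          total_demand_mj = NULL)
  led <- build_demand_ledger(total, fodder)
  expect_equal(led$grazing_demand_mj, 286e9)
  expect_equal(round(led$grazing_gap, 2), 0.78)
  expect_equal(ledger_totals(led)$grazing_demand_pj, 286)
  # fodder above demand clamps to zero grazing demand and zero gap
  led2 <- build_demand_ledger(total, dplyr::mutate(fodder, fodder_mj = 400e9))
  expect_equal(led2$grazing_demand_mj, 0)
  expect_equal(led2$grazing_gap, 0)
  expect_error(build_demand_ledger(dplyr::mutate(total,
                                                 total_demand_mj = -1)),
               class = "grazemap_error_validation")
})

test_that("grazing gap lies in [0,1] and falls as fodder rises", {
  total <- tibble::tibble(district_id = 1L, province_id = 1L,
                          species = "cattle", farm_type = "HH",
                          total_demand_mj = 1e6)
  gaps <- vapply(seq(0, 2e6, length.out = 11), function(f) {
    build_demand_ledger(total, dplyr::mutate(total, fodder_mj = f,
                                             total_demand_mj = NULL))$grazing_gap
  }, numeric(1))
  expect_true(all(gaps >= 0 & gaps <= 1))
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("owner fraction follows the piecewise-linear knots", {
  expect_equal(owner_fraction(c(0, 500, 1000)), rep(0.95, 3))
  expect_equal(owner_fraction(5000), 0.80)
  expect_equal(owner_fraction(10000), 0.30)
  expect_equal(owner_fraction(50000), 0.10)
  expect_equal(owner_fraction(1e6), 0.005)
  expect_equal(owner_fraction(5e6), 0.005)   # constant beyond the last knot
  expect_equal(owner_fraction(7500), 0.55)   # midpoint of 5k-10k segment
  expect_error(owner_fraction(-1), class = "grazemap_error_validation")
})

test_that("settlement demand splits by owner-weighted population and conserves", {
  led <- build_demand_ledger(
    tibble::tibble(district_id = 1L, province_id = 1L, species = "cattle",
                   farm_type = "HH", total_demand_mj = 3950))
  # single settlement receives everything
  s1 <- tibble::tibble(settlement_id = 1L, x = 0, y = 0, population = 1000,
                       district_id = 1L)
  expect_equal(settlement_demand(led, s1)$grazing_demand_mj, 3950)
  # weights 950 and 3000 from populations 1000 and 10000
  s2 <- tibble::tibble(settlement_id = 1:2, x = 0, y = 0,
                       population = c(1000, 10000), district_id = 1L)
  out <- settlement_demand(led, s2)
  expect_equal(out$grazing_demand_mj, 3950 * c(950, 3000) / 3950)
  expect_equal(sum(out$grazing_demand_mj), 3950, tolerance = 1e-12)
  # district with demand but no settlements errors
  expect_error(settlement_demand(led, dplyr::mutate(s2, district_id = 2L)),
               class = "grazemap_error_validation")
})

test_that("demand pipeline conserves mass end-to-end and scales linearly", {
  b <- generate_landscape(synth_config(seed = 11, n_rows = 60L, n_cols = 60L,
                                       n_settlements = 20L))
  ages <- disaggregate_herd_ages(b$livestock, b$census)
  # conservation province->district ages
  a_sum <- ages |>
    dplyr::group_by(district_id, species, farm_type) |>
    dplyr::summarise(head = sum(head), .groups = "drop") |>
    dplyr::arrange(district_id, species, farm_type)
  l_sum <- b$livestock |>
    dplyr::arrange(district_id, species, farm_type)
  expect_equal(a_sum$head, l_sum$head, tolerance = 1e-9)
  total <- herd_energy_demand(ages, b$nutritive)
  led <- build_demand_ledger(total, allocate_fodder(b$fodder, b$fodder_tables))
  sd <- settlement_demand(led, b$settlements)
  # conservation district->settlement
  back <- sd |>
    dplyr::group_by(district_id, species, farm_type) |>
    dplyr::summarise(mj = sum(grazing_demand_mj), .groups = "drop")
  ref <- led |>
    dplyr::filter(grazing_demand_mj > 0) |>
    dplyr::select(district_id, species, farm_type,
                  mj_ref = grazing_demand_mj)
  j <- dplyr::inner_join(back, ref, by = c("district_id", "species",
                                           "farm_type"))
  expect_equal(nrow(j), nrow(ref))
  expect_equal(j$mj, j$mj_ref, tolerance = 1e-9)
  # linearity in herd size
  total2 <- herd_energy_demand(dplyr::mutate(ages, head = 2 * head),
                               b$nutritive)
  expect_equal(total2$total_demand_mj, 2 * total$total_demand_mj,
               tolerance = 1e-12)
})
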