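test_that("group table encodes the mobility ordering and radii", {
  gs <- group_specs()
  expect_equal(nrow(gs), 9)
  expect_equal(gs$order, 1:9)
  expect_equal(gs$radius_km[gs$species == "horses"], rep(10, 3))
  expect_equal(gs$radius_km[gs$farm_type == "AE" & gs$species != "horses"],
               rep(5, 2))
  expect_equal(gs$radius_km[gs$farm_type %in% c("HH", "PF") &
                              gs$species != "horses"], rep(2, 4))
  # households first, enterprises later, horses last
  expect_true(all(which(gs$species == "horses") > 6))
  expect_equal(gs$farm_type[1:2], c("HH", "HH"))
})

test_that("zero demand claims nothing; greedy run consumes 5,5,2 on a uniform grid", {
  sup <- make_uniform_supply(5, 5, 10)
  sett <- one_settlement(1250, 1250)
  res0 <- run_allocation(sup, demand_row(1L, 0), sett, 0.5, quiet = TRUE)
  expect_equal(sum(!is.na(res0$claim$values)), 0)
  res <- run_allocation(sup, demand_row(1L, 12), sett, 0.5)
  taken <- res$consumed$values[!is.na(res$claim$values)]
  expect_equal(sort(taken, decreasing = TRUE), c(5, 5, 2))
  expect_equal(sum(taken), 12)
  s <- tidy(res) |> dplyr::filter(demand_mj > 0)
  expect_true(s$demand_met)
  expect_equal(s$n_pixels, 3L)
})

test_that("equidistant contested pixel goes to the smaller settlement id", {
  # single high-energy pixel centred between two settlements
  mj <- matrix(1, 3, 5); mj[2, 3] <- 50
  sup <- make_supply(mj / 250000, 500)
  sett <- tibble::tibble(settlement_id = 1:2,
                         x = c(750, 1750), y = 750,
                         population = 100, district_id = 1L)
  dem <- demand_row(1:2, c(25, 25))
  res <- run_allocation(sup, dem, sett, 1.0, quiet = TRUE)
  best <- which(t(res$claim$values) == 1 | t(res$claim$values) == 2)
  claim_of_peak <- res$claim$values[2, 3]
  expect_equal(claim_of_peak, 1)
  # swapping ids swaps the winner
  sett2 <- dplyr::mutate(sett, settlement_id = c(2L, 1L))
  res2 <- run_allocation(sup, dem, sett2, 1.0, quiet = TRUE)
  expect_equal(res2$claim$values[2, 3], 1)
})

test_that("later groups never claim pixels already claimed by earlier groups", {
  set.seed(5)
  sup <- make_supply(matrix(stats::runif(400, 0, 4e-5), 20, 20), 500)
  sett <- one_settlement(5000, 5000)
  dem <- dplyr::bind_rows(
    demand_row(1L, 4000, "sheep_goats", "HH"),
    demand_row(1L, 4000, "cattle", "HH"),
    demand_row(1L, 4000, "horses", "AE"))
  res <- run_allocation(sup, dem, sett, 0.4, quiet = TRUE)
  g <- res$group$values
  expect_true(all(table(g[!is.na(g)]) > 0))
  # claim mask injective: consumed recorded once per pixel, groups disjoint
  expect_equal(sum(!is.na(res$claim$values)), sum(tidy(res)$n_pixels))
})

test_that("conservation and the per-pixel intensity cap hold on random runs", {
  for (seed in 1:5) {
    inst <- random_instance(seed, nr = 8, nc = 8, ns = 3, ng = 3)
    res <- run_instance(inst)
    s <- tidy(res)
    met_all <- all(s$demand_met[s$demand_mj > 0])
    if (met_all) {
      expect_equal(sum(s$consumed_mj), sum(s$demand_mj), tolerance = 1e-9)
    }
    # per-pixel intensity <= the claiming settlement's rate
    cl <- t(res$claim$values); it <- t(res$intensity$values)
    claimed <- !is.na(cl)
    rates <- res$offtake$rate[match(cl[claimed], res$offtake$settlement_id)]
    expect_true(all(it[claimed] <= rates + 1e-12))
  }
})

test_that("engine matches the brute-force oracle pixel-for-pixel on small grids", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    res <- run_instance(inst)
    orc <- oracle_instance(inst)
    cl <- res$claim$values; cl[is.na(cl)] <- 0
    gr <- res$group$values; gr[is.na(gr)] <- 0
    expect_identical(unname(cl), unname(orc$claim * 1.0),
                     label = sprintf("claims, seed %d", seed))
    expect_identical(unname(gr), unname(orc$group * 1.0),
                     label = sprintf("groups, seed %d", seed))
    expect_equal(res$consumed$values, orc$consumed, tolerance = 1e-12)
    s <- tidy(res)
    expect_equal(matrix(s$max_distance_km,
                        nrow(inst$sett), nrow(inst$specs), byrow = TRUE),
                 orc$max_d_m / 1000, tolerance = 1e-12)
    expect_equal(matrix(s$demand_met, nrow(inst$sett), nrow(inst$specs),
                        byrow = TRUE),
                 orc$met)
  }
})

test_that("maximum grazing distance is the Euclidean reach of the claims", {
  # a single claimable pixel offset 3 km east, 4 km north of the settlement
  mj <- matrix(0, 20, 20)
  mj[4, 16] <- 100    # centre at (7750, 8250)
  sup <- make_supply(mj / 250000, 500)
  sett <- one_settlement(7750 - 3000, 8250 - 4000)
  res <- run_allocation(sup, demand_row(1L, 10), sett, 1, quiet = TRUE)
  expect_equal(max_grazing_distance(res, 1L, "cattle", "HH"), 5)
  # no claims -> 0
  res0 <- run_allocation(sup, demand_row(1L, 0), sett, 1, quiet = TRUE)
  expect_equal(max_grazing_distance(res0, 1L, "cattle", "HH"), 0)
})

test_that("exhausted landscapes warn and flag unmet demand", {
  sup <- make_uniform_supply(3, 3, 1)
  sett <- one_settlement(750, 750)
  expect_warning(
    res <- run_allocation(sup, demand_row(1L, 100), sett, 0.5),
    "exhausted")
  s <- tidy(res) |> dplyr::filter(demand_mj > 0)
  expect_false(s$demand_met)
  expect_equal(s$consumed_mj, 9 * 0.5, tolerance = 1e-12)
})

test_that("utilized area shrinks and max distance falls as the rate rises", {
  b <- generate_landscape(synth_config(seed = 3, n_rows = 80L, n_cols = 80L,
                                       n_settlements = 12L,
                                       n_district_rows = 2L,
                                       n_district_cols = 2L,
                                       n_provinces = 1L))
  sup <- build_supply(b$npp, b$cover)
  ages <- disaggregate_herd_ages(b$livestock, b$census)
  led <- build_demand_ledger(herd_energy_demand(ages, b$nutritive),
                             allocate_fodder(b$fodder, b$fodder_tables))
  dem <- settlement_demand(led, b$settlements)
  rates <- seq(0.10, 0.60, by = 0.05)
  runs <- lapply(rates, function(o)
    run_allocation(sup, dem, b$settlements, o, quiet = TRUE))
  areas <- vapply(runs, function(r) glance(r)$utilized_area_km2, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  # single-settlement max distance non-increasing in the rate
  sid <- dem$settlement_id[which.max(dem$grazing_demand_mj)]
  dists <- vapply(runs, function(r)
    max(tidy(r)$max_distance_km[tidy(r)$settlement_id == sid]), numeric(1))
  expect_true(all(diff(dists) <= 1e-9))
})

test_that("identical inputs give bit-identical claim maps", {
  inst <- random_instance(99, nr = 8, nc = 8, ns = 3, ng = 2)
  r1 <- run_instance(inst)
  r2 <- run_instance(inst)
  expect_identical(r1$claim$values, r2$claim$values)
  expect_identical(r1$consumed$values, r2$consumed$values)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("allocate_group stacks onto prior claims exclusively", {
  sup <- make_uniform_supply(6, 6, 10)
  sett <- one_settlement(1500, 1500)
  gs <- group_specs()
  r1 <- allocate_group(sup, demand_row(1L, 40, "sheep_goats", "HH"), sett,
                       0.5, gs[1, ], quiet = TRUE)
  r2 <- allocate_group(sup, demand_row(1L, 40, "cattle", "HH"), sett,
                       0.5, gs[2, ], claims = r1, quiet = TRUE)
  g <- r2$group$values
  expect_equal(sum(g == 1, na.rm = TRUE), 8)
  expect_equal(sum(g == 2, na.rm = TRUE), 8)
  expect_equal(sum(r2$consumed$values), 80, tolerance = 1e-12)
})
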