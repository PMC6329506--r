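# Shared in-code fixtures. All grids are metres; energies MJ.

# Supply object with an exactly prescribed energy-density matrix (MJ/m2) on
# all-grassland cover; inverts the grassland conversion so build_supply()
# reproduces `density` bit-for-bit path-wise.
make_supply <- function(density, cell = 500) {
  p <- supply_params()
  npp <- graze_raster(density * p$carbon_to_dm * 1000 / p$grass_energy, cell)
  cov <- graze_raster(matrix(cover_classes()[["grassland"]],
                             nrow(as.matrix(density)),
                             ncol(as.matrix(density))), cell)
  build_supply(npp, cov, p)
}

# Supply whose pixels each hold `mj_per_pixel` MJ in total.
make_uniform_supply <- function(nr, nc, mj_per_pixel, cell = 500) {
  make_supply(matrix(mj_per_pixel / cell^2, nr, nc), cell)
}

one_settlement <- function(x, y, population = 100, district_id = 1L) {
  tibble::tibble(settlement_id = 1L, x = x, y = y,
                 population = population, district_id = district_id)
}

demand_row <- function(settlement_id, mj, species = "cattle",
                       farm_type = "HH", district_id = 1L) {
  tibble::tibble(settlement_id = settlement_id, district_id = district_id,
                 species = species, farm_type = farm_type,
                 grazing_demand_mj = mj)
}

# Random small allocation instance with deliberate energy ties, for oracle
# comparison. Grid <= 8x8, <= 3 settlements, <= 3 groups.
random_instance <- function(seed, nr = NULL, nc = NULL, ns = NULL, ng = NULL) {
  set.seed(seed)
  if (is.null(nr)) nr <- sample(3:8, 1)
  if (is.null(nc)) nc <- sample(3:8, 1)
  if (is.null(ns)) ns <- sample(1:3, 1)
  if (is.null(ng)) ng <- sample(1:3, 1)
  cell <- 500
  # few discrete energy levels force tie-breaking; some zero pixels
  levels <- c(0, 4, 4, 6, 10)
  mj <- matrix(sample(levels, nr * nc, replace = TRUE), nr, nc)
  supply <- make_supply(mj / cell^2, cell)
  sett <- tibble::tibble(
    settlement_id = seq_len(ns),
    x = stats::runif(ns, 0, nc * cell),
    y = stats::runif(ns, 0, nr * cell),
    population = 100, district_id = 1L)
  specs <- group_specs()[seq_len(ng), ]
  demands <- matrix(stats::runif(ns * ng, 0, 30), ns, ng)
  demands[stats::runif(ns * ng) < 0.2] <- 0
  offtake <- sample(c(0.2, 0.5, 1.0), ns, replace = TRUE)
  list(supply = supply, sett = sett, specs = specs, demands = demands,
       offtake = offtake, cell = cell)
}

run_instance <- function(inst) {
  dem <- purrr::map_dfr(seq_len(nrow(inst$specs)), function(g) {
    tibble::tibble(settlement_id = inst$sett$settlement_id,
                   district_id = 1L,
                   species = inst$specs$species[g],
                   farm_type = inst$specs$farm_type[g],
                   grazing_demand_mj = inst$demands[, g])
  })
  run_allocation(inst$supply, dem, inst$sett,
                 tibble::tibble(settlement_id = inst$sett$settlement_id,
                                rate = inst$offtake),
                 specs = inst$specs, quiet = TRUE)
}

oracle_instance <- function(inst) {
  er <- inst$supply$energy
  oracle_allocate(er$values * inst$cell^2, inst$cell, er$xll, er$yll,
                  inst$sett, inst$demands, inst$specs$radius_km * 1000,
                  inst$offtake)
}

# Small demand-side tables used across demand tests.
toy_counts <- function() {
  tibble::tibble(
    district_id = c(1L, 1L, 2L), province_id = 1L,
    species = c("cattle", "cattle", "cattle"),
    farm_type = c("HH", "PF", "HH"),
    head = c(1000, 500, 0))
}

toy_census <- function() {
  tibble::tibble(
    province_id = 1L, species = "cattle",
    age_group = c("A", "B", "C"),
    head = c(400, 600, 1000))
}
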