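test_that("mass-balance SO2 follows the sulfur bookkeeping", {
  # direct arithmetic: 2 * 0.01 * 1000 * 0.8 * (1 - 0.6) * 1e3 = 6400 kg
  expect_equal(mass_balance_so2(0.01, 1000, 0.8, 0.6), 6400)
  # full desulfurization or sulfur-free fuel emits nothing
  expect_equal(mass_balance_so2(0.02, 5000, 0.8, 1), 0)
  expect_equal(mass_balance_so2(0, 1000, 0.8, 0), 0)
  # linear in fuel consumption and sulfur content
  expect_equal(mass_balance_so2(0.01, 3000, 0.8, 0.6),
               3 * mass_balance_so2(0.01, 1000, 0.8, 0.6))
  expect_error(mass_balance_so2(1.2, 1000), "fraction")
  expect_error(mass_balance_so2(0.01, -5), "fuel_consumption")
  expect_error(mass_balance_so2(0.01, 1000, desulfurization_rate = -0.1),
               "fraction")
})

test_that("vehicle emissions scale with fleet, mileage and factor", {
  fleet <- data.frame(vehicle_type = c("a", "b"),
                      count = c(100, 0),
                      annual_mileage_km = c(10000, 5000),
                      ef_so2_gkm = c(0.05, 0.05),
                      ef_pm10_gkm = c(0.02, 0.02))
  ve <- vehicle_emissions(fleet, "SO2")
  # 100 vehicles x 10,000 km x 0.05 g/km = 50 kg = 0.05 t
  expect_equal(ve$emission_t, c(0.05, 0))
  expect_equal(vehicle_total(ve), 0.05)
  # zero fleet emits zero
  fleet0 <- transform(fleet, count = 0)
  expect_equal(vehicle_total(vehicle_emissions(fleet0, "PM10")), 0)
  expect_error(vehicle_emissions(fleet, "NOx"))
  expect_error(vehicle_emissions(fleet[0, ], "SO2"), "non-empty")
})

test_that("pollutant ratio equals the emission-factor ratio per class", {
  set.seed(11)
  fleet <- data.frame(vehicle_type = letters[1:6],
                      count = round(runif(6, 10, 1e5)),
                      annual_mileage_km = round(runif(6, 1e3, 5e4)),
                      ef_so2_gkm = runif(6, 0.005, 0.2),
                      ef_pm10_gkm = runif(6, 0.005, 0.2))
  so2 <- vehicle_emissions(fleet, "SO2")$emission_t
  pm10 <- vehicle_emissions(fleet, "PM10")$emission_t
  expect_equal(pm10 / so2, fleet$ef_pm10_gkm / fleet$ef_so2_gkm)
})

test_that("area-source emission is activity times factor", {
  rec <- list(source_category = "agricultural", activity_amount = 1000,
              ef_so2 = 0.4, ef_pm10 = 10)
  # 1000 t residue x 10 kg/t = 10 t PM10; x 0.4 kg/t = 0.4 t SO2
  expect_equal(area_source_emissions(rec, "PM10"), 10)
  expect_equal(area_source_emissions(rec, "SO2"), 0.4)
  rec$activity_amount <- 0
  expect_equal(area_source_emissions(rec, "PM10"), 0)
  # a category whose SO2 comes from mass balance has no SO2 factor
  kp <- list(source_category = "key_plot", activity_amount = 100,
             ef_so2 = NA, ef_pm10 = 2.97)
  expect_error(area_source_emissions(kp, "SO2"), "mass_balance_so2")
})

test_that("inventory assembles emissions, totals and shares", {
  sources <- data.frame(source = "only", so2_t = 123.4, pm10_t = 5)
  inv <- build_inventory(sources, year = 2010)
  # a single source owns 100% of its group share
  expect_equal(inv$entries$share_pct, c(100, 100))
  # mixed methods: mass balance, emission factor, direct
  sources <- data.frame(
    source = c("key_plot", "agricultural"),
    sulfur_content = c(0.01, NA), fuel_t = c(1000, NA),
    conversion_rate = c(0.8, NA), desulf_rate = c(0.6, NA),
    activity_t = c(NA, 1000), ef_so2_kgt = c(NA, 0.4),
    ef_pm10_kgt = c(NA, 10), pm10_t = c(50, NA))
  inv <- build_inventory(sources, year = 2010)
  e <- inv$entries
  expect_equal(e$emission_t[e$source == "key_plot" & e$pollutant == "SO2"],
               6.4)          # 6400 kg from the mass balance
  expect_equal(e$emission_t[e$source == "agricultural" &
                              e$pollutant == "SO2"], 0.4)
  expect_equal(inventory_total(inv, "PM10"), 60)
  # shares within each pollutant group sum to 100
  sums <- tapply(e$share_pct, interaction(e$group, e$pollutant, drop = TRUE),
                 sum)
  expect_equal(as.vector(sums), rep(100, length(sums)))
  # missing parameters are a named validation error
  bad <- data.frame(source = "mystery")
  expect_error(build_inventory(bad), "mystery")
})

test_that("scaling every activity scales emissions, not shares", {
  set.seed(3)
  sources <- data.frame(source = c("rural_residential", "agricultural"),
                        activity_t = runif(2, 1e4, 1e5),
                        ef_so2_kgt = c(0.4, 0.4), ef_pm10_kgt = c(3.74, 10))
  fleet <- data.frame(vehicle_type = c("car", "truck"),
                      count = c(1e4, 2e3), annual_mileage_km = c(2e4, 5e4),
                      ef_so2_gkm = c(0.01, 0.1), ef_pm10_gkm = c(0.02, 0.02))
  k <- 2.5
  inv1 <- build_inventory(sources, fleet)
  inv2 <- build_inventory(transform(sources, activity_t = activity_t * k),
                          transform(fleet, count = count * k))
  expect_equal(inv2$entries$emission_t, k * inv1$entries$emission_t)
  expect_equal(inv2$entries$share_pct, inv1$entries$share_pct)
})

test_that("published inventory rows reproduce printed totals and shares", {
  rows <- published_inventory_rows(2010)
  inv <- build_inventory(rows$sources, rows$fleet, year = 2010)
  expect_equal(inventory_total(inv, "SO2", "point_area"), 35135.45)
  expect_equal(inventory_total(inv, "PM10", "point_area"), 25267.99)
  e <- inv$entries
  share <- function(src, pol)
    e$share_pct[e$source == src & e$pollutant == pol]
  expect_equal(round(share("key_plot", "SO2"), 1), 74.1)
  expect_equal(round(share("agricultural", "PM10"), 1), 58.9)
  expect_equal(round(share("small_car", "SO2"), 2), 13.68)
  # transportation PM10: exact row sum (printed total carries a rounding slip)
  expect_equal(inventory_total(inv, "PM10", "transportation"), 8805.23)
})

test_that("rasterization spreads emissions uniformly and conserves mass", {
  g <- lapmd_grid(4, 4, 300)
  lu <- matrix(6L, 4, 4)
  lu[1:2, 1:2] <- 4L                    # 4 agricultural cells
  landuse <- lapmd_raster(lu, g)
  dem <- lapmd_raster(matrix(10, 4, 4), g)
  inv <- build_inventory(
    data.frame(source = "agricultural", so2_t = 100, pm10_t = 0))
  sf <- rasterize_emissions(inv, landuse, c(agricultural = 4L),
                            c(agricultural = 0), dem, "SO2")
  # 100 t over 4 cells -> 25 t each, zero elsewhere
  expect_equal(unname(sf$q[1:2, 1:2]), matrix(25, 2, 2))
  expect_equal(sum(sf$q), 100)
  expect_equal(as.numeric(sf$elevation[3, 3]), 10)
  # emission in a category absent from the raster is an error
  inv2 <- build_inventory(data.frame(source = "key_plot", so2_t = 5,
                                     pm10_t = 0))
  expect_error(
    rasterize_emissions(inv2, landuse, c(agricultural = 4L, key_plot = 1L),
                        c(key_plot = 45), dem, "SO2"),
    "zero cells")
})

test_that("point plots override uniform spreading and keep conservation", {
  g <- lapmd_grid(5, 5, 300)
  lu <- matrix(6L, 5, 5); lu[3, 3] <- 1L
  landuse <- lapmd_raster(lu, g)
  dem <- lapmd_raster(matrix(0, 5, 5), g)
  inv <- build_inventory(data.frame(source = "key_plot", so2_t = 300,
                                    pm10_t = 0))
  plots <- data.frame(row = c(1, 5), col = c(1, 5),
                      emission_t = c(100, 200), delta_h = c(30, 60))
  sf <- rasterize_emissions(inv, landuse, c(key_plot = 1L),
                            c(key_plot = 45), dem, "SO2",
                            point_plots = plots)
  expect_equal(sum(sf$q > 0), 2L)
  expect_equal(as.numeric(sf$q[1, 1]), 100)
  expect_equal(as.numeric(sf$q[5, 5]), 200)
  expect_equal(as.numeric(sf$delta_h[5, 5]), 60)
  expect_equal(sum(sf$q), 300)
  # tonnages that disagree with the inventory are rejected
  plots$emission_t <- c(100, 100)
  expect_error(rasterize_emissions(inv, landuse, c(key_plot = 1L),
                                   c(key_plot = 45), dem, "SO2",
                                   point_plots = plots), "sum")
})

test_that("rasterized mass matches the inventory on the toy city", {
  city <- make_toy_city(toy_city_spec(nrow = 20, ncol = 20, seed = 5))
  inv <- build_inventory(city$params$sources, city$params$fleet)
  for (pol in c("SO2", "PM10")) {
    sf <- rasterize_emissions(inv, city$landuse, city$legend,
                              city$params$heights, city$dem, pol)
    expect_equal(sum(sf$q), inventory_total(inv, pol),
                 tolerance = 1e-6)
  }
})
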