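#' Specification of the synthetic toy city
#'
#' Defines a small self-contained study area with the layers the pipeline
#' consumes: a categorical land-use raster (urban core, rural patches,
#' agricultural background, a road cross, a handful of key industrial
#' plots), a gently sloping DEM, a year of daily meteorology with a
#' prevailing wind sector, and plausible inventory parameters. All
#' randomness is driven by `seed`; regenerating with the same spec is
#' bit-identical.
#'
#' Defaults mirror the scale of a city-level planning assessment: a 40 x 40
#' grid at the 300-m resolution such assessments use, a temperate coastal
#' meteorology (mean daily wind 3.2 m/s, southeast prevailing sector
#' holding 30% of days), and emission parameters in the ranges typical of
#' coal-burning mid-size Chinese cities (coal sulfur content around 1%,
#' key-plot desulfurization 0.6, none for residential use).
#'
#' @param nrow,ncol grid dimensions (>= 10)
#' @param cellsize cell size, m
#' @param seed integer seed fixing all generated randomness
#' @param fractions named fractions of grid cells for `urban_residential`,
#'   `rural_residential` and `agricultural`; must sum to <= 1 (the road
#'   cross and key plots are carved out geometrically)
#' @param n_key_plots number of key industrial plot cells
#' @param prevailing_dir centre (degrees) of the prevailing wind sector
#' @param prevailing_frac fraction of days blowing from that sector; the
#'   other seven sectors share the rest equally
#' @param speed_mean,speed_sd daily mean wind speed distribution, m/s
#' @param latitude degrees north, for solar elevation in the stability
#'   scheme
#' @return list of class `lapmd_toy_spec`
#' @export
toy_city_spec <- function(nrow = 40, ncol = 40, cellsize = 300, seed = 42,
                          fractions = c(urban_residential = 0.08,
                                        rural_residential = 0.12,
                                        agricultural = 0.55),
                          n_key_plots = 3,
                          prevailing_dir = 135, prevailing_frac = 0.30,
                          speed_mean = 3.2, speed_sd = 1.2,
                          latitude = 34.6) {
  if (nrow < 10 || ncol < 10) stop("toy grid must be at least 10 x 10")
  if (sum(fractions) > 1) stop("land-use fractions must sum to <= 1")
  if (prevailing_frac < 1 / 8 || prevailing_frac > 1)
    stop("prevailing_frac must be in [1/8, 1]")
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize,
                 seed = as.integer(seed), fractions = fractions,
                 n_key_plots = n_key_plots,
                 prevailing_dir = prevailing_dir,
                 prevailing_frac = prevailing_frac,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 latitude = latitude),
            class = "lapmd_toy_spec")
}

#' Land-use code legend of the toy city
#' @return named integer vector category -> raster code
#' @export
toy_legend <- function() {
  c(key_plot = 1L, urban_residential = 2L, rural_residential = 3L,
    agricultural = 4L, transportation = 5L, other = 6L)
}

#' Default source heights of the toy city
#'
#' Key plots carry stack height; residential categories carry half the
#' typical building height; ground-level release for agricultural burning
#' and traffic.
#' @return named numeric vector, metres above ground
#' @export
toy_heights <- function() {
  c(key_plot = 45, urban_residential = 10, rural_residential = 3,
    agricultural = 0, transportation = 0.5)
}

#' Generate the toy land-use raster and DEM
#'
#' The urban core is the block of cells nearest the grid centre; rural
#' patches grow around random seeds outside the core; agricultural land
#' fills outward from the rural fringe; a one-cell road cross runs through
#' the centre; `n_key_plots` cells on the urban fringe carry the key-plot
#' code. The DEM slopes gently upward away from the south-west corner with
#' smooth low-amplitude relief.
#'
#' @param spec a [toy_city_spec()]
#' @return list with `landuse` and `dem` rasters and the `legend`
#' @export
make_landuse <- function(spec) {
  set.seed(spec$seed)
  leg <- toy_legend()
  nr <- spec$nrow; nc <- spec$ncol
  ncell <- nr * nc
  lu <- matrix(leg[["other"]], nr, nc)
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  d_ctr <- sqrt((rowm - ctr[1])^2 + (colm - ctr[2])^2)
  # road cross first so other categories can overwrite nothing of it
  mid_r <- ceiling(nr / 2); mid_c <- ceiling(nc / 2)
  lu[mid_r, ] <- leg[["transportation"]]
  lu[, mid_c] <- leg[["transportation"]]
  free <- lu == leg[["other"]]
  # contiguous urban core: nearest free cells to the centre
  n_urban <- round(spec$fractions[["urban_residential"]] * ncell)
  ord <- order(d_ctr + ifelse(free, 0, 1e6))
  urban_cells <- ord[seq_len(n_urban)]
  lu[urban_cells] <- leg[["urban_residential"]]
  # rural patches: grow around random distant seeds
  n_rural <- round(spec$fractions[["rural_residential"]] * ncell)
  free <- lu == leg[["other"]]
  far <- which(free & d_ctr > max(nr, nc) / 4)
  seeds <- sample(far, min(6L, length(far)))
  d_seed <- Reduce(pmin, lapply(seeds, function(s) {
    sr <- rowm[s]; sc <- colm[s]
    sqrt((rowm - sr)^2 + (colm - sc)^2)
  }))
  ord <- order(d_seed + ifelse(free, 0, 1e6))
  lu[ord[seq_len(min(n_rural, sum(free)))]] <- leg[["rural_residential"]]
  # agricultural background: outward from the urban fringe
  n_agri <- round(spec$fractions[["agricultural"]] * ncell)
  free <- lu == leg[["other"]]
  ord <- order(d_ctr + ifelse(free, 0, 1e6))
  lu[ord[seq_len(min(n_agri, sum(free)))]] <- leg[["agricultural"]]
  # key plots on the urban fringe (replace urban cells, keep count exact)
  fringe <- urban_cells[order(-d_ctr[urban_cells])]
  plots <- fringe[seq_len(spec$n_key_plots)]
  lu[plots] <- leg[["key_plot"]]
  grid <- lapmd_grid(nr, nc, spec$cellsize)
  dem <- 5 + 25 * (colm / nc) + 10 * (1 - rowm / nr) +
    3 * sin(rowm / 4) * cos(colm / 5)
  list(landuse = lapmd_raster(lu, grid),
       dem = lapmd_raster(dem, grid),
       legend = leg, key_plot_cells = plots)
}

#' Generate a year of daily meteorology
#'
#' Wind-from directions are drawn sector-wise (the prevailing sector with
#' probability `prevailing_frac`, the rest uniform) with uniform jitter
#' within the sector; speeds are normal truncated at 0.2 m/s; cloud cover
#' is Beta(2, 2); solar elevation is the noon value for the day of year at
#' the spec latitude.
#'
#' @param spec a [toy_city_spec()]
#' @param n_days number of daily records
#' @return data frame with `date`, `wind_dir_deg`, `wind_speed_ms`,
#'   `cloud_frac`, `solar_elev_deg`
#' @export
make_met <- function(spec, n_days = 365) {
  set.seed(spec$seed + 1L)
  defs <- sector_definitions()
  prev <- sector_index(spec$prevailing_dir)
  probs <- rep((1 - spec$prevailing_frac) / 7, 8)
  probs[prev] <- spec$prevailing_frac
  sec <- sample.int(8L, n_days, replace = TRUE, prob = probs)
  dir <- (defs$center[sec] + runif(n_days, -22.5, 22.5)) %% 360
  speed <- pmax(rnorm(n_days, spec$speed_mean, spec$speed_sd), 0.2)
  cloud <- rbeta(n_days, 2, 2)
  date <- as.Date("2010-01-01") + seq_len(n_days) - 1L
  data.frame(date = date, wind_dir_deg = dir, wind_speed_ms = speed,
             cloud_frac = cloud,
             solar_elev_deg = solar_noon_elevation(date, spec$latitude))
}

#' Generate toy inventory parameters
#'
#' Produces the point/area source table (mass-balance inputs for key
#' plots and urban residential SO2, emission-factor inputs elsewhere), a
#' per-plot tonnage split for point placement, and a nine-class vehicle
#' fleet. Emission factors follow the published per-category values used
#' for city inventories (rural residential 0.4 / 3.74 kg/ton, agricultural
#' 0.4 / 10 kg/ton, key-plot PM10 2.97 kg/ton, urban PM10 0.15 kg/ton).
#'
#' @param spec a [toy_city_spec()]
#' @return list with `sources` (data frame), `fleet` (data frame),
#'   `plot_fuel_t` (per-key-plot coal, ton/yr) and `heights`
#' @export
make_inventory_params <- function(spec) {
  set.seed(spec$seed + 2L)
  np <- spec$n_key_plots
  plot_fuel <- round(runif(np, 4e4, 1.2e5))
  sources <- data.frame(
    source = c("key_plot", "urban_residential", "rural_residential",
               "agricultural"),
    sulfur_content = c(0.011, 0.009, NA, NA),
    fuel_t = c(sum(plot_fuel), round(runif(1, 3e4, 6e4)), NA, NA),
    conversion_rate = c(0.8, 0.8, NA, NA),
    desulf_rate = c(0.6, 0, NA, NA),
    activity_t = c(sum(plot_fuel), NA, round(runif(1, 5e4, 9e4)),
                   round(runif(1, 1e5, 2e5))),
    ef_so2_kgt = c(NA, NA, 0.4, 0.4),
    ef_pm10_kgt = c(2.97, NA, 3.74, 10),
    stringsAsFactors = FALSE)
  # urban residential PM10 via its own activity (same fuel, EF 0.15)
  sources$activity_t[2] <- sources$fuel_t[2]
  sources$ef_pm10_kgt[2] <- 0.15
  fleet <- data.frame(
    vehicle_type = c("large_vehicle", "medium_vehicle", "small_car",
                     "mini_vehicle", "heavy_truck", "medium_truck",
                     "light_truck", "mini_truck", "tricar"),
    count = round(runif(9, 2e3, 6e4)),
    annual_mileage_km = round(runif(9, 8e3, 6e4)),
    ef_so2_gkm = c(0.05, 0.01, 0.01, 0.01, 0.10, 0.05, 0.01, 0.01, 0.05),
    ef_pm10_gkm = rep(0.02, 9),
    stringsAsFactors = FALSE)
  list(sources = sources, fleet = fleet, plot_fuel_t = plot_fuel,
       heights = toy_heights())
}

#' Generate a toy planning layer
#'
#' Two planning categories on the toy grid: newly planned urban land (a
#' ring of cells just outside the present urban core) and newly planned
#' rural land (a sample of agricultural cells away from the core). Cells
#' outside the scheme are `NA`.
#'
#' @param spec a [toy_city_spec()]
#' @param landuse result of [make_landuse()]
#' @return list with `planning` raster and `legend`
#'   (`c(new_urban = 1, new_rural = 2)`)
#' @export
make_planning <- function(spec, landuse) {
  set.seed(spec$seed + 3L)
  leg <- landuse$legend
  lu <- unclass_matrix(landuse$landuse)
  nr <- spec$nrow; nc <- spec$ncol
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  d_ctr <- sqrt((rowm - ctr[1])^2 + (colm - ctr[2])^2)
  urbanish <- lu %in% c(leg[["urban_residential"]], leg[["key_plot"]])
  r_core <- max(d_ctr[urbanish])
  plan <- matrix(NA_real_, nr, nc)
  ring <- !urbanish & d_ctr > r_core & d_ctr <= r_core + 3
  plan[ring] <- 1
  agri_far <- which(lu == leg[["agricultural"]] & d_ctr > r_core + 6)
  pick <- sample(agri_far, min(length(agri_far), round(0.3 * length(agri_far))))
  plan[pick] <- 2
  list(planning = lapmd_raster(plan, raster_grid(landuse$landuse)),
       legend = c(new_urban = 1L, new_rural = 2L))
}

#' Generate the complete toy city
#'
#' Convenience wrapper chaining [make_landuse()], [make_met()],
#' [make_inventory_params()] and [make_planning()]; optionally writes
#' every layer to `dir` in the pipeline's file formats (.asc rasters,
#' .csv tables, .json config).
#'
#' @param spec a [toy_city_spec()]
#' @param dir optional output directory
#' @return list with all layers, parameters and (if written) file paths
#' @export
make_toy_city <- function(spec = toy_city_spec(), dir = NULL) {
  land <- make_landuse(spec)
  met <- make_met(spec)
  params <- make_inventory_params(spec)
  plan <- make_planning(spec, land)
  city <- list(spec = spec, landuse = land$landuse, dem = land$dem,
               legend = land$legend, key_plot_cells = land$key_plot_cells,
               met = met, params = params,
               planning = plan$planning, planning_legend = plan$legend)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_asc(land$landuse, file.path(dir, "landuse.asc"), digits = 1)
    write_asc(land$dem, file.path(dir, "dem.asc"))
    write_asc(plan$planning, file.path(dir, "planning.asc"), digits = 1)
    write_met_csv(met, file.path(dir, "met.csv"))
    utils::write.csv(params$sources, file.path(dir, "sources.csv"),
                     row.names = FALSE)
    utils::write.csv(params$fleet, file.path(dir, "fleet.csv"),
                     row.names = FALSE)
    cfg <- list(legend = as.list(land$legend),
                planning_legend = as.list(plan$legend),
                heights = as.list(params$heights),
                plot_fuel_t = params$plot_fuel_t,
                key_plot_cells = land$key_plot_cells,
                seed = spec$seed, latitude = spec$latitude)
    jsonlite::write_json(cfg, file.path(dir, "toy_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    city$files <- list(
      landuse = file.path(dir, "landuse.asc"),
      dem = file.path(dir, "dem.asc"),
      planning = file.path(dir, "planning.asc"),
      met = file.path(dir, "met.csv"),
      sources = file.path(dir, "sources.csv"),
      fleet = file.path(dir, "fleet.csv"),
      config = file.path(dir, "toy_config.json"))
  }
  city
}
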