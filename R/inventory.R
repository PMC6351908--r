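#' Annual SO2 emission by the mass-balance method
#'
#' Sulfur entering combustion leaves as SO2 except for the fraction that is
#' not converted or is captured by desulfurization equipment:
#' \deqn{E = (M_{SO2}/M_S)\, S\, \omega\, \varepsilon\, (1-\eta)\times 10^3
#'  \quad \mathrm{kg}}
#' with molecular-weight ratio \eqn{M_{SO2}/M_S = 64/32 = 2}.
#'
#' @param sulfur_content sulfur mass fraction of the fuel, in `[0, 1]`
#' @param fuel_consumption fuel burned, ton/yr (>= 0)
#' @param conversion_rate fraction of fuel sulfur converted to SO2, in
#'   `[0, 1]`; 0.8 is typical for coal and 1.0 for oil
#' @param desulfurization_rate fraction of formed SO2 removed by controls,
#'   in `[0, 1]`; 0 when no controls are in place
#' @return emitted SO2 mass in kg/yr (vectorized over its arguments)
#' @examples
#' mass_balance_so2(0.01, 1000, 0.8, 0.6)  # 6400 kg
#' @export
mass_balance_so2 <- function(sulfur_content, fuel_consumption,
                             conversion_rate = 0.8,
                             desulfurization_rate = 0) {
  check_fraction(sulfur_content, "sulfur_content")
  check_fraction(conversion_rate, "conversion_rate")
  check_fraction(desulfurization_rate, "desulfurization_rate")
  if (any(fuel_consumption < 0)) stop("fuel_consumption must be >= 0")
  2 * sulfur_content * fuel_consumption * conversion_rate *
    (1 - desulfurization_rate) * 1e3
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must be a fraction in [0, 1]", name))
  invisible(x)
}

#' Vehicle-fleet emissions by the emission-factor method
#'
#' Per vehicle class j: \eqn{E_j = P_j M_j EF_{i,j} \times 10^{-3}} kg,
#' with fleet size `P` (vehicles), annual mileage `M` (km/vehicle/yr) and
#' emission factor `EF` (g/km per vehicle). Results are reported in tons.
#'
#' @param fleet data frame with columns `vehicle_type`, `count`,
#'   `annual_mileage_km`, `ef_so2_gkm`, `ef_pm10_gkm`
#' @param pollutant `"SO2"` or `"PM10"`
#' @return data frame with per-type `emission_t` plus a `total_t` attribute;
#'   `vehicle_total()` retrieves the total
#' @export
vehicle_emissions <- function(fleet, pollutant = c("SO2", "PM10")) {
  pollutant <- match.arg(pollutant)
  need <- c("vehicle_type", "count", "annual_mileage_km",
            "ef_so2_gkm", "ef_pm10_gkm")
  miss <- setdiff(need, names(fleet))
  if (length(miss)) stop("fleet is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(fleet) == 0) stop("fleet must be non-empty")
  if (any(fleet$count < 0) || any(fleet$annual_mileage_km < 0))
    stop("count and annual_mileage_km must be >= 0")
  ef <- if (pollutant == "SO2") fleet$ef_so2_gkm else fleet$ef_pm10_gkm
  if (any(ef < 0)) stop("emission factors must be >= 0")
  kg <- as.numeric(fleet$count) * as.numeric(fleet$annual_mileage_km) *
    ef * 1e-3
  out <- data.frame(vehicle_type = fleet$vehicle_type,
                    pollutant = pollutant,
                    emission_t = kg / 1e3,
                    stringsAsFactors = FALSE)
  attr(out, "total_t") <- sum(out$emission_t)
  out
}

#' @rdname vehicle_emissions
#' @param x result of `vehicle_emissions()`
#' @export
vehicle_total <- function(x) attr(x, "total_t")

#' Area-source emission by the emission-factor method
#'
#' Emission = activity amount (ton/yr of fuel burned or crop residue
#' combusted) x emission factor (kg/ton) x 1e-3, in ton/yr. Used for
#' rural-residential and agricultural SO2 and PM10 and for the PM10 of key
#' plots and urban residential land; SO2 from fossil-fuel categories goes
#' through [mass_balance_so2()] instead.
#'
#' @param record list or one-row data frame with `source_category`,
#'   `activity_amount` (ton/yr) and `ef_so2` / `ef_pm10` (kg/ton; `NA`
#'   where the pollutant is inventoried by another method)
#' @param pollutant `"SO2"` or `"PM10"`
#' @return emission in ton/yr
#' @export
area_source_emissions <- function(record, pollutant = c("SO2", "PM10")) {
  pollutant <- match.arg(pollutant)
  act <- record$activity_amount
  ef <- if (pollutant == "SO2") record$ef_so2 else record$ef_pm10
  if (is.null(act) || is.na(act) || act < 0)
    stop("activity_amount must be a non-negative number")
  if (is.null(ef) || is.na(ef))
    stop(sprintf(paste0("no %s emission factor defined for category '%s';",
                        " fossil-fuel SO2 is computed with mass_balance_so2()"),
                 pollutant, record$source_category))
  if (ef < 0) stop("emission factor must be >= 0")
  act * ef * 1e-3
}

#' Build a land-use-based annual emission inventory
#'
#' Assembles per-source annual SO2 and PM10 emissions into an inventory
#' with group totals and percentage shares. Point and area sources (key
#' plots, urban/rural residential, agricultural land) form one reporting
#' group; the vehicle fleet on transportation land forms the other, since
#' the two are tabulated separately.
#'
#' Each point/area source row resolves each pollutant's emission in this
#' order: a direct tonnage column (`so2_t` / `pm10_t`) if present and
#' non-`NA`; for SO2, the mass-balance parameters (`sulfur_content`,
#' `fuel_t`, `conversion_rate`, `desulf_rate`); otherwise the
#' emission-factor pair (`activity_t` with `ef_so2_kgt` / `ef_pm10_kgt`).
#' Fleet rows use direct `so2_t` / `pm10_t` if present, else
#' `count` x `annual_mileage_km` x EF via [vehicle_emissions()].
#'
#' @param sources data frame of point/area sources (column `source` plus
#'   the parameter columns above); may be `NULL`
#' @param fleet data frame of vehicle classes (column `vehicle_type` plus
#'   parameters above); may be `NULL`
#' @param year calendar year label
#' @return object of class `lapmd_inventory`: list with `year`, `entries`
#'   (group, source, pollutant, emission_t, share_pct) and `totals`
#' @export
build_inventory <- function(sources = NULL, fleet = NULL, year = NA) {
  entries <- list()
  if (!is.null(sources)) {
    if (!"source" %in% names(sources)) stop("sources needs a 'source' column")
    for (i in seq_len(nrow(sources))) {
      row <- sources[i, , drop = FALSE]
      for (pol in c("SO2", "PM10")) {
        e <- resolve_point_area_emission(row, pol)
        entries[[length(entries) + 1L]] <- data.frame(
          group = "point_area", source = row$source, pollutant = pol,
          emission_t = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(fleet)) {
    if (!"vehicle_type" %in% names(fleet))
      stop("fleet needs a 'vehicle_type' column")
    for (pol in c("SO2", "PM10")) {
      direct <- paste0(tolower(sub("SO2", "so2", sub("PM10", "pm10", pol))),
                       "_t")
      if (direct %in% names(fleet) && all(!is.na(fleet[[direct]]))) {
        em <- fleet[[direct]]
      } else {
        em <- vehicle_emissions(fleet, pol)$emission_t
      }
      entries[[length(entries) + 1L]] <- data.frame(
        group = "transportation", source = fleet$vehicle_type,
        pollutant = pol, emission_t = em, stringsAsFactors = FALSE)
    }
  }
  if (!length(entries)) stop("no sources or fleet given")
  entries <- do.call(rbind, entries)
  if (any(!is.finite(entries$emission_t) | entries$emission_t < 0))
    stop("all emissions must be finite and >= 0")
  grp <- interaction(entries$group, entries$pollutant, drop = TRUE)
  tot <- ave(entries$emission_t, grp, FUN = sum)
  entries$share_pct <- ifelse(tot > 0, 100 * entries$emission_t / tot, 0)
  totals <- aggregate(emission_t ~ group + pollutant, entries, sum)
  names(totals)[names(totals) == "emission_t"] <- "total_t"
  structure(list(year = year, entries = entries, totals = totals),
            class = "lapmd_inventory")
}

resolve_point_area_emission <- function(row, pollutant) {
  direct <- if (pollutant == "SO2") "so2_t" else "pm10_t"
  if (direct %in% names(row) && !is.na(row[[direct]]))
    return(as.numeric(row[[direct]]))
  if (pollutant == "SO2") {
    mb <- c("sulfur_content", "fuel_t")
    if (all(mb %in% names(row)) && all(!is.na(unlist(row[mb])))) {
      conv <- if (!is.null(row$conversion_rate) && !is.na(row$conversion_rate))
        row$conversion_rate else 0.8
      eta <- if (!is.null(row$desulf_rate) && !is.na(row$desulf_rate))
        row$desulf_rate else 0
      return(mass_balance_so2(row$sulfur_content, row$fuel_t, conv, eta) / 1e3)
    }
  }
  efcol <- if (pollutant == "SO2") "ef_so2_kgt" else "ef_pm10_kgt"
  if (all(c("activity_t", efcol) %in% names(row)) &&
      !is.na(row$activity_t) && !is.na(row[[efcol]])) {
    return(area_source_emissions(
      list(source_category = row$source, activity_amount = row$activity_t,
           ef_so2 = if (pollutant == "SO2") row[[efcol]] else NA,
           ef_pm10 = if (pollutant == "PM10") row[[efcol]] else NA),
      pollutant))
  }
  stop(sprintf("source '%s': missing parameters for %s (give %s, %s, or %s)",
               row$source, pollutant, direct,
               if (pollutant == "SO2") "mass-balance inputs" else "-",
               paste0("activity_t+", efcol)))
}

#' @export
print.lapmd_inventory <- function(x, digits = 2, ...) {
  cat(sprintf("<lapmd_inventory> year %s\n", x$year))
  e <- x$entries
  e$emission_t <- round(e$emission_t, digits)
  e$share_pct <- round(e$share_pct, digits)
  print(e, row.names = FALSE)
  cat("Totals:\n")
  t2 <- x$totals
  t2$total_t <- round(t2$total_t, digits)
  print(t2, row.names = FALSE)
  invisible(x)
}

#' Total emission of one pollutant in one reporting group
#' @param inventory a `lapmd_inventory`
#' @param pollutant `"SO2"` or `"PM10"`
#' @param group `"point_area"`, `"transportation"`, or `NULL` for all
#' @export
inventory_total <- function(inventory, pollutant, group = NULL) {
  t <- inventory$totals
  t <- t[t$pollutant == pollutant, ]
  if (!is.null(group)) t <- t[t$group == group, ]
  sum(t$total_t)
}

#' Spread inventoried emissions onto the land-use grid
#'
#' Each spatial source category's annual emission is divided evenly over
#' the raster cells carrying that category's land-use code; all
#' transportation-group (vehicle) emissions are spread over transportation
#' land the same way. Key plots may instead be placed as individual point
#' sources at stated cells via `point_plots`. Per-cell source height is the
#' emission-weighted mean of the contributing categories' heights, and
#' ground elevation is copied from the DEM.
#'
#' @param inventory a `lapmd_inventory`
#' @param landuse categorical [lapmd_raster()] of integer land-use codes
#' @param legend named integer vector mapping category name -> raster code,
#'   e.g. `c(key_plot = 1, urban_residential = 2, ...)`; inventory sources
#'   whose name is not in the legend must be covered by `category_of`
#' @param heights named numeric vector: source height above ground
#'   (delta H, m) per category
#' @param dem elevation [lapmd_raster()] (m above sea level), congruent
#'   with `landuse`
#' @param pollutant `"SO2"` or `"PM10"`
#' @param point_plots optional data frame (`row`, `col`, `emission_t`,
#'   optional `delta_h`) placing the key-plot category's emission at
#'   individual cells; the tonnages must sum to that category's
#'   inventoried emission
#' @param category_of optional named character vector mapping an inventory
#'   source name to a legend category (defaults: identical names;
#'   all `transportation` group entries -> `"transportation"`)
#' @return object of class `lapmd_source_field`: list with `grid`, and
#'   rasters `q` (ton/yr), `delta_h` (m) and `elevation` (m)
#' @export
rasterize_emissions <- function(inventory, landuse, legend, heights, dem,
                                pollutant = c("SO2", "PM10"),
                                point_plots = NULL, category_of = NULL) {
  pollutant <- match.arg(pollutant)
  stop_unless_congruent(landuse, dem, "landuse and dem")
  grid <- raster_grid(landuse)
  e <- inventory$entries
  e <- e[e$pollutant == pollutant & e$emission_t > 0, , drop = FALSE]
  # aggregate emissions per spatial category
  cat_of <- function(group, source) {
    if (!is.null(category_of) && source %in% names(category_of))
      return(category_of[[source]])
    if (group == "transportation") return("transportation")
    source
  }
  e$category <- mapply(cat_of, e$group, e$source)
  agg <- aggregate(emission_t ~ category, e, sum)
  q <- matrix(0, grid$nrow, grid$ncol)
  hsum <- matrix(0, grid$nrow, grid$ncol)
  lu <- unclass(landuse)
  for (i in seq_len(nrow(agg))) {
    categ <- agg$category[i]
    emis <- agg$emission_t[i]
    dh <- if (categ %in% names(heights)) heights[[categ]] else 0
    if (categ == "key_plot" && !is.null(point_plots)) {
      if (abs(sum(point_plots$emission_t) - emis) > 1e-8 * max(emis, 1))
        stop("point_plots tonnages must sum to the key_plot inventory total")
      for (k in seq_len(nrow(point_plots))) {
        r <- point_plots$row[k]; cc <- point_plots$col[k]
        ek <- point_plots$emission_t[k]
        dhk <- if (!is.null(point_plots$delta_h)) point_plots$delta_h[k] else dh
        q[r, cc] <- q[r, cc] + ek
        hsum[r, cc] <- hsum[r, cc] + ek * dhk
      }
      next
    }
    if (!categ %in% names(legend))
      stop(sprintf("no land-use code in legend for category '%s'", categ))
    cells <- which(lu == legend[[categ]])
    if (!length(cells))
      stop(sprintf(
        "category '%s' has emission %.3f t but zero cells in the raster",
        categ, emis))
    per_cell <- emis / length(cells)
    q[cells] <- q[cells] + per_cell
    hsum[cells] <- hsum[cells] + per_cell * dh
  }
  dH <- ifelse(q > 0, hsum / pmax(q, .Machine$double.xmin), 0)
  structure(list(grid = grid,
                 q = lapmd_raster(q, grid),
                 delta_h = lapmd_raster(dH, grid),
                 elevation = lapmd_raster(unclass_matrix(dem), grid),
                 pollutant = pollutant),
            class = "lapmd_source_field")
}

#' Construct a source field from rasters
#'
#' Low-level constructor when per-cell source intensities are already
#' known (e.g. built by hand for a test case or imported from another
#' inventory system); [rasterize_emissions()] is the usual path.
#'
#' @param q annual emission per cell, ton/yr, as a [lapmd_raster()]
#' @param delta_h source height above ground per cell, m
#' @param elevation ground elevation per cell, m above sea level
#' @param pollutant optional pollutant label
#' @return a `lapmd_source_field`
#' @export
source_field <- function(q, delta_h, elevation, pollutant = NULL) {
  stop_unless_congruent(q, delta_h, "q and delta_h")
  stop_unless_congruent(q, elevation, "q and elevation")
  if (any(unclass_matrix(q) < 0)) stop("q must be >= 0 everywhere")
  structure(list(grid = raster_grid(q), q = q, delta_h = delta_h,
                 elevation = elevation, pollutant = pollutant),
            class = "lapmd_source_field")
}

unclass_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "grid") <- NULL
  m
}

#' @export
print.lapmd_source_field <- function(x, ...) {
  cat(sprintf(
    "<lapmd_source_field> %s: %d x %d @ %g m, total Q %.3f ton/yr\n",
    x$pollutant %||% "?", x$grid$nrow, x$grid$ncol, x$grid$cellsize,
    sum(x$q)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
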