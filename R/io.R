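#' Read daily meteorology from CSV
#'
#' Expected columns: `date`, `wind_dir_deg`, `wind_speed_ms`,
#' `cloud_frac` and optionally `solar_elev_deg`.
#' @param path CSV path
#' @export
read_met_csv <- function(path) {
  met <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wind_dir_deg", "wind_speed_ms")
  miss <- setdiff(need, names(met))
  if (length(miss)) stop("met CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if ("date" %in% names(met)) met$date <- as.Date(met$date)
  met
}

#' @rdname read_met_csv
#' @param met daily meteorology data frame
#' @export
write_met_csv <- function(met, path) {
  utils::write.csv(met, path, row.names = FALSE)
  invisible(path)
}

#' Echo a wind rose (and its provenance) to JSON
#' @param rose a `lapmd_wind_rose`
#' @param path destination path
#' @export
write_wind_rose_json <- function(rose, path) {
  jsonlite::write_json(
    list(sectors = as.data.frame(rose),
         calm_fraction = attr(rose, "calm_fraction"),
         n_days = attr(rose, "n_days")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an inventory as a CSV table
#'
#' One row per (source, pollutant) with emission and within-group share,
#' followed by the group totals, mirroring the layout of published
#' land-use inventory tables.
#' @param inventory a `lapmd_inventory`
#' @param path destination path
#' @export
write_inventory_csv <- function(inventory, path) {
  e <- inventory$entries
  e$share_pct <- round(e$share_pct, 2)
  tot <- inventory$totals
  tot <- data.frame(group = tot$group, source = "Total",
                    pollutant = tot$pollutant, emission_t = tot$total_t,
                    share_pct = 100)
  utils::write.csv(rbind(e, tot), path, row.names = FALSE)
  invisible(path)
}

#' Published city inventory rows
#'
#' The per-source annual SO2 and PM10 emissions of the Lianyungang
#' 2010/2020 land-use inventories, as published, shipped as plain-text
#' CSVs with the package. Point/area rows carry the direct tonnages plus
#' the published emission factors and desulfurization rates; vehicle rows
#' carry tonnages and per-km emission factors. These serve as reference
#' inputs for inventory aggregation.
#'
#' @param year 2010 or 2020
#' @return list with data frames `sources` (point/area) and `fleet`
#'   (vehicle classes), shaped for [build_inventory()]
#' @export
published_inventory_rows <- function(year = c(2010, 2020)) {
  year <- match.arg(as.character(year), c("2010", "2020"))
  pa <- utils::read.csv(system.file("extdata", "lianyungang_point_area.csv",
                                    package = "lapmd"))
  vh <- utils::read.csv(system.file("extdata", "lianyungang_vehicles.csv",
                                    package = "lapmd"))
  list(sources = pa[pa$year == as.integer(year), , drop = FALSE],
       fleet = vh[vh$year == as.integer(year), , drop = FALSE])
}

#' Write a JSON provenance sidecar for an artifact
#'
#' Records the package version, an MD5 hash of the run configuration and
#' the MD5 of the artifact itself in `<artifact>.prov.json`. Deliberately
#' timestamp-free so re-runs with unchanged inputs are byte-identical.
#'
#' @param artifact path of the artifact just written
#' @param config the run configuration (any JSON-serializable list)
#' @param extra optional named list merged into the sidecar
#' @export
write_provenance <- function(artifact, config, extra = list()) {
  side <- c(list(
    artifact = basename(artifact),
    artifact_md5 = unname(tools::md5sum(artifact)),
    config_md5 = config_hash(config),
    package = "lapmd",
    version = as.character(utils::packageVersion("lapmd"))), extra)
  jsonlite::write_json(side, paste0(artifact, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(artifact)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
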