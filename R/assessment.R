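#' Concentration level scheme
#'
#' Ordered bin edges (mg/m^3) splitting a concentration field into
#' pollution levels. Defaults are the six-level schemes used for annual
#' city-scale mapping, anchored on the Chinese ambient air quality
#' standard (GB 3095-2012) annual limits: SO2 edges
#' 0.005/0.01/0.02/0.06/0.1 and PM10 edges 0.005/0.02/0.04/0.07/0.14.
#' A coarser three-level scheme can be had by passing three edges.
#' Intervals are `[lower, upper)`: a value equal to an edge belongs to the
#' higher level.
#'
#' @param pollutant `"SO2"` or `"PM10"` (selects the default edges)
#' @param edges optional strictly increasing numeric vector of bin edges,
#'   mg/m^3, overriding the default
#' @return list of class `lapmd_level_scheme` with `pollutant`, `edges`
#'   and human-readable `labels`
#' @export
level_scheme <- function(pollutant = c("SO2", "PM10"), edges = NULL) {
  pollutant <- match.arg(pollutant)
  if (is.null(edges))
    edges <- if (pollutant == "SO2") c(0.005, 0.01, 0.02, 0.06, 0.1)
             else c(0.005, 0.02, 0.04, 0.07, 0.14)
  if (length(edges) < 1 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  n <- length(edges)
  labels <- c(sprintf("<%g", edges[1]),
              if (n > 1) sprintf("%g-%g", edges[-n], edges[-1]),
              sprintf(">%g", edges[n]))
  structure(list(pollutant = pollutant, edges = edges, labels = labels),
            class = "lapmd_level_scheme")
}

#' Classify a concentration field into pollution levels
#'
#' @param field concentration [lapmd_raster()], mg/m^3; all cells must be
#'   finite
#' @param scheme a [level_scheme()]
#' @return list of class `lapmd_classification`: `levels` (integer
#'   [lapmd_raster()], 1 = cleanest), `table` (per level: label, cell
#'   count, area in hm^2, percent of grid) and `mean_concentration`
#' @export
classify_field <- function(field, scheme) {
  if (!inherits(scheme, "lapmd_level_scheme"))
    stop("scheme must be a lapmd_level_scheme")
  v <- unclass_matrix(field)
  if (any(!is.finite(v)))
    stop("concentration field contains non-finite cells")
  grid <- raster_grid(field)
  lev <- matrix(findInterval(v, scheme$edges) + 1L, grid$nrow, grid$ncol)
  nlev <- length(scheme$edges) + 1L
  counts <- tabulate(lev, nbins = nlev)
  area <- counts * cell_area_hm2(grid)
  tab <- data.frame(level = seq_len(nlev), label = scheme$labels,
                    cells = counts, area_hm2 = area,
                    pct = 100 * counts / sum(counts))
  structure(list(levels = lapmd_raster(lev, grid), table = tab,
                 mean_concentration = mean(v), scheme = scheme),
            class = "lapmd_classification")
}

#' @export
print.lapmd_classification <- function(x, ...) {
  cat(sprintf("<lapmd_classification> %s, mean %.5g mg/m^3\n",
              x$scheme$pollutant, x$mean_concentration))
  tab <- x$table
  tab$area_hm2 <- round(tab$area_hm2, 2)
  tab$pct <- round(tab$pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Overlay a level raster with a planning map
#'
#' Tabulates, for every planning category, the area falling in each
#' concentration level - the environmental-friendliness table of a
#' planning scheme. The planning layer is a categorical raster congruent
#' with the level raster (polygon inputs are rasterized by cell-centre
#' containment upstream); cells with `NA` planning code are outside the
#' scheme and ignored.
#'
#' @param classification a `lapmd_classification` (or a level
#'   [lapmd_raster()])
#' @param planning categorical [lapmd_raster()] of planning codes
#' @param legend optional named integer vector mapping category name ->
#'   planning code; unnamed codes are reported as `code_<n>`
#' @return data frame of class `lapmd_overlay`: `category`, `level`,
#'   `label`, `cells`, `area_hm2`, `pct` (of category); plus a
#'   `category_totals` attribute
#' @export
overlay_levels <- function(classification, planning, legend = NULL) {
  lev_r <- if (inherits(classification, "lapmd_classification"))
    classification$levels else classification
  labels <- if (inherits(classification, "lapmd_classification"))
    classification$scheme$labels else NULL
  stop_unless_congruent(lev_r, planning, "levels and planning")
  grid <- raster_grid(lev_r)
  lev <- unclass_matrix(lev_r)
  plan <- unclass_matrix(planning)
  inside <- !is.na(plan)
  if (!any(inside))
    stop("planning layer does not intersect the grid (all cells NA)")
  codes <- sort(unique(plan[inside]))
  name_of <- function(code) {
    if (!is.null(legend) && code %in% legend)
      names(legend)[match(code, legend)] else sprintf("code_%g", code)
  }
  nlev <- max(lev, if (!is.null(labels)) length(labels) else 0L)
  rows <- list()
  for (code in codes) {
    sel <- inside & plan == code
    counts <- tabulate(lev[sel], nbins = nlev)
    tot <- sum(counts)
    rows[[length(rows) + 1L]] <- data.frame(
      category = name_of(code), level = seq_len(nlev),
      label = if (!is.null(labels)) labels else sprintf("level_%d",
                                                        seq_len(nlev)),
      cells = counts,
      area_hm2 = counts * cell_area_hm2(grid),
      pct = if (tot > 0) 100 * counts / tot else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  totals <- aggregate(cbind(cells, area_hm2) ~ category, out, sum)
  structure(out, class = c("lapmd_overlay", "data.frame"),
            category_totals = totals)
}

#' Compare reference- and target-year concentration fields
#'
#' @param ref,target congruent concentration [lapmd_raster()]s, mg/m^3
#' @param scheme a [level_scheme()] applied to both fields
#' @return list of class `lapmd_comparison`: per-level area table with
#'   reference, target and change columns; mean concentrations and their
#'   change; and the cellwise `difference` raster (target - reference)
#' @export
compare_scenarios <- function(ref, target, scheme) {
  stop_unless_congruent(ref, target, "reference and target fields")
  cr <- classify_field(ref, scheme)
  ct <- classify_field(target, scheme)
  tab <- data.frame(level = cr$table$level, label = cr$table$label,
                    ref_area_hm2 = cr$table$area_hm2,
                    target_area_hm2 = ct$table$area_hm2)
  tab$change_hm2 <- tab$target_area_hm2 - tab$ref_area_hm2
  diff <- lapmd_raster(unclass_matrix(target) - unclass_matrix(ref),
                       raster_grid(ref))
  structure(list(table = tab,
                 ref_mean = cr$mean_concentration,
                 target_mean = ct$mean_concentration,
                 mean_change = ct$mean_concentration - cr$mean_concentration,
                 difference = diff, scheme = scheme),
            class = "lapmd_comparison")
}

#' @export
print.lapmd_comparison <- function(x, ...) {
  cat(sprintf(
    "<lapmd_comparison> %s: mean %.5g -> %.5g mg/m^3 (change %+.3g)\n",
    x$scheme$pollutant, x$ref_mean, x$target_mean, x$mean_change))
  print(x$table, row.names = FALSE)
  invisible(x)
}
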