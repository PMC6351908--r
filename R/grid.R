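#' Grid geometry for raster layers
#'
#' A minimal planar raster geometry: `nrow` x `ncol` cells of side
#' `cellsize` metres, lower-left corner at (`xll`, `yll`) in a projected
#' coordinate system. Row 1 of the value matrix is the NORTH edge of the
#' grid (map convention), so the cell-centre northing decreases with the
#' row index.
#'
#' @param nrow,ncol grid dimensions (positive integers)
#' @param cellsize cell side length in metres (> 0)
#' @param xll,yll easting/northing of the lower-left grid corner, metres
#' @return an object of class `lapmd_grid`
#' @export
lapmd_grid <- function(nrow, ncol, cellsize, xll = 0, yll = 0) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = as.numeric(cellsize),
                 xll = as.numeric(xll), yll = as.numeric(yll)),
            class = "lapmd_grid")
}

#' @export
print.lapmd_grid <- function(x, ...) {
  cat(sprintf("<lapmd_grid> %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Attach grid geometry to a value matrix
#'
#' @param values numeric or integer matrix with `grid$nrow` rows and
#'   `grid$ncol` columns; row 1 is the north edge
#' @param grid a [lapmd_grid()]
#' @return the matrix with class `lapmd_raster` and the geometry attached
#' @export
lapmd_raster <- function(values, grid) {
  values <- as.matrix(values)
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol)
    stop("matrix dimensions do not match the grid geometry")
  structure(values, grid = grid, class = c("lapmd_raster", class(values)))
}

#' @export
print.lapmd_raster <- function(x, ...) {
  g <- raster_grid(x)
  v <- as.vector(x)
  cat(sprintf("<lapmd_raster> %d x %d @ %g m; range [%g, %g]\n",
              g$nrow, g$ncol, g$cellsize,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @rdname lapmd_raster
#' @param x a `lapmd_raster`
#' @export
raster_grid <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("object carries no grid geometry")
  g
}

#' Test whether two geometries (or rasters) describe the same grid
#' @param a,b `lapmd_grid` or `lapmd_raster` objects
#' @export
grids_congruent <- function(a, b) {
  ga <- if (inherits(a, "lapmd_raster")) raster_grid(a) else a
  gb <- if (inherits(b, "lapmd_raster")) raster_grid(b) else b
  isTRUE(ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
           all.equal(ga$cellsize, gb$cellsize) == TRUE &&
           all.equal(ga$xll, gb$xll) == TRUE &&
           all.equal(ga$yll, gb$yll) == TRUE)
}

stop_unless_congruent <- function(a, b, what = "rasters") {
  if (!grids_congruent(a, b))
    stop(sprintf("grid geometry mismatch: %s must share one geometry", what))
  invisible(TRUE)
}

#' Cell-centre coordinates of every cell
#'
#' @param grid a [lapmd_grid()]
#' @return list with matrices `x` (easting) and `y` (northing), both
#'   `nrow` x `ncol`; row 1 holds the northernmost centres
#' @export
cell_centers <- function(grid) {
  cs <- grid$cellsize
  xs <- grid$xll + (seq_len(grid$ncol) - 0.5) * cs
  ys <- grid$yll + (grid$nrow - seq_len(grid$nrow) + 0.5) * cs
  list(x = matrix(xs, grid$nrow, grid$ncol, byrow = TRUE),
       y = matrix(ys, grid$nrow, grid$ncol, byrow = FALSE))
}

#' Cell area in hectares
#'
#' One hectare (hm^2) is 10,000 m^2; a 300 m cell is 9 hm^2.
#' @param grid a [lapmd_grid()]
#' @export
cell_area_hm2 <- function(grid) grid$cellsize^2 / 1e4

#' Read an ESRI ASCII grid (.asc)
#'
#' Plain-text raster interchange format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' whitespace-separated cell values, first row = north edge.
#'
#' @param path file path
#' @return a [lapmd_raster()]; NODATA cells become `NA`
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) in ", path)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ESRI ASCII grid body has wrong cell count in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  lapmd_raster(m, lapmd_grid(hdr$nrows, hdr$ncols, hdr$cellsize,
                             hdr$xllcorner, hdr$yllcorner))
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param x a [lapmd_raster()]
#' @param path destination path
#' @param nodata value written for `NA` cells
#' @param digits significant digits for fractional values (whole numbers
#'   are always written exactly)
#' @export
write_asc <- function(x, path, nodata = -9999, digits = 10) {
  g <- raster_grid(x)
  m <- unclass(x)
  attr(m, "grid") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$ncol),
               sprintf("nrows %d", g$nrow),
               sprintf("xllcorner %.6f", g$xll),
               sprintf("yllcorner %.6f", g$yll),
               sprintf("cellsize %.6f", g$cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  body <- apply(m, 1L, function(r) {
    s <- formatC(r, digits = digits, format = "g")
    # whole numbers (categorical codes, counts) are written exactly,
    # untouched by the digits setting; so is the NODATA marker
    whole <- is.finite(r) & r == round(r)
    s[whole] <- format(r[whole], scientific = FALSE, trim = TRUE)
    s[is.na(r)] <- format(nodata)
    paste(s, collapse = " ")
  })
  writeLines(body, con)
  invisible(path)
}
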