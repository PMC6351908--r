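# Small in-code builders shared across test files.

# A wind rose with explicit per-sector values, bypassing daily records.
manual_rose <- function(freq, mean_speed = rep(3, 8),
                        stability = rep("D", 8)) {
  defs <- sector_definitions()
  structure(data.frame(sector = defs$sector, name = defs$name,
                       lower = defs$lower, upper = defs$upper,
                       freq = freq, mean_speed = mean_speed,
                       stability = stability),
            class = c("lapmd_wind_rose", "data.frame"))
}

# A flat source field with emissions at chosen cells.
flat_source_field <- function(nrow, ncol, cellsize = 300,
                              cells = list(), delta_h = 0, elevation = 0) {
  g <- lapmd_grid(nrow, ncol, cellsize)
  q <- matrix(0, nrow, ncol)
  dh <- matrix(delta_h, nrow, ncol)
  el <- matrix(elevation, nrow, ncol)
  for (cl in cells) {
    q[cl$row, cl$col] <- cl$q
    if (!is.null(cl$delta_h)) dh[cl$row, cl$col] <- cl$delta_h
  }
  source_field(lapmd_raster(q, g), lapmd_raster(dh, g), lapmd_raster(el, g))
}

# Daily records with one day per sector centre, all above calm threshold.
one_day_per_sector <- function(speed = 3) {
  data.frame(wind_dir_deg = seq(0, 315, by = 45), wind_speed_ms = speed,
             cloud_frac = 0.5)
}
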