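# Independent brute-force re-evaluation of the sector-averaged long-term
# model: plain scalar loops over every source-receptor pair with its own
# sector assignment and its own arithmetic, kept deliberately separate
# from the package's vectorized engine.

oracle_sector_of <- function(wind_from) {
  wind_from <- wind_from %% 360
  bounds <- cbind(lower = (seq(0, 315, 45) - 22.5) %% 360,
                  upper = seq(0, 315, 45) + 22.5)
  for (s in 1:8) {
    lo <- bounds[s, 1]; up <- bounds[s, 2]
    inside <- if (lo > up %% 360) {           # the north sector wraps 360
      wind_from > lo || wind_from <= up %% 360
    } else {
      wind_from > lo && wind_from <= up
    }
    if (inside) return(s)
  }
  stop("no sector found")                     # unreachable
}

oracle_disperse <- function(sf, rose, attenuation = 1, min_d = NULL,
                            coefs = sigma_coefficients(),
                            height_convention = "absolute") {
  grid <- sf$grid
  cs <- grid$cellsize
  if (is.null(min_d)) min_d <- cs / 2
  q <- matrix(as.numeric(sf$q), grid$nrow, grid$ncol)
  dH <- matrix(as.numeric(sf$delta_h), grid$nrow, grid$ncol)
  H <- matrix(as.numeric(sf$elevation), grid$nrow, grid$ncol)
  out <- matrix(0, grid$nrow, grid$ncol)
  seconds <- 3.1536e7
  for (sr in seq_len(grid$nrow)) for (sc in seq_len(grid$ncol)) {
    if (q[sr, sc] <= 0) next
    q_gs <- q[sr, sc] * 1e6 / seconds
    for (rr in seq_len(grid$nrow)) for (rc in seq_len(grid$ncol)) {
      dxe <- (rc - sc) * cs
      dyn <- (sr - rr) * cs
      dist <- sqrt(dxe^2 + dyn^2)
      h <- if (height_convention == "absolute") {
        dH[sr, sc] + H[sr, sc]
      } else {
        max(dH[sr, sc] + H[sr, sc] - H[rr, rc], dH[sr, sc])
      }
      if (dist == 0) {
        # self cell: min-distance evaluation summed across all sectors
        for (s in 1:8) {
          if (rose$freq[s] <= 0) next
          k <- match(rose$stability[s], coefs$class)
          sy <- coefs$a_y[k] * (min_d / 1000)^coefs$b_y[k]
          sz <- coefs$a_z[k] * (min_d / 1000)^coefs$b_z[k]
          out[rr, rc] <- out[rr, rc] +
            1000 * q_gs * rose$freq[s] /
            (2 * pi * rose$mean_speed[s] * sy * sz) *
            exp(-h^2 / (2 * sz^2)) / (pi * min_d * 45 / 180) * attenuation
        }
        next
      }
      bearing <- (atan2(dxe, dyn) * 180 / pi) %% 360
      s <- oracle_sector_of(bearing + 180)
      if (rose$freq[s] <= 0) next
      x <- max(dist, min_d)
      k <- match(rose$stability[s], coefs$class)
      sy <- coefs$a_y[k] * (x / 1000)^coefs$b_y[k]
      sz <- coefs$a_z[k] * (x / 1000)^coefs$b_z[k]
      out[rr, rc] <- out[rr, rc] +
        1000 * q_gs * rose$freq[s] /
        (2 * pi * rose$mean_speed[s] * sy * sz) *
        exp(-h^2 / (2 * sz^2)) / (pi * x * 45 / 180) * attenuation
    }
  }
  out
}
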