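#' Settings for the long-term multi-source dispersion run
#'
#' @param attenuation dimensionless scalar decay factor T >= 0 applied to
#'   every concentration (pollutant-specific; 1 = no decay)
#' @param min_distance floor on the source-receptor distance in metres;
#'   `NULL` defaults to half the cell size at run time
#' @param height_convention `"absolute"` uses the effective height
#'   delta H + H (stack height plus ground elevation above sea level);
#'   `"relative"` uses delta H + H_source - H_receptor, floored at
#'   delta H, so that sources and receptors on a common plateau behave as
#'   at sea level
#' @param self_cell `"min_distance"` evaluates a source's own cell at the
#'   distance floor (summing over all sectors with their frequencies);
#'   `"zero"` leaves the self cell without a self contribution
#' @return list of class `lapmd_settings`
#' @export
dispersion_settings <- function(attenuation = 1, min_distance = NULL,
                                height_convention = c("absolute", "relative"),
                                self_cell = c("min_distance", "zero")) {
  if (attenuation < 0) stop("attenuation T must be >= 0")
  if (!is.null(min_distance) && min_distance <= 0)
    stop("min_distance must be > 0")
  structure(list(attenuation = attenuation, min_distance = min_distance,
                 height_convention = match.arg(height_convention),
                 self_cell = match.arg(self_cell)),
            class = "lapmd_settings")
}

#' Convert an annual emission to an emission rate
#'
#' Uses 3.1536e7 seconds per year. This is the single unit bridge between
#' the inventory (ton/yr) and the plume kernel (g/s).
#'
#' @param tons_per_year annual mass, ton/yr
#' @return rate in g/s
#' @export
tons_per_year_to_g_per_s <- function(tons_per_year)
  tons_per_year * 1e6 / 3.1536e7

#' Sector-averaged plume kernel
#'
#' Long-term concentration at downwind distance `x` from a steady source
#' whose emission is smeared uniformly over one wind sector:
#' \deqn{c = \frac{Q}{2\pi \bar u \sigma_y \sigma_z}
#'   \exp\!\left(-\frac{h^2}{2\sigma_z^2}\right)
#'   \Big/ \frac{\pi x (\alpha_2-\alpha_1)}{180} \times T}
#' where the divisor is the arc width of the sector at distance `x`. Units
#' follow the inputs: with `q_rate` in mass/s and metres throughout, the
#' result is mass/m^3.
#'
#' @param q_rate sector emission rate (source rate times sector frequency),
#'   mass/s
#' @param u sector mean wind speed, m/s (> 0)
#' @param sigma_y,sigma_z dispersion parameters at `x`, m (> 0)
#' @param h_eff effective source height, m
#' @param x downwind distance, m (> 0)
#' @param sector_width sector angular width in degrees
#' @param attenuation scalar decay factor T
#' @return concentration in mass/m^3 (vectorized)
#' @export
sector_plume <- function(q_rate, u, sigma_y, sigma_z, h_eff, x,
                         sector_width = 45, attenuation = 1) {
  if (any(u <= 0)) stop("wind speed must be > 0 (calm is handled upstream)")
  if (any(x <= 0)) stop("downwind distance must be > 0")
  if (any(sigma_y <= 0) || any(sigma_z <= 0)) stop("sigma must be > 0")
  arc <- pi * x * sector_width / 180
  q_rate / (2 * pi * u * sigma_y * sigma_z) *
    exp(-h_eff^2 / (2 * sigma_z^2)) / arc * attenuation
}

#' Sector-averaged concentration from an annual emission
#'
#' Convenience wrapper around [sector_plume()] taking the sector emission
#' in ton/yr and returning mg/m^3.
#'
#' @inheritParams sector_plume
#' @param q_tons_yr sector annual emission, ton/yr
#' @export
sector_concentration <- function(q_tons_yr, u, sigma_y, sigma_z, h_eff, x,
                                 sector_width = 45, attenuation = 1) {
  1e3 * sector_plume(tons_per_year_to_g_per_s(q_tons_yr), u,
                     sigma_y, sigma_z, h_eff, x, sector_width, attenuation)
}

#' Crosswind-integrated flux identity of the sector-averaged plume
#'
#' The sector-uniform profile integrates across the sector arc to
#' \eqn{c \cdot w} with arc width \eqn{w = \pi x (\alpha_2-\alpha_1)/180},
#' which by construction equals
#' \eqn{Q/(2\pi \bar u \sigma_y \sigma_z)\exp(-h^2/2\sigma_z^2)\,T}.
#' Exposed as a verification utility for the crosswind mass bookkeeping.
#'
#' @inheritParams sector_plume
#' @return list with `concentration`, `arc_width`, `flux` (= c * w) and
#'   `rhs` (the closed-form crosswind integral)
#' @export
crosswind_integral_check <- function(q_rate, u, sigma_y, sigma_z, h_eff, x,
                                     sector_width = 45, attenuation = 1) {
  conc <- sector_plume(q_rate, u, sigma_y, sigma_z, h_eff, x,
                       sector_width, attenuation)
  w <- pi * x * sector_width / 180
  rhs <- q_rate / (2 * pi * u * sigma_y * sigma_z) *
    exp(-h_eff^2 / (2 * sigma_z^2)) * attenuation
  list(concentration = conc, arc_width = w, flux = conc * w, rhs = rhs)
}

#' Annual multi-source dispersion over the grid
#'
#' Superposes the sector-averaged plumes of every emitting cell. Each
#' source's annual emission Q is split across the eight wind sectors by
#' the rose frequencies; a receptor lies downwind of a source through
#' exactly one sector - the one whose from-direction is opposite the
#' source-to-receptor bearing - and receives
#' [sector_concentration()] evaluated at the source-receptor cell-centre
#' distance with that sector's mean speed and stability-class dispersion
#' coefficients.
#'
#' @param sources a `lapmd_source_field` from [rasterize_emissions()]
#' @param rose a `lapmd_wind_rose` carrying a `stability` column (or pass
#'   `stability` explicitly)
#' @param settings a [dispersion_settings()]
#' @param coefs dispersion-coefficient table, see [sigma_coefficients()]
#' @param stability optional length-8 character vector overriding the
#'   rose's per-sector stability classes
#' @return annual mean near-ground concentration as a [lapmd_raster()]
#'   in mg/m^3
#' @export
disperse <- function(sources, rose, settings = dispersion_settings(),
                     coefs = sigma_coefficients(), stability = NULL) {
  if (!inherits(sources, "lapmd_source_field"))
    stop("sources must be a lapmd_source_field")
  grid <- sources$grid
  stop_unless_congruent(sources$q, sources$elevation, "source-field rasters")
  if (abs(sum(rose$freq) - 1) > 1e-9)
    stop("wind-rose frequencies must sum to 1")
  stab <- stability %||% rose$stability
  if (is.null(stab))
    stop("per-sector stability classes are required (rose$stability)")
  stab <- rep_len(stab, 8)
  min_d <- settings$min_distance %||% (grid$cellsize / 2)
  cc <- cell_centers(grid)
  q <- unclass_matrix(sources$q)
  dH <- unclass_matrix(sources$delta_h)
  elev <- unclass_matrix(sources$elevation)
  width <- 45
  ay <- coefs$a_y[match(stab, coefs$class)]
  by <- coefs$b_y[match(stab, coefs$class)]
  az <- coefs$a_z[match(stab, coefs$class)]
  bz <- coefs$b_z[match(stab, coefs$class)]
  if (any(is.na(ay))) stop("unknown stability class in rose")
  conc <- matrix(0, grid$nrow, grid$ncol)
  src_idx <- which(q > 0)
  for (i in src_idx) {
    q_gs <- tons_per_year_to_g_per_s(q[i])
    h_src <- dH[i] + elev[i]
    dx <- cc$x - cc$x[i]
    dy <- cc$y - cc$y[i]
    dist <- sqrt(dx^2 + dy^2)
    bearing <- (atan2(dx, dy) * 180 / pi) %% 360
    sec_rec <- sector_index((bearing + 180) %% 360)
    h_vec <- if (settings$height_convention == "absolute") {
      h_src
    } else {
      pmax(dH[i] + elev[i] - elev, dH[i])
    }
    for (s in 1:8) {
      if (rose$freq[s] <= 0) next
      sel <- sec_rec == s & dist > 0
      if (!any(sel)) next
      x <- pmax(dist[sel], min_d)
      xk <- x / 1000
      sy <- ay[s] * xk^by[s]
      sz <- az[s] * xk^bz[s]
      h <- if (length(h_vec) == 1) h_vec else h_vec[sel]
      conc[sel] <- conc[sel] + 1e3 * sector_plume(
        q_gs * rose$freq[s], rose$mean_speed[s], sy, sz, h, x,
        width, settings$attenuation)
    }
    if (settings$self_cell == "min_distance") {
      x <- min_d
      xk <- x / 1000
      h <- if (length(h_vec) == 1) h_vec else h_vec[i]
      for (s in 1:8) {
        if (rose$freq[s] <= 0) next
        sy <- ay[s] * xk^by[s]
        sz <- az[s] * xk^bz[s]
        conc[i] <- conc[i] + 1e3 * sector_plume(
          q_gs * rose$freq[s], rose$mean_speed[s], sy, sz, h, x,
          width, settings$attenuation)
      }
    }
  }
  lapmd_raster(conc, grid)
}
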