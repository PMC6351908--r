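#' Eight-sector compass definitions
#'
#' Sectors span 45 degrees and are centred on the eight principal compass
#' points, sector 1 on north (337.5-22.5 degrees). Intervals are
#' `(lower, upper]`: a direction exactly on a boundary joins the
#' lower-angle sector, so 22.5 stays in sector 1 and 337.5 in sector 8.
#' Directions are where the wind blows FROM; transport is toward the
#' opposite bearing.
#'
#' @return data frame with `sector`, `name`, `center`, `lower`, `upper`
#' @export
sector_definitions <- function() {
  center <- seq(0, 315, by = 45)
  data.frame(sector = 1:8,
             name = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
             center = center,
             lower = (center - 22.5) %% 360,
             upper = center + 22.5)
}

#' Sector index of a wind direction
#'
#' @param deg direction(s) in degrees; any real number (reduced mod 360)
#' @return integer sector index in 1..8 (vectorized)
#' @export
sector_index <- function(deg) {
  shift <- (deg + 22.5) %% 360
  idx <- ceiling(shift / 45)
  idx[idx < 1L] <- 8L          # boundary at 337.5 joins the NW sector
  as.integer(idx)
}

#' Build an annual wind rose from daily records
#'
#' Non-calm days (speed >= `calm_threshold`) are binned into the eight
#' 45-degree sectors by the direction the wind blows from; each sector's
#' frequency is its share of non-calm days and its mean speed the average
#' daily speed of those days. If the records carry cloud cover and solar
#' elevation (or a date from which noon elevation can be computed given
#' `latitude`), each sector is also assigned its annual-representative
#' Pasquill stability class: the modal daily class among its days.
#'
#' @param records data frame with columns `wind_dir_deg`, `wind_speed_ms`
#'   and optionally `cloud_frac` and `solar_elev_deg` or `date`
#' @param calm_threshold m/s; slower days are excluded and reported as the
#'   calm fraction
#' @param equal_freq if `TRUE` force every sector frequency to 1/8 while
#'   keeping the data-driven mean speeds (uniform-rose assumption)
#' @param latitude degrees north, used only to derive solar elevation from
#'   `date` when `solar_elev_deg` is absent
#' @return data frame of class `lapmd_wind_rose` with columns `sector`,
#'   `name`, `lower`, `upper`, `freq`, `mean_speed` and (when derivable)
#'   `stability`; attributes `calm_fraction` and `n_days`
#' @export
build_wind_rose <- function(records, calm_threshold = 0.5,
                            equal_freq = FALSE, latitude = 35) {
  if (!all(c("wind_dir_deg", "wind_speed_ms") %in% names(records)))
    stop("records need wind_dir_deg and wind_speed_ms columns")
  if (any(records$wind_speed_ms < 0)) stop("wind speeds must be >= 0")
  dir <- records$wind_dir_deg %% 360
  calm <- records$wind_speed_ms < calm_threshold
  if (all(calm)) stop("all records are calm; cannot build a wind rose")
  use <- !calm
  sec <- sector_index(dir[use])
  spd <- records$wind_speed_ms[use]
  defs <- sector_definitions()
  n <- tabulate(sec, nbins = 8L)
  freq <- n / sum(n)
  mean_speed <- vapply(1:8, function(s) {
    if (n[s] > 0) mean(spd[sec == s]) else mean(spd)
  }, numeric(1))
  if (equal_freq) freq <- rep(1 / 8, 8)
  rose <- data.frame(sector = defs$sector, name = defs$name,
                     lower = defs$lower, upper = defs$upper,
                     freq = freq, mean_speed = mean_speed)
  cls <- daily_stability(records, latitude = latitude)
  if (!is.null(cls)) {
    cls_use <- cls[use]
    rose$stability <- vapply(1:8, function(s) {
      x <- cls_use[sec == s]
      if (!length(x)) x <- cls_use
      names(which.max(table(factor(x, levels = LETTERS[1:6]))))
    }, character(1))
  }
  structure(rose, class = c("lapmd_wind_rose", "data.frame"),
            calm_fraction = mean(calm), n_days = nrow(records))
}

daily_stability <- function(records, latitude) {
  if (!"cloud_frac" %in% names(records)) return(NULL)
  elev <- records$solar_elev_deg
  if (is.null(elev)) {
    if (!"date" %in% names(records)) return(NULL)
    elev <- solar_noon_elevation(records$date, latitude)
  }
  stability_class(records$wind_speed_ms, elev, records$cloud_frac)
}

#' Solar elevation at local noon
#'
#' Noon elevation = 90 - |latitude - declination| with the usual
#' small-angle declination approximation
#' \eqn{\delta = 23.44 \sin(2\pi (284 + doy)/365)}. Adequate for banding
#' insolation into the broad stability-scheme categories.
#'
#' @param date Date vector (or coercible)
#' @param latitude degrees north
#' @return elevation in degrees
#' @export
solar_noon_elevation <- function(date, latitude) {
  doy <- as.integer(format(as.Date(date), "%j"))
  decl <- 23.44 * sin(2 * pi * (284 + doy) / 365)
  90 - abs(latitude - decl)
}

#' Pasquill atmospheric stability class
#'
#' Classic surface-observation scheme: daytime insolation is banded by
#' solar elevation (strong > 60, moderate 35-60, slight 15-35 degrees);
#' elevation below 15 degrees or cloud cover of 7/8 and above gives
#' neutral D, and cloud of 3/4 and above knocks the insolation down one
#' band. Night (elevation <= 0) splits at 4/8 cloud. Split entries of the
#' published table (A-B, B-C, C-D) resolve to the more unstable member;
#' the rarely used night class G is reported as F.
#'
#' @param wind_speed 10-m wind speed, m/s
#' @param solar_elev solar elevation, degrees (<= 0 means night)
#' @param cloud_frac total cloud cover as a fraction in `[0, 1]`
#' @return character vector of classes `"A"` to `"F"` (vectorized)
#' @export
stability_class <- function(wind_speed, solar_elev, cloud_frac) {
  if (any(is.na(wind_speed)) || any(is.na(solar_elev)) ||
      any(is.na(cloud_frac)))
    stop("wind_speed, solar_elev and cloud_frac must all be present")
  check_fraction(cloud_frac, "cloud_frac")
  n <- max(length(wind_speed), length(solar_elev), length(cloud_frac))
  u <- rep_len(wind_speed, n)
  el <- rep_len(solar_elev, n)
  cl <- rep_len(cloud_frac, n)
  band <- findInterval(u, c(2, 3, 5, 6)) + 1L  # 1:<2, 2:2-3, 3:3-5, 4:5-6, 5:>=6
  day_tab <- rbind(strong   = c("A", "A", "B", "C", "C"),
                   moderate = c("A", "B", "B", "C", "D"),
                   slight   = c("B", "C", "C", "D", "D"))
  night_cloudy <- c("E", "E", "D", "D", "D")
  night_clear  <- c("F", "F", "E", "D", "D")
  out <- character(n)
  for (i in seq_len(n)) {
    if (el[i] <= 0) {
      out[i] <- if (cl[i] >= 0.5) night_cloudy[band[i]] else night_clear[band[i]]
    } else if (el[i] < 15 || cl[i] >= 7 / 8) {
      out[i] <- "D"
    } else {
      ins <- if (el[i] > 60) 1L else if (el[i] > 35) 2L else 3L
      if (cl[i] >= 0.75) ins <- min(ins + 1L, 3L)
      out[i] <- day_tab[ins, band[i]]
    }
  }
  out
}

#' Pasquill-Gifford power-law dispersion coefficients
#'
#' Power-law fits \eqn{\sigma = a (x/1000)^b} (x in metres, sigma in
#' metres) to the Pasquill-Gifford curves, one row per stability class
#' A-F. The lateral coefficients use the common single-exponent fit
#' (b = 0.894 for all classes); the vertical ones are the mid-range
#' (around 1 km) fits with the small additive offsets dropped so the pure
#' power-law form holds. Valid roughly over 0.1-10 km, which covers the
#' source-receptor distances of a city-scale grid. Pass an edited copy to
#' [sigma_yz()] or [disperse()] to swap in another coefficient set.
#'
#' @return data frame with columns `class`, `a_y`, `b_y`, `a_z`, `b_z`
#' @export
sigma_coefficients <- function() {
  data.frame(class = LETTERS[1:6],
             a_y = c(213, 156, 104, 68, 50.5, 34),
             b_y = rep(0.894, 6),
             a_z = c(440.8, 106.6, 61, 33.2, 22.8, 14.35),
             b_z = c(1.941, 1.149, 0.911, 0.725, 0.678, 0.740))
}

#' Dispersion parameters at a downwind distance
#'
#' @param x downwind distance in metres (> 0; vectorized)
#' @param stability stability class `"A"`..`"F"`
#' @param coefs coefficient table in the layout of [sigma_coefficients()]
#' @return list with `sigma_y` and `sigma_z` in metres
#' @export
sigma_yz <- function(x, stability, coefs = sigma_coefficients()) {
  if (any(x <= 0)) stop("downwind distance x must be > 0")
  row <- coefs[coefs$class == stability, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown stability class '%s'", stability))
  xk <- x / 1000
  list(sigma_y = row$a_y * xk^row$b_y,
       sigma_z = row$a_z * xk^row$b_z)
}

#' @export
print.lapmd_wind_rose <- function(x, ...) {
  cat(sprintf("<lapmd_wind_rose> %d days, calm fraction %.3f\n",
              attr(x, "n_days") %||% NA_integer_,
              attr(x, "calm_fraction") %||% NA_real_))
  print.data.frame(cbind(x[, c("sector", "name")],
                         round(x[, c("freq", "mean_speed")], 3),
                         if ("stability" %in% names(x))
                           x[, "stability", drop = FALSE]),
                   row.names = FALSE)
  invisible(x)
}
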