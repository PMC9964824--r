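#' Sunrise and sunset times
#'
#' Computes local sunrise and sunset with the standard solar-position
#' algorithm (fractional-year series for declination and the equation of
#' time, hour angle at solar altitude -0.833 deg to account for refraction
#' and the solar disc). Accurate to about +/-3 minutes at low latitudes,
#' which is immaterial against hourly wind data.
#'
#' @param latitude Degrees north; must satisfy `|latitude| < 66`.
#' @param longitude Degrees east.
#' @param dates Date vector.
#' @param utc_offset Local clock offset from UTC in hours.
#' @return A data frame: `date`, `sunrise`, `sunset` (POSIXct local clock),
#'   `sunrise_h`, `sunset_h` (decimal hours).
#' @export
#' @examples
#' solar_times(13.67, 100.61, as.Date("2020-03-20"), 7)
solar_times <- function(latitude, longitude, dates, utc_offset) {
  if (abs(latitude) >= 66)
    stop("solar_times supports |latitude| < 66 (no polar day/night)",
         call. = FALSE)
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  g <- 2 * pi / 365 * (doy - 1)
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- latitude * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  if (any(abs(cos_ha) > 1))
    stop("polar day or night: sun does not cross the horizon", call. = FALSE)
  ha <- acos(cos_ha) * 180 / pi
  sr <- (720 - 4 * (longitude + ha) - eqt + utc_offset * 60) / 60
  ss <- (720 - 4 * (longitude - ha) - eqt + utc_offset * 60) / 60
  midnight <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  data.frame(date = dates,
             sunrise = midnight + round(sr * 3600),
             sunset = midnight + round(ss * 3600),
             sunrise_h = sr, sunset_h = ss)
}

#' Coastal geometry for wind-sector classification
#'
#' The onshore sector collects wind-FROM directions for air arriving off the
#' sea; the offshore sector, air leaving towards the sea; the coast normal is
#' the bearing pointing inland (the direction onshore air moves TOWARD).
#' Sectors are `c(lo, hi)` in degrees and may wrap through north
#' (`lo > hi`). Defaults suit a south-facing gulf coastline: onshore
#' 135--255, offshore 315--75, coast normal 15, calm below 0.5 m s-1.
#'
#' @param onshore,offshore Sector bounds `c(lo, hi)` in degrees from north.
#' @param coast_normal_deg Inland-pointing bearing in degrees.
#' @param calm_ms Wind speeds below this are treated as calm (m s-1).
#' @return A list of class `coast_geometry`.
#' @export
coast_geometry <- function(onshore = c(135, 255), offshore = c(315, 75),
                           coast_normal_deg = 15, calm_ms = 0.5) {
  g <- list(onshore = onshore, offshore = offshore,
            coast_normal_deg = coast_normal_deg, calm_ms = calm_ms)
  if (any(in_sector(seq(0, 359), onshore) & in_sector(seq(0, 359), offshore)))
    stop("onshore and offshore sectors must be disjoint", call. = FALSE)
  structure(g, class = "coast_geometry")
}

# sector membership for wind-FROM directions, wrapping through north
in_sector <- function(wd, sector) {
  wd <- wd %% 360
  if (sector[1] <= sector[2]) wd >= sector[1] & wd <= sector[2]
  else wd >= sector[1] | wd <= sector[2]
}

# hours of a series falling in the closed time window [t0, t1]
window_idx <- function(time, t0, t1) which(time >= t0 & time <= t1)

# longest TRUE run in a logical vector; returns c(start, end) or NULL
longest_run <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  len <- r$lengths
  len[!r$values] <- 0L
  i <- which.max(len)
  c(starts[i], ends[i])
}

#' Classify sea-breeze days
#'
#' Applies four surface criteria to every requested day:
#' \describe{
#'   \item{(a)}{in the window from 6 h before to 2 h after sunrise, strictly
#'     more than half of the valid wind hours blow offshore or are calm;}
#'   \item{(b)}{between 2 h after sunrise and 2 h after sunset the wind blows
#'     onshore for at least two consecutive hours;}
#'   \item{(c)}{in the post-breeze window (default 2 h to 8 h after sunset)
#'     strictly more than half of the valid hours are offshore or calm;}
#'   \item{(d)}{mean land temperature between sunrise and sunset exceeds the
#'     day's sea-surface temperature by more than 3 degrees C.}
#' }
#' A day is a sea-breeze day when all four hold. The onshore onset, end,
#' duration and inland penetration are taken from the longest onshore run in
#' the (b) window. Days with fewer than `min_valid_frac` valid wind hours in
#' any criterion window are unclassifiable (`classifiable = FALSE`) and
#' excluded from downstream statistics.
#'
#' @param series A [station_series()] with `ws`, `wd`, `temp`.
#' @param sst Data frame `date`, `sst` (daily sea-surface temperature, C).
#' @param geometry A [coast_geometry()].
#' @param dates Days to classify; default every complete day in the series.
#' @param delta_t_min Land-sea contrast threshold, C (default 3).
#' @param c_window Post-breeze window as hours after sunset, `c(from, to)`.
#' @param min_valid_frac Minimum valid fraction of window hours.
#' @return A data frame of class `sea_breeze_days`: `date`, `classifiable`,
#'   `crit_a`..`crit_d`, `is_sb`, `onset`, `end`, `duration_h`,
#'   `penetration_km`, `delta_t`.
#' @export
classify_sea_breeze <- function(series, sst, geometry = coast_geometry(),
                                dates = NULL, delta_t_min = 3,
                                c_window = c(2, 8), min_valid_frac = 0.75) {
  stopifnot(inherits(series, "station_series"),
            all(c("date", "sst") %in% names(sst)))
  if (is.null(dates)) {
    dates <- sort(unique(as.Date(format(series$time, "%Y-%m-%d"))))
    dates <- dates[dates > min(dates) & dates < max(dates)]  # need margins
  }
  sun <- solar_times(series$meta$latitude, series$meta$longitude, dates,
                     series$meta$utc_offset)
  uv <- wind_to_uv(series$values$ws, series$values$wd)
  calm <- !is.na(series$values$ws) & series$values$ws < geometry$calm_ms
  onsh <- !is.na(series$values$wd) & !is.na(series$values$ws) &
    in_sector(series$values$wd, geometry$onshore) & !calm
  offsh <- !is.na(series$values$wd) & !is.na(series$values$ws) &
    in_sector(series$values$wd, geometry$offshore) & !calm
  wind_ok <- !is.na(series$values$ws) & !is.na(series$values$wd)

  majority_offshore <- function(idx) {
    nv <- sum(wind_ok[idx])
    if (length(idx) == 0L || nv / length(idx) < min_valid_frac)
      return(NA)
    sum((offsh | calm)[idx]) > nv / 2
  }

  res <- lapply(seq_along(dates), function(i) {
    sr <- sun$sunrise[i]
    ss <- sun$sunset[i]
    ia <- window_idx(series$time, sr - 6 * 3600, sr + 2 * 3600)
    ib <- window_idx(series$time, sr + 2 * 3600, ss + 2 * 3600)
    ic <- window_idx(series$time, ss + c_window[1] * 3600,
                     ss + c_window[2] * 3600)
    id <- window_idx(series$time, sr, ss)
    a <- majority_offshore(ia)
    cc <- majority_offshore(ic)
    b_ok <- length(ib) > 0L &&
      sum(wind_ok[ib]) / length(ib) >= min_valid_frac
    run <- if (b_ok) longest_run(onsh[ib]) else NULL
    b <- if (!b_ok) NA else (!is.null(run) && run[2] - run[1] + 1L >= 2L)
    land_t <- mean(series$values$temp[id], na.rm = TRUE)
    sst_i <- sst$sst[match(dates[i], as.Date(sst$date))]
    dT <- land_t - sst_i
    d <- if (is.finite(dT)) dT > delta_t_min else NA
    classifiable <- !anyNA(c(a, b, cc, d))
    onset <- end <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
    dur <- pen <- NA_real_
    if (!is.null(run) && run[2] - run[1] + 1L >= 2L) {
      ridx <- ib[run[1]:run[2]]
      onset <- series$time[ridx[1]]
      end <- series$time[ridx[length(ridx)]]
      dur <- length(ridx)
      pen <- sb_penetration(uv$u[ridx], uv$v[ridx], geometry$coast_normal_deg)
    }
    data.frame(date = dates[i], classifiable = classifiable,
               crit_a = a, crit_b = b, crit_c = cc, crit_d = d,
               is_sb = classifiable && isTRUE(a) && isTRUE(b) &&
                 isTRUE(cc) && isTRUE(d),
               onset = onset, end = end, duration_h = dur,
               penetration_km = pen, delta_t = dT)
  })
  out <- do.call(rbind, res)
  class(out) <- c("sea_breeze_days", "data.frame")
  out
}

#' Inland penetration of an onshore run
#'
#' Cumulative inland displacement of the sea-breeze front, estimated as the
#' sum over the run's hours of the positive part of the hourly wind vector
#' projected on the inland coast normal, converted to km (1 m s-1 sustained
#' for an hour is 3.6 km).
#'
#' @param u,v Hourly east/north wind components (m s-1) over the run.
#' @param coast_normal_deg Inland-pointing bearing, degrees.
#' @return Penetration distance in km (non-negative).
#' @export
sb_penetration <- function(u, v, coast_normal_deg) {
  rad <- coast_normal_deg * pi / 180
  proj <- u * sin(rad) + v * cos(rad)
  sum(pmax(0, proj), na.rm = TRUE) * 3600 / 1000
}

# core recirculation arithmetic on hourly components (t_hours per sample):
# net displacement over total wind run, subtracted from one
recirculation_from_uv <- function(u, v, t_hours = 1) {
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]
  v <- v[ok]
  km <- t_hours * 3.6  # km travelled per (m s-1) per sample
  X <- km * sum(u)
  Y <- km * sum(v)
  WR <- km * sum(sqrt(u^2 + v^2))
  rf <- if (WR > 0) 1 - sqrt(X^2 + Y^2) / WR else NA_real_
  list(X = X, Y = Y, WR = WR, RF = rf, N = length(u), T = t_hours)
}

#' Daytime wind recirculation factor
#'
#' For each day, over the daytime window (default 10:00--18:00 local, nine
#' hourly samples), computes the net east-west and north-south displacements
#' X and Y, the total wind run WR (summed hourly travel distance), and the
#' recirculation factor RF = 1 - sqrt(X^2 + Y^2) / WR. RF is 0 for
#' straight-line transport and 1 for a closed loop; it is undefined (NA) when
#' the wind run is zero or fewer than `min_valid_frac` of the window hours
#' are valid.
#'
#' @param series A [station_series()] with `ws` and `wd`.
#' @param dates Days to evaluate; default all days present.
#' @param window Inclusive local-hour window, `c(first, last)` (default
#'   `c(10, 18)`).
#' @param min_valid_frac Minimum valid fraction of window hours.
#' @return A data frame of class `recirculation`: `date`, `X`, `Y`, `WR`
#'   (km), `RF`, `N`.
#' @export
recirculation_factor <- function(series, dates = NULL, window = c(10, 18),
                                 min_valid_frac = 0.75) {
  stopifnot(inherits(series, "station_series"))
  day <- as.Date(format(series$time, "%Y-%m-%d"))
  hr <- as.integer(format(series$time, "%H"))
  if (is.null(dates)) dates <- sort(unique(day))
  uv <- wind_to_uv(series$values$ws, series$values$wd)
  n_window <- window[2] - window[1] + 1L
  res <- lapply(dates, function(d) {
    idx <- which(day == d & hr >= window[1] & hr <= window[2])
    ok <- sum(!is.na(uv$u[idx]) & !is.na(uv$v[idx]))
    if (ok < min_valid_frac * n_window)
      return(data.frame(date = d, X = NA_real_, Y = NA_real_, WR = NA_real_,
                        RF = NA_real_, N = as.integer(ok)))
    r <- recirculation_from_uv(uv$u[idx], uv$v[idx])
    data.frame(date = d, X = r$X, Y = r$Y, WR = r$WR, RF = r$RF,
               N = as.integer(r$N))
  })
  out <- do.call(rbind, res)
  class(out) <- c("recirculation", "data.frame")
  out
}
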