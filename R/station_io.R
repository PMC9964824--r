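# Recognised hourly variables and their units. Cloud cover (cc) is in tenths,
# CO in ppm, the gas-phase pollutants in ppb, pm25/pm10 in ug m-3.
HAZEMET_VARIABLES <- c("pm25", "pm10", "nox", "so2", "co", "temp", "rh",
                       "ws", "wd", "gr", "cc", "rain")

#' Station metadata
#'
#' Describes one surface monitoring station: identifier, coordinates,
#' province, siting background, and the UTC offset of its local clock
#' (local time = UTC + offset; the study region observes no daylight saving).
#'
#' @param station_id Short station identifier, e.g. `"P05"`.
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param longitude Degrees east, in `[-180, 180]`.
#' @param province Free-text province name.
#' @param background Free-text siting description (e.g. "General area").
#' @param utc_offset Hours east of UTC of the local clock (default 7).
#' @return A list of class `station_meta`.
#' @export
#' @examples
#' station_meta("P05", 13.67, 100.61, "Bangkok")
station_meta <- function(station_id, latitude, longitude, province = "",
                         background = "", utc_offset = 7) {
  stopifnot(is.character(station_id), length(station_id) == 1L)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  if (!is.finite(longitude) || longitude < -180 || longitude > 180)
    stop("longitude must lie in [-180, 180]", call. = FALSE)
  structure(list(station_id = station_id, latitude = latitude,
                 longitude = longitude, province = province,
                 background = background, utc_offset = utc_offset),
            class = "station_meta")
}

#' Construct an hourly station series
#'
#' The container every downstream stage consumes: a complete, strictly
#' increasing hourly local-time grid, a numeric data frame of variables, and a
#' parallel data frame of per-value QC flags (`"valid"`, `"missing"`,
#' `"out_of_range"`, `"gap_filled"`). Local clock times are stored as POSIXct
#' in the "UTC" timezone slot so that arithmetic is free of DST surprises.
#'
#' @param meta A [station_meta()].
#' @param time POSIXct vector, strictly increasing, on a whole-hour grid.
#' @param values Data frame of numeric columns named from the recognised
#'   variable set (pm25, pm10, nox, so2, co, temp, rh, ws, wd, gr, cc, rain).
#' @param qc Optional data frame of flag strings, same shape as `values`.
#' @return An object of class `station_series`.
#' @export
station_series <- function(meta, time, values, qc = NULL) {
  stopifnot(inherits(meta, "station_meta"), inherits(time, "POSIXct"),
            is.data.frame(values))
  if (nrow(values) != length(time))
    stop("values must have one row per timestamp", call. = FALSE)
  if (any(duplicated(time)))
    stop("duplicate timestamps in series", call. = FALSE)
  if (is.unsorted(as.numeric(time), strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  unknown <- setdiff(names(values), HAZEMET_VARIABLES)
  if (length(unknown))
    stop("unknown variable column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  values[] <- lapply(values, as.numeric)
  if (is.null(qc)) {
    qc <- as.data.frame(lapply(values, function(x)
      ifelse(is.na(x), "missing", "valid")), optional = TRUE)
  }
  stopifnot(identical(dim(qc), dim(values)))
  names(qc) <- names(values)
  structure(list(meta = meta, time = time, values = values, qc = qc),
            class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("<station_series> %s (%.2fN, %.2fE)  %d hours: %s .. %s\n",
              x$meta$station_id, x$meta$latitude, x$meta$longitude,
              length(x$time), format(min(x$time)), format(max(x$time))))
  nv <- vapply(x$values, function(v) sum(!is.na(v)), integer(1))
  cat("  variables:", paste(sprintf("%s[%d]", names(nv), nv), collapse = " "),
      "\n")
  invisible(x)
}

#' Read one station's hourly CSV
#'
#' Expects a header row with a `datetime` column (local time) plus any subset
#' of the recognised variable columns; missing values are empty fields. Rows
#' absent from the file become missing hours: the returned series always sits
#' on the complete hourly grid between the first and last timestamp.
#'
#' @param path Path to the delimited text file.
#' @param meta A [station_meta()] for the station.
#' @param datetime_format `strptime` format of the datetime column.
#' @return A [station_series()].
#' @export
read_station_csv <- function(path, meta,
                             datetime_format = "%Y-%m-%dT%H:%M:%S") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"datetime" %in% names(raw))
    stop("station CSV must have a 'datetime' column", call. = FALSE)
  tm <- as.POSIXct(raw$datetime, format = datetime_format, tz = "UTC")
  if (anyNA(tm))
    stop("unparseable datetime value(s) in ", path, call. = FALSE)
  if (any(duplicated(tm)))
    stop("duplicate timestamp(s) in ", path, call. = FALSE)
  vars <- intersect(names(raw), HAZEMET_VARIABLES)
  grid <- seq(min(tm), max(tm), by = "hour")
  idx <- match(as.numeric(grid), as.numeric(tm))
  values <- as.data.frame(lapply(raw[vars], function(col)
    as.numeric(col)[idx]), optional = TRUE)
  names(values) <- vars
  station_series(meta, grid, values)
}

#' Write a station series back to CSV
#'
#' Inverse of [read_station_csv()]: one row per grid hour, missing values as
#' empty fields. Round-tripping preserves finite values bit-identically.
#'
#' @param series A [station_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(series, path) {
  fmt <- lapply(series$values, function(x) {
    s <- formatC(x, digits = 17, format = "g")  # round-trips doubles exactly
    s[is.na(x)] <- ""
    s
  })
  out <- data.frame(datetime = format(series$time, "%Y-%m-%dT%H:%M:%S"),
                    fmt, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Default quality-control ranges
#'
#' Closed probable-range intervals per variable used to screen suspicious
#' values: pm25/pm10 0--1000 ug m-3, nox/so2 0--1000 ppb, co 0--100 ppm,
#' temp -5--50 C, rh 0--100 %, ws 0--50 m s-1, wd 0--360 deg, rain 0--1000
#' mm h-1, gr 0--1000 W m-2, cc 0--10 tenths.
#'
#' @return Named list of `c(lower, upper)` vectors.
#' @export
qc_ranges <- function() {
  list(pm25 = c(0, 1000), pm10 = c(0, 1000), nox = c(0, 1000),
       so2 = c(0, 1000), co = c(0, 100), temp = c(-5, 50), rh = c(0, 100),
       ws = c(0, 50), wd = c(0, 360), rain = c(0, 1000), gr = c(0, 1000),
       cc = c(0, 10))
}

#' Range-screen a station series
#'
#' Values outside their closed probable-range interval are flagged
#' `out_of_range` and masked (set missing) for all computation; in-range
#' values are untouched. Screening never fails and is idempotent.
#'
#' @param series A [station_series()].
#' @param ranges Named list of `c(lower, upper)`; see [qc_ranges()].
#' @param quiet Suppress the per-variable masking log message.
#' @return The screened [station_series()].
#' @export
apply_qc <- function(series, ranges = qc_ranges(), quiet = FALSE) {
  n_masked <- integer(0)
  for (v in names(series$values)) {
    r <- ranges[[v]]
    if (is.null(r))
      stop("no QC range supplied for variable '", v, "'", call. = FALSE)
    x <- series$values[[v]]
    bad <- !is.na(x) & (x < r[1] | x > r[2])
    if (any(bad)) {
      series$values[[v]][bad] <- NA_real_
      series$qc[[v]][bad] <- "out_of_range"
      n_masked[v] <- sum(bad)
    }
  }
  if (!quiet && length(n_masked))
    message("apply_qc [", series$meta$station_id, "]: masked ",
            paste(sprintf("%s=%d", names(n_masked), n_masked),
                  collapse = ", "))
  series
}

# wd is the meteorological direction the wind blows FROM; u,v point TOWARD
# the direction the air moves (u east, v north).
wind_to_uv <- function(ws, wd) {
  rad <- wd * pi / 180
  list(u = -ws * sin(rad), v = -ws * cos(rad))
}

uv_to_wind <- function(u, v) {
  ws <- sqrt(u^2 + v^2)
  wd <- (atan2(-u, -v) * 180 / pi) %% 360
  wd[ws == 0] <- 0
  list(ws = ws, wd = wd)
}

#' Gap-fill wind from a donor station
#'
#' Fills missing wind hours in `target` using a neighbouring `donor` station
#' that shares the time grid. Wind is first converted to east/north components
#' (regressing components rather than speed/direction avoids circular-variable
#' artifacts); separate least-squares fits of target-u on donor-u and target-v
#' on donor-v over overlapping valid hours predict the missing target hours
#' where the donor is valid. Remaining short gaps (at most `max_interp_gap`
#' hours) are closed by linear interpolation in u,v. Filled values are flagged
#' `gap_filled`; hours already valid are never altered.
#'
#' @param target,donor [station_series()] objects on the same grid with
#'   `ws`/`wd` columns.
#' @param min_overlap Minimum overlapping valid wind hours for the fits.
#' @param max_interp_gap Longest interior gap (hours) closed by interpolation.
#' @return `target` with wind gaps filled.
#' @export
gap_fill_wind_from_donor <- function(target, donor, min_overlap = 48,
                                     max_interp_gap = 3) {
  stopifnot(inherits(target, "station_series"),
            inherits(donor, "station_series"))
  if (!identical(as.numeric(target$time), as.numeric(donor$time)))
    stop("target and donor must share a time grid", call. = FALSE)
  tv <- wind_to_uv(target$values$ws, target$values$wd)
  dv <- wind_to_uv(donor$values$ws, donor$values$wd)
  ok_t <- !is.na(tv$u) & !is.na(tv$v)
  ok_d <- !is.na(dv$u) & !is.na(dv$v)
  overlap <- ok_t & ok_d
  if (sum(overlap) < min_overlap)
    stop("insufficient donor overlap: ", sum(overlap), " valid hours (need ",
         min_overlap, ")", call. = FALSE)
  fit_u <- stats::lm(y ~ x, data.frame(y = tv$u[overlap], x = dv$u[overlap]))
  fit_v <- stats::lm(y ~ x, data.frame(y = tv$v[overlap], x = dv$v[overlap]))
  u <- tv$u
  v <- tv$v
  fill <- !ok_t & ok_d
  u[fill] <- stats::predict(fit_u, data.frame(x = dv$u[fill]))
  v[fill] <- stats::predict(fit_v, data.frame(x = dv$v[fill]))
  # isolated leftover gaps: linear interpolation in components
  interp <- is.na(u)
  u <- zoo::na.approx(u, na.rm = FALSE, maxgap = max_interp_gap)
  v <- zoo::na.approx(v, na.rm = FALSE, maxgap = max_interp_gap)
  interp <- interp & !is.na(u) & !is.na(v)
  filled <- (fill | interp)
  w <- uv_to_wind(u, v)
  target$values$ws[filled] <- w$ws[filled]
  target$values$wd[filled] <- w$wd[filled]
  target$qc$ws[filled] <- "gap_filled"
  target$qc$wd[filled] <- "gap_filled"
  target
}

#' Daily aggregation of an hourly series
#'
#' Computes the mean of each variable over the valid hours of every local
#' calendar day. A daily mean is reported only when the day's completeness
#' (valid hours / 24) reaches `min_completeness`; the default 0.75 requires
#' 18 valid hours.
#'
#' @param series A [station_series()].
#' @param min_completeness Fraction in (0, 1]; default 0.75.
#' @return A data frame with columns `date`, `station_id`, `variable`,
#'   `mean`, `n_valid`, `completeness`.
#' @export
daily_aggregate <- function(series, min_completeness = 0.75) {
  stopifnot(min_completeness > 0, min_completeness <= 1)
  day <- as.Date(format(series$time, "%Y-%m-%d"))
  out <- lapply(names(series$values), function(v) {
    x <- series$values[[v]]
    n_valid <- tapply(!is.na(x), day, sum)
    m <- tapply(x, day, function(z) mean(z, na.rm = TRUE))
    comp <- as.numeric(n_valid) / 24
    m <- ifelse(comp >= min_completeness & is.finite(m), m, NA_real_)
    data.frame(date = as.Date(names(n_valid)),
               station_id = series$meta$station_id, variable = v,
               mean = as.numeric(m), n_valid = as.integer(n_valid),
               completeness = comp, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res[order(res$date, res$variable), , drop = FALSE]
}

#' Daily means of one variable across stations, in wide form
#'
#' Convenience pivot of [daily_aggregate()] output: one row per date, one
#' column per station, values are the daily means of `variable`.
#'
#' @param daily Row-bound [daily_aggregate()] output for several stations.
#' @param variable Variable to extract (default `"pm25"`).
#' @return A data frame with `date` plus one numeric column per station.
#' @export
daily_wide <- function(daily, variable = "pm25") {
  d <- daily[daily$variable == variable, c("date", "station_id", "mean")]
  stations <- sort(unique(d$station_id))
  dates <- sort(unique(d$date))
  wide <- data.frame(date = dates)
  for (s in stations) {
    ds <- d[d$station_id == s, ]
    wide[[s]] <- ds$mean[match(dates, ds$date)]
  }
  wide
}
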