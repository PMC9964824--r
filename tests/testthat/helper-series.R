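# Builders for small in-code fixtures.

bkk_meta <- function(id = "T01") station_meta(id, 13.67, 100.61, "Bangkok")

# hourly series from a named list of value vectors, starting at `start`
make_series <- function(values, start = "2022-01-01 00:00:00",
                        meta = bkk_meta()) {
  n <- length(values[[1]])
  time <- seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
  station_series(meta, time, as.data.frame(values))
}

# n full days of constant values for the named variables
constant_days <- function(n_days, ..., start = "2022-01-01 00:00:00") {
  vals <- lapply(list(...), rep, times = 24 * n_days)
  make_series(vals, start = start)
}

# wind series from u,v components (m s-1)
series_from_uv <- function(u, v, start = "2022-01-01 00:00:00",
                           meta = bkk_meta()) {
  ws <- sqrt(u^2 + v^2)
  wd <- (atan2(-u, -v) * 180 / pi) %% 360
  make_series(list(ws = ws, wd = wd), start = start, meta = meta)
}

# long daily_aggregate-shaped frame for pm25 from a date x station matrix
daily_pm25 <- function(dates, station_values) {
  do.call(rbind, lapply(names(station_values), function(s)
    data.frame(date = as.Date(dates), station_id = s, variable = "pm25",
               mean = station_values[[s]],
               n_valid = ifelse(is.na(station_values[[s]]), 0L, 24L),
               completeness = ifelse(is.na(station_values[[s]]), 0, 1))))
}

# a hand-built sea-breeze day flanked by two neighbours: offshore nights,
# onshore 11:00-18:00, constant land temperature
sb_fixture_series <- function(onshore_hours = 11:18, land_temp = 30,
                              onshore_ws = 2, offshore_ws = 1.5) {
  n <- 24 * 3
  hr <- rep(0:23, 3)
  ws <- rep(offshore_ws, n)
  wd <- rep(30, n)  # offshore (NE) by default
  mid <- hr == hr & rep(c(FALSE, TRUE, FALSE), each = 24)
  ws[mid & hr %in% 9:10] <- 0.2  # calm gap before onset
  ws[mid & hr %in% onshore_hours] <- onshore_ws
  wd[mid & hr %in% onshore_hours] <- 195  # onshore (S)
  make_series(list(ws = ws, wd = wd, temp = rep(land_temp, n)),
              start = "2022-01-14 00:00:00")
}
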