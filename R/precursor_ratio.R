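#' Season year of a date
#'
#' The season year runs from November of the preceding calendar year through
#' October of the named year, so that a December--February winter belongs to
#' a single season year (e.g. season year 2020 covers Nov 2019 -- Oct 2020).
#'
#' @param dates Date vector.
#' @return Integer vector of season years.
#' @export
#' @examples
#' season_year(as.Date(c("2019-11-15", "2019-12-31", "2020-01-15")))
season_year <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m >= 11, y + 1L, y)
}

#' Daily daytime CO-normalized precursor ratios
#'
#' For each day, computes PM2.5/CO, NOx/CO and SO2/CO as ratios of daytime
#' means (the mean of the numerator over the window divided by the mean of
#' CO), using daytime hours only (default 06:00--18:00 local) when fresh
#' morning emissions and later photochemistry are both sampled. The
#' ratio-of-means convention is robust to hour-level CO noise. A day is
#' invalid when CO has a non-positive mean or when PM2.5 or CO fall below
#' `min_valid_frac` valid hours in the window; NOx or SO2 may be absent
#' individually (their ratio is NA).
#'
#' @param series A [station_series()] with `pm25`, `co` and optionally
#'   `nox`, `so2`.
#' @param dates Days to evaluate; default all days present.
#' @param window Inclusive local-hour window (default `c(6, 18)`).
#' @param min_valid_frac Minimum valid fraction of window hours.
#' @return A data frame of class `ratio_days`: `date`, `pm25_co`
#'   (ug m-3 per ppm), `nox_co`, `so2_co` (ppb per ppm), `valid`.
#' @export
daytime_ratios <- function(series, dates = NULL, window = c(6, 18),
                           min_valid_frac = 0.75) {
  stopifnot(inherits(series, "station_series"))
  day <- as.Date(format(series$time, "%Y-%m-%d"))
  hr <- as.integer(format(series$time, "%H"))
  if (is.null(dates)) dates <- sort(unique(day))
  n_window <- window[2] - window[1] + 1L
  wmean <- function(x, idx) {
    if (is.null(x)) return(c(NA_real_, 0))
    v <- x[idx]
    c(mean(v, na.rm = TRUE), sum(!is.na(v)))
  }
  res <- lapply(dates, function(d) {
    idx <- which(day == d & hr >= window[1] & hr <= window[2])
    co <- wmean(series$values$co, idx)
    pm <- wmean(series$values$pm25, idx)
    nox <- wmean(series$values$nox, idx)
    so2 <- wmean(series$values$so2, idx)
    enough <- function(w) w[2] >= min_valid_frac * n_window
    valid <- enough(co) && enough(pm) && is.finite(co[1]) && co[1] > 0
    ratio <- function(w) {
      if (!valid || !enough(w) || !is.finite(w[1])) NA_real_
      else w[1] / co[1]
    }
    data.frame(date = d, pm25_co = ratio(pm), nox_co = ratio(nox),
               so2_co = ratio(so2), valid = valid)
  })
  out <- do.call(rbind, res)
  class(out) <- c("ratio_days", "data.frame")
  out
}

#' Clean-day baseline ratios for one season year
#'
#' Averages the daily ratios over the clean days -- December--February days
#' of the episode's season year that are neither haze days nor bridged
#' episode days -- to form the baseline each episode is compared against.
#'
#' @param ratio_days A `ratio_days` frame from [daytime_ratios()].
#' @param cal A `haze_calendar` from [compute_haze_days()].
#' @param sy Season year (see [season_year()]).
#' @param exclude_dates Additional dates to exclude (e.g. bridged days).
#' @param min_clean_days Minimum number of valid clean days (default 10).
#' @return A list `pm25_co`, `nox_co`, `so2_co`, `n_clean_days`.
#' @export
season_clean_baseline <- function(ratio_days, cal, sy, exclude_dates = NULL,
                                  min_clean_days = 10) {
  d <- as.Date(ratio_days$date)
  m <- as.integer(format(d, "%m"))
  in_djf <- season_year(d) == sy & m %in% c(12L, 1L, 2L)
  haze_dates <- cal$date[cal$haze]
  keep <- in_djf & ratio_days$valid & !d %in% haze_dates &
    !d %in% as.Date(exclude_dates)
  n <- sum(keep)
  if (n < min_clean_days)
    stop("only ", n, " valid clean days in DJF of season year ", sy,
         " (need ", min_clean_days, ")", call. = FALSE)
  list(pm25_co = mean(ratio_days$pm25_co[keep], na.rm = TRUE),
       nox_co = mean(ratio_days$nox_co[keep], na.rm = TRUE),
       so2_co = mean(ratio_days$so2_co[keep], na.rm = TRUE),
       n_clean_days = n)
}

#' Compare clean and episodic mean ratios
#'
#' The core screening rule on already-averaged ratios: PM2.5/CO must rise
#' strictly on episode days, and a fall in NOx/CO and/or SO2/CO indicates
#' gas-to-particle conversion. All comparisons are strict, so a tie is no
#' change; a missing episodic SO2 ratio cannot count as a decrease. The
#' category is `sulfate+nitrate` when both precursors fall, `nitrate-only`
#' or `sulfate-only` when one does, `none` otherwise.
#'
#' @param clean,episodic Lists (or 1-row data frames) with `pm25_co`,
#'   `nox_co`, `so2_co`.
#' @return A list: `pm_up`, `nox_down`, `so2_down`, `secondary_flag`,
#'   `category`.
#' @export
compare_ratio_means <- function(clean, episodic) {
  gt <- function(a, b) !is.na(a) && !is.na(b) && a > b
  pm_up <- gt(episodic$pm25_co, clean$pm25_co)
  nox_down <- gt(clean$nox_co, episodic$nox_co)
  so2_down <- gt(clean$so2_co, episodic$so2_co)
  category <- if (nox_down && so2_down) "sulfate+nitrate"
  else if (nox_down) "nitrate-only"
  else if (so2_down) "sulfate-only"
  else "none"
  list(pm_up = pm_up, nox_down = nox_down, so2_down = so2_down,
       secondary_flag = pm_up && (nox_down || so2_down),
       category = category)
}

#' Screen one episode for secondary-aerosol influence
#'
#' Averages the daily ratios over the episode's days and applies
#' [compare_ratio_means()] against the clean-day baseline of the episode's
#' season year.
#'
#' @param episode One row of a `haze_episodes` frame.
#' @param ratio_days A `ratio_days` frame covering the episode.
#' @param baseline Output of [season_clean_baseline()].
#' @return A one-row data frame: episode id, season year, clean and episodic
#'   means of the three ratios, the three comparison booleans,
#'   `secondary_flag` and `category`.
#' @export
compare_episode_ratios <- function(episode, ratio_days, baseline) {
  days <- seq(episode$start, episode$end, by = "day")
  rd <- ratio_days[as.Date(ratio_days$date) %in% days & ratio_days$valid, ]
  if (!nrow(rd))
    stop("no valid ratio day within episode ", episode$episode_id,
         call. = FALSE)
  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  episodic <- list(pm25_co = avg(rd$pm25_co), nox_co = avg(rd$nox_co),
                   so2_co = avg(rd$so2_co))
  cmp <- compare_ratio_means(baseline, episodic)
  data.frame(episode_id = episode$episode_id,
             season_year = season_year(episode$start),
             pm25_co_clean = baseline$pm25_co, pm25_co_episodic = episodic$pm25_co,
             nox_co_clean = baseline$nox_co, nox_co_episodic = episodic$nox_co,
             so2_co_clean = baseline$so2_co, so2_co_episodic = episodic$so2_co,
             pm_up = cmp$pm_up, nox_down = cmp$nox_down,
             so2_down = cmp$so2_down, secondary_flag = cmp$secondary_flag,
             category = cmp$category, n_episode_days = nrow(rd))
}
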