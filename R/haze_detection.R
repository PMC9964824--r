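#' Build the haze-day calendar from multi-station daily PM2.5
#'
#' A date is a haze day when strictly more than `threshold` ug m-3 of daily
#' mean PM2.5 is observed at `min_stations` or more stations. Dates with
#' fewer than `min_stations` valid station values cannot satisfy the rule and
#' are additionally flagged `data_poor`.
#'
#' @param daily Row-bound [daily_aggregate()] output over the stations, or a
#'   wide data frame from [daily_wide()].
#' @param threshold Daily PM2.5 threshold in ug m-3 (default 50). Exceedance
#'   is strict: a daily mean equal to the threshold is not haze.
#' @param min_stations Minimum number of exceeding stations (default 2).
#' @return A data frame of class `haze_calendar`: `date`, `n_valid`,
#'   `n_exceed`, `haze`, `data_poor`.
#' @export
compute_haze_days <- function(daily, threshold = 50, min_stations = 2) {
  stopifnot(threshold > 0, min_stations >= 1)
  wide <- if ("variable" %in% names(daily)) daily_wide(daily, "pm25") else daily
  if (nrow(wide) == 0L) stop("empty daily input", call. = FALSE)
  vals <- as.matrix(wide[, setdiff(names(wide), "date"), drop = FALSE])
  if (ncol(vals) < min_stations)
    stop("need at least ", min_stations, " stations", call. = FALSE)
  n_valid <- rowSums(!is.na(vals))
  n_exceed <- rowSums(vals > threshold, na.rm = TRUE)
  cal <- data.frame(date = wide$date,
                    n_valid = as.integer(n_valid),
                    n_exceed = as.integer(n_exceed),
                    haze = n_exceed >= min_stations,
                    data_poor = n_valid < min_stations)
  class(cal) <- c("haze_calendar", "data.frame")
  cal
}

# Core segmentation on a logical haze vector over consecutive days.
# Returns an integer matrix with columns start, end (1-based indices).
# Maximal haze runs are found with rle(); adjacent runs whose separating
# non-haze gap is <= max_bridge days are merged in one left-to-right pass.
segment_runs <- function(haze, max_bridge) {
  n <- length(haze)
  if (n == 0L || !any(haze))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  r <- rle(haze)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hs <- starts[r$values]
  he <- ends[r$values]
  out_s <- hs[1]
  out_e <- he[1]
  if (length(hs) > 1L) {
    for (i in 2:length(hs)) {
      gap <- hs[i] - out_e[length(out_e)] - 1L
      if (gap <= max_bridge) {
        out_e[length(out_e)] <- he[i]
      } else {
        out_s <- c(out_s, hs[i])
        out_e <- c(out_e, he[i])
      }
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Segment the haze calendar into episodes
#'
#' Episodes are maximal runs of haze days; two runs separated by at most
#' `max_bridge` intervening non-haze days are merged into one episode, the
#' intervening days recorded as bridged. Episodes never start or end on a
#' bridged day; duration counts every day in the span, bridged days included.
#' Calendars with date gaps (e.g. restricted to winter months) are segmented
#' within each contiguous block of dates, so episodes never bridge a season
#' boundary.
#'
#' @param cal A `haze_calendar` from [compute_haze_days()].
#' @param max_bridge Maximum bridged gap in days (default 2).
#' @return A data frame of class `haze_episodes`: `episode_id`, `start`,
#'   `end`, `duration`, `haze_day_count`, `bridged_day_count`,
#'   `bridged_dates` (comma-separated), `persistent`.
#' @export
segment_episodes <- function(cal, max_bridge = 2) {
  stopifnot(max_bridge >= 0)
  cal <- cal[order(cal$date), , drop = FALSE]
  # split into contiguous daily blocks
  brk <- c(0, cumsum(diff(as.integer(cal$date)) != 1L))
  spans <- list()
  for (b in unique(brk)) {
    sub <- cal[brk == b, , drop = FALSE]
    m <- segment_runs(sub$haze, max_bridge)
    if (nrow(m) == 0L) next
    for (i in seq_len(nrow(m))) {
      d <- sub$date[m[i, "start"]:m[i, "end"]]
      h <- sub$haze[m[i, "start"]:m[i, "end"]]
      spans[[length(spans) + 1L]] <- data.frame(
        start = min(d), end = max(d),
        duration = as.integer(length(d)),
        haze_day_count = as.integer(sum(h)),
        bridged_day_count = as.integer(sum(!h)),
        bridged_dates = paste(format(d[!h]), collapse = ","))
    }
  }
  if (!length(spans)) {
    ep <- data.frame(episode_id = integer(0), start = as.Date(character(0)),
                     end = as.Date(character(0)), duration = integer(0),
                     haze_day_count = integer(0),
                     bridged_day_count = integer(0),
                     bridged_dates = character(0), persistent = logical(0))
  } else {
    ep <- do.call(rbind, spans)
    ep <- ep[order(ep$start), , drop = FALSE]
    ep <- data.frame(episode_id = seq_len(nrow(ep)), ep,
                     persistent = ep$duration > 7, row.names = NULL)
  }
  class(ep) <- c("haze_episodes", "data.frame")
  ep
}

#' Episode pollution statistics
#'
#' For each episode, the cross-station mean daily PM2.5 is computed for every
#' day of the span (bridged days included), then summarised as the episode
#' mean, sample (n-1) standard deviation, and coefficient of variation
#' cv = sd/mean. A single-day episode has sd and cv 0 by convention. Days
#' with no valid station value are dropped from the statistics with a
#' warning.
#'
#' @param episodes A `haze_episodes` data frame.
#' @param daily Long [daily_aggregate()] output or wide [daily_wide()] frame.
#' @return `episodes` with `mean_pm25`, `sd_pm25`, `cv_pm25` appended.
#' @export
episode_stats <- function(episodes, daily) {
  wide <- if ("variable" %in% names(daily)) daily_wide(daily, "pm25") else daily
  vals <- as.matrix(wide[, setdiff(names(wide), "date"), drop = FALSE])
  xmean <- rowMeans(vals, na.rm = TRUE)
  xmean[!is.finite(xmean)] <- NA_real_
  episodes$mean_pm25 <- NA_real_
  episodes$sd_pm25 <- NA_real_
  episodes$cv_pm25 <- NA_real_
  for (i in seq_len(nrow(episodes))) {
    days <- seq(episodes$start[i], episodes$end[i], by = "day")
    x <- xmean[match(days, wide$date)]
    if (anyNA(x)) {
      warning("episode ", episodes$episode_id[i],
              ": day(s) with no valid station PM2.5 dropped from statistics")
      x <- x[!is.na(x)]
    }
    if (!length(x)) next
    m <- mean(x)
    s <- if (length(x) > 1L) stats::sd(x) else 0
    episodes$mean_pm25[i] <- m
    episodes$sd_pm25[i] <- s
    episodes$cv_pm25[i] <- s / m
  }
  episodes
}

#' Duration-frequency table of typed episodes
#'
#' Tabulates episode counts by duration, split by haze type, with the mean
#' coefficient of variation per duration, plus a `Total` row.
#'
#' @param episodes A `haze_episodes` frame carrying a `type` column
#'   (`"I"`, `"II"`, `"III"`, `"IV"`) and optionally `cv_pm25`.
#' @return A data frame: `duration`, `n_episodes`, `type_I` .. `type_IV`,
#'   `mean_cv`; last row is the totals row (`duration` NA).
#' @export
duration_frequency <- function(episodes) {
  if (!"type" %in% names(episodes))
    stop("episodes must carry a 'type' column; see classify_episodes()",
         call. = FALSE)
  durs <- sort(unique(episodes$duration))
  rows <- lapply(durs, function(d) {
    e <- episodes[episodes$duration == d, ]
    data.frame(duration = d, n_episodes = nrow(e),
               type_I = sum(e$type == "I"), type_II = sum(e$type == "II"),
               type_III = sum(e$type == "III"), type_IV = sum(e$type == "IV"),
               mean_cv = if ("cv_pm25" %in% names(e))
                 mean(e$cv_pm25, na.rm = TRUE) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(duration = NA_integer_, n_episodes = nrow(episodes),
                      type_I = sum(episodes$type == "I"),
                      type_II = sum(episodes$type == "II"),
                      type_III = sum(episodes$type == "III"),
                      type_IV = sum(episodes$type == "IV"),
                      mean_cv = NA_real_)
  rbind(tab, total)
}
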