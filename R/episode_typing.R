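#' Typing configuration
#'
#' Thresholds that turn the narrative haze-type definitions into a decision
#' rule. An episode is cold-surge (CS) influenced when at least one CS day
#' falls between `pre_haze_window` days before the episode start and the end
#' of the first `cs_scan` fraction of the episode (CS days can arrive a few
#' days ahead of the haze, or, in reversed episodes, within its first half).
#' It is sea-breeze (SB) influenced when the fraction of episode days
#' classified as SB days reaches `sb_fraction_threshold`; pure sea-breeze
#' episodes (Type II) with a fraction below `sb_type2_threshold` keep the
#' type but carry a low-confidence note.
#'
#' @param pre_haze_window Days scanned before the episode start (default 3).
#' @param cs_scan Fraction of the episode, from its start, scanned for CS
#'   days (default 0.5).
#' @param sb_fraction_threshold Minimum SB-day fraction for SB influence
#'   (default 1/3).
#' @param sb_type2_threshold "Most of the days" fraction for a confident
#'   Type II (default 0.5).
#' @return A list of class `typing_config`.
#' @export
typing_config <- function(pre_haze_window = 3, cs_scan = 0.5,
                          sb_fraction_threshold = 1 / 3,
                          sb_type2_threshold = 0.5) {
  stopifnot(pre_haze_window >= 1, cs_scan > 0, cs_scan <= 1,
            sb_fraction_threshold > 0, sb_fraction_threshold <= 1,
            sb_type2_threshold > 0, sb_type2_threshold <= 1)
  structure(list(pre_haze_window = pre_haze_window, cs_scan = cs_scan,
                 sb_fraction_threshold = sb_fraction_threshold,
                 sb_type2_threshold = sb_type2_threshold),
            class = "typing_config")
}

#' Assign the four meteorology-based haze types
#'
#' Each episode receives exactly one type from the truth table over cold-
#' surge and sea-breeze influence: Type I (CS only), Type II (SB only),
#' Type III (both, the synergistic type), Type IV (neither).
#'
#' @param episodes A `haze_episodes` data frame.
#' @param cs_calendar Data frame `date`, `cs_flag` (logical) covering at
#'   least `[start - pre_haze_window, end]` of every episode.
#' @param sb_days A `sea_breeze_days` frame from [classify_sea_breeze()]
#'   covering the episode days.
#' @param config A [typing_config()].
#' @return `episodes` with `type`, `cs_influenced`, `sb_influenced`,
#'   `cs_days_found`, `sb_day_fraction`, `rationale` appended.
#' @export
classify_episodes <- function(episodes, cs_calendar, sb_days,
                              config = typing_config()) {
  cs_dates <- as.Date(cs_calendar$date)[as.logical(cs_calendar$cs_flag)]
  sbd <- as.Date(sb_days$date)
  episodes$type <- NA_character_
  episodes$cs_influenced <- NA
  episodes$sb_influenced <- NA
  episodes$cs_days_found <- NA_character_
  episodes$sb_day_fraction <- NA_real_
  episodes$rationale <- NA_character_
  for (i in seq_len(nrow(episodes))) {
    start <- episodes$start[i]
    end <- episodes$end[i]
    dur <- episodes$duration[i]
    scan_end <- start + ceiling(dur * config$cs_scan) - 1
    need <- seq(start - config$pre_haze_window, end, by = "day")
    if (!all(need %in% as.Date(cs_calendar$date)))
      stop("cs_calendar does not cover episode ", episodes$episode_id[i],
           " and its pre-haze window", call. = FALSE)
    cs_hits <- cs_dates[cs_dates >= start - config$pre_haze_window &
                          cs_dates <= scan_end]
    cs <- length(cs_hits) > 0L
    days <- seq(start, end, by = "day")
    m <- match(days, sbd)
    covered <- !is.na(m)
    classifiable <- covered & sb_days$classifiable[m]
    classifiable[is.na(classifiable)] <- FALSE
    if (sum(covered & !classifiable) > 0.25 * dur)
      warning("episode ", episodes$episode_id[i],
              ": more than 25% of days unclassifiable for sea breeze")
    sb_hits <- sum(sb_days$is_sb[m[classifiable]], na.rm = TRUE)
    frac <- sb_hits / dur
    sb <- frac >= config$sb_fraction_threshold
    type <- if (cs && !sb) "I" else if (!cs && sb) "II"
    else if (cs && sb) "III" else "IV"
    note <- sprintf("cs=%s (%d CS day(s) in scan), sb=%s (%.2f of days)",
                    cs, length(cs_hits), sb, frac)
    if (type == "II" && frac < config$sb_type2_threshold)
      note <- paste(note, "; low confidence: SB fraction below",
                    config$sb_type2_threshold)
    episodes$type[i] <- type
    episodes$cs_influenced[i] <- cs
    episodes$sb_influenced[i] <- sb
    episodes$cs_days_found[i] <- paste(format(cs_hits), collapse = ",")
    episodes$sb_day_fraction[i] <- frac
    episodes$rationale[i] <- note
  }
  episodes
}

#' Per-type summary of pollution and meteorology
#'
#' Mean and standard deviation, over episode days pooled within each type,
#' of daily PM2.5 (cross-station mean), temperature, relative humidity,
#' cloud cover, global radiation, the recirculation factor, and -- over the
#' sea-breeze days among them -- SB duration and penetration. A `clean`
#' column summarises the non-episode days of the supplied calendar. Types
#' with no SB days report NA for the SB statistics.
#'
#' @param episodes Typed `haze_episodes` (from [classify_episodes()]).
#' @param daily Long [daily_aggregate()] output across stations.
#' @param rf A `recirculation` frame from [recirculation_factor()].
#' @param sb_days A `sea_breeze_days` frame.
#' @param cal A `haze_calendar` (used to find clean days).
#' @return A data frame: `variable`, `stat` (`mean`/`sd`), one column per
#'   type plus `clean`.
#' @export
type_summary <- function(episodes, daily, rf, sb_days, cal) {
  ep_days <- lapply(c("I", "II", "III", "IV"), function(tp) {
    e <- episodes[episodes$type == tp, , drop = FALSE]
    if (!nrow(e)) return(as.Date(character(0)))
    do.call(c, lapply(seq_len(nrow(e)), function(i)
      seq(e$start[i], e$end[i], by = "day")))
  })
  names(ep_days) <- c("I", "II", "III", "IV")
  all_ep <- do.call(c, c(ep_days, list(as.Date(character(0)))))
  clean <- cal$date[!cal$haze & !cal$date %in% all_ep]
  groups <- c(list(clean = clean), ep_days)

  met_vars <- c("pm25", "temp", "rh", "cc", "gr")
  day_mean <- function(v) {
    w <- daily_wide(daily, v)
    vals <- as.matrix(w[, setdiff(names(w), "date"), drop = FALSE])
    m <- rowMeans(vals, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    stats::setNames(m, format(w$date))
  }
  rows <- list()
  add <- function(variable, values_by_date) {
    means <- vapply(groups, function(dd) {
      x <- values_by_date[format(dd)]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    sds <- vapply(groups, function(dd) {
      x <- values_by_date[format(dd)]
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else stats::sd(x)
    }, numeric(1))
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable,
                                             stat = "mean", t(means))
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable,
                                             stat = "sd", t(sds))
  }
  for (v in met_vars) {
    if (v %in% unique(daily$variable)) add(v, day_mean(v))
  }
  add("rf", stats::setNames(rf$RF, format(rf$date)))
  sb_only <- sb_days[which(sb_days$is_sb), ]
  add("sb_duration_h",
      stats::setNames(sb_only$duration_h, format(sb_only$date)))
  add("sb_penetration_km",
      stats::setNames(sb_only$penetration_km, format(sb_only$date)))
  out <- do.call(rbind, rows)
  names(out) <- c("variable", "stat", "clean", "type_I", "type_II",
                  "type_III", "type_IV")
  rownames(out) <- NULL
  out
}
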