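#' Assemble a pipeline configuration
#'
#' Accepts a named list or a path to a YAML file and fills in defaults for
#' every tunable of the analysis: winter analysis months, the 50 ug m-3
#' haze threshold with 2-station minimum, 2-day episode bridging, coastal
#' geometry, typing thresholds, the reference station for the ratio and
#' sea-breeze stages, and the daytime windows.
#'
#' @param config Named list or YAML file path. Recognised keys:
#'   `station_files` (named character vector or list, one CSV per station),
#'   `station_meta_file`, `sst_file`, `cs_calendar_file`, `months`
#'   (default `c(12, 1, 2)`), `haze_threshold` (50), `min_stations` (2),
#'   `max_bridge` (2), `min_completeness` (0.75), `geometry` (list passed to
#'   [coast_geometry()]), `typing` (list passed to [typing_config()]),
#'   `ratio_station`, `sb_station`, `ratio_window` (`c(6, 18)`),
#'   `rf_window` (`c(10, 18)`), `seed` (1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(months = c(12L, 1L, 2L), haze_threshold = 50,
                   min_stations = 2L, max_bridge = 2L,
                   min_completeness = 0.75, geometry = list(),
                   typing = list(), ratio_station = NULL, sb_station = NULL,
                   ratio_window = c(6, 18), rf_window = c(10, 18), seed = 1L)
  defaults[names(config)] <- config
  defaults$geometry <- do.call(coast_geometry, as.list(defaults$geometry))
  defaults$typing <- do.call(typing_config, as.list(defaults$typing))
  structure(defaults, class = "pipeline_config")
}

read_station_table <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("station_id", "lat", "lon")
  if (!all(needed %in% names(m)))
    stop("station metadata needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  m
}

#' Run the full haze analysis pipeline
#'
#' Orchestrates every stage: read and QC the station series, aggregate to
#' daily means, restrict to the analysis months, detect haze days and
#' segment episodes, classify sea-breeze days and daily recirculation at the
#' reference station, type the episodes against the cold-surge calendar,
#' screen episodes for secondary-aerosol influence with the precursor-ratio
#' method, and emit the report tables. Deterministic given its inputs.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @param stations Optional list of in-memory [station_series()] (e.g. from
#'   [generate_scenario()]), bypassing `station_files`.
#' @param sst Optional in-memory `date`,`sst` frame.
#' @param cs_calendar Optional in-memory `date`,`cs_flag` frame.
#' @param outdir Optional output directory for the report CSVs and a JSON
#'   run manifest.
#' @return A list of class `haze_report`: `daily`, `haze_calendar`,
#'   `episodes` (typed, with statistics), `sb_days`, `rf`,
#'   `duration_frequency`, `type_summary`, `ratio_comparisons`, `log`.
#' @export
run_pipeline <- function(config = list(), stations = NULL, sst = NULL,
                         cs_calendar = NULL, outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (is.null(stations)) {
    meta_tab <- read_station_table(config$station_meta_file)
    stations <- lapply(names(config$station_files), function(sid) {
      row <- meta_tab[meta_tab$station_id == sid, ]
      if (!nrow(row)) stop("no metadata for station ", sid, call. = FALSE)
      meta <- station_meta(sid, row$lat[1], row$lon[1],
                           if ("province" %in% names(row)) row$province[1]
                           else "",
                           if ("background" %in% names(row))
                             row$background[1] else "")
      read_station_csv(config$station_files[[sid]], meta)
    })
  }
  stations <- lapply(stations, apply_qc, quiet = TRUE)
  ids <- vapply(stations, function(s) s$meta$station_id, character(1))
  names(stations) <- ids
  say("stage read: %d stations, %d-%d hours", length(stations),
      min(lengths(lapply(stations, `[[`, "time"))),
      max(lengths(lapply(stations, `[[`, "time"))))

  if (is.null(sst)) sst <- utils::read.csv(config$sst_file,
                                           stringsAsFactors = FALSE)
  sst$date <- as.Date(sst$date)
  if (is.null(cs_calendar))
    cs_calendar <- utils::read.csv(config$cs_calendar_file,
                                   stringsAsFactors = FALSE)
  cs_calendar$date <- as.Date(cs_calendar$date)
  cs_calendar$cs_flag <- as.logical(cs_calendar$cs_flag)

  daily <- do.call(rbind, lapply(stations, daily_aggregate,
                                 min_completeness = config$min_completeness))
  months <- as.integer(config$months)
  in_months <- as.integer(format(daily$date, "%m")) %in% months
  daily_a <- daily[in_months, , drop = FALSE]
  say("stage daily: %d station-days (%d in analysis months)",
      length(unique(daily$date)), length(unique(daily_a$date)))

  cal <- compute_haze_days(daily_a, threshold = config$haze_threshold,
                           min_stations = config$min_stations)
  episodes <- segment_episodes(cal, max_bridge = config$max_bridge)
  say("stage detect: %d haze days, %d episodes", sum(cal$haze),
      nrow(episodes))

  ref_id <- if (!is.null(config$sb_station)) config$sb_station else
    if (!is.null(config$ratio_station)) config$ratio_station else ids[1]
  ref <- stations[[ref_id]]
  sb_days <- classify_sea_breeze(ref, sst, geometry = config$geometry)
  rf <- recirculation_factor(ref, window = config$rf_window)
  say("stage seabreeze: %d SB days of %d classifiable (station %s)",
      sum(sb_days$is_sb), sum(sb_days$classifiable), ref_id)

  if (nrow(episodes)) {
    episodes <- episode_stats(episodes, daily_a)
    episodes <- classify_episodes(episodes, cs_calendar, sb_days,
                                  config$typing)
    say("stage classify: types %s",
        paste(sprintf("%s=%d", c("I", "II", "III", "IV"),
                      tabulate(match(episodes$type,
                                     c("I", "II", "III", "IV")), 4)),
              collapse = " "))
  }

  dur_freq <- if (nrow(episodes)) duration_frequency(episodes) else NULL
  typ_sum <- if (nrow(episodes))
    type_summary(episodes, daily_a, rf, sb_days, cal) else NULL

  ratio_id <- if (!is.null(config$ratio_station)) config$ratio_station
  else ids[1]
  rdays <- daytime_ratios(stations[[ratio_id]],
                          window = config$ratio_window)
  comparisons <- NULL
  if (nrow(episodes)) {
    bridged <- as.Date(unlist(strsplit(
      episodes$bridged_dates[nzchar(episodes$bridged_dates)], ",")))
    rows <- lapply(seq_len(nrow(episodes)), function(i) {
      sy <- season_year(episodes$start[i])
      base <- tryCatch(season_clean_baseline(rdays, cal, sy,
                                             exclude_dates = bridged),
                       error = function(e) NULL)
      if (is.null(base)) {
        say("stage ratios: episode %d skipped (no clean baseline, season year %d)",
            episodes$episode_id[i], sy)
        return(NULL)
      }
      tryCatch(compare_episode_ratios(episodes[i, ], rdays, base),
               error = function(e) NULL)
    })
    comparisons <- do.call(rbind, rows)
    say("stage ratios: %d of %d episodes compared, %d flagged secondary",
        if (is.null(comparisons)) 0L else nrow(comparisons), nrow(episodes),
        if (is.null(comparisons)) 0L else sum(comparisons$secondary_flag))
    if (!is.null(comparisons)) {
      episodes$secondary <- FALSE
      m <- match(comparisons$episode_id, episodes$episode_id)
      episodes$secondary[m] <- comparisons$secondary_flag
    }
  }

  report <- structure(list(daily = daily_a, haze_calendar = cal,
                           episodes = episodes, sb_days = sb_days, rf = rf,
                           duration_frequency = dur_freq,
                           type_summary = typ_sum,
                           ratio_comparisons = comparisons, log = log),
                      class = "haze_report")
  if (!is.null(outdir)) write_report(report, outdir, config)
  report
}

#' Write the report bundle to disk
#'
#' Emits `episodes.csv`, `duration_frequency.csv`, `type_summary.csv`,
#' `ratio_comparisons.csv`, `sea_breeze_days.csv`, `recirculation.csv` and
#' a `manifest.json` with counts and the configuration echo.
#'
#' @param report A `haze_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param config The [pipeline_config()] used (echoed into the manifest).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir, config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x) && NROW(x))
    utils::write.csv(x, file.path(outdir, name), row.names = FALSE,
                     na = "")
  wr(report$episodes, "episodes.csv")
  wr(report$duration_frequency, "duration_frequency.csv")
  wr(report$type_summary, "type_summary.csv")
  wr(report$ratio_comparisons, "ratio_comparisons.csv")
  wr(report$sb_days, "sea_breeze_days.csv")
  wr(report$rf, "recirculation.csv")
  manifest <- list(
    package = "hazemet",
    version = as.character(utils::packageVersion("hazemet")),
    n_haze_days = sum(report$haze_calendar$haze),
    n_episodes = NROW(report$episodes),
    n_sb_days = sum(report$sb_days$is_sb),
    log = report$log,
    config = if (!is.null(config))
      lapply(unclass(config), function(x)
        if (inherits(x, c("coast_geometry", "typing_config"))) unclass(x)
        else x))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.haze_report <- function(x, ...) {
  cat("<haze_report>\n")
  cat(" ", sum(x$haze_calendar$haze), "haze days,", NROW(x$episodes),
      "episodes,", sum(x$sb_days$is_sb), "sea-breeze days\n")
  if (NROW(x$episodes) && "type" %in% names(x$episodes))
    print(table(type = x$episodes$type))
  invisible(x)
}
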