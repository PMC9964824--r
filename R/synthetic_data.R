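#' Scenario configuration for the synthetic generator
#'
#' Describes a multi-station hourly scenario with planted cold surges,
#' sea-breeze days, emission events and secondary-aerosol episodes. The
#' defaults emulate a winter (DJF) season at a tropical coastal city:
#' a 28 C mean temperature with a 4 C diurnal cycle, mild north-easterly
#' (offshore) synoptic wind, a 20 ug m-3 PM2.5 background, and first-order
#' box-model pollution dynamics
#' `C(t+1) = C(t) + E - k_vent * ws(t) * (C(t) - background)` floored at the
#' background. With the default emission 4 ug m-3 h-1 and k_vent 0.1 per
#' (m s-1 h), clean windy days equilibrate near 36 ug m-3, sea-breeze days
#' near 60, and cold-surge stagnation climbs past 100 -- the regimes the
#' detection stages are meant to separate.
#'
#' @param start,end Scenario date span (local days).
#' @param n_stations Number of stations (default 5).
#' @param seed Integer seed fixing all randomness.
#' @param temp_mean,temp_amp Diurnal temperature cycle, C (peak 14:00 LT).
#' @param rh_mean,rh_amp Diurnal relative-humidity cycle, % (anti-phase).
#' @param background_pm25 PM2.5 background, ug m-3.
#' @param emission Per-station emission rate, ug m-3 h-1 (recycled).
#' @param k_vent Ventilation coefficient per (m s-1 h).
#' @param base_ws,base_wd Default synoptic wind (m s-1, degrees FROM).
#' @param co_background CO background, ppm.
#' @param co_emission_ratio CO emission per unit PM emission (ppm per
#'   ug m-3).
#' @param nox_per_co,so2_per_co Co-emission ratios (ppb per ppm CO).
#' @param sst_default Default daily sea-surface temperature, C.
#' @param cs_events List of cold-surge events, each a list with `start`
#'   (date), `length` (days), and optionally `dT_drop` (C, default 4),
#'   `dRH_drop` (%, default 15), `surge_days` (default 1, windy onset),
#'   `surge_ws` (default 6), `stagnation_ws` (default 0.3).
#' @param sb_days List of planted sea-breeze days, each a list with `date`
#'   and optionally `onset_offset` (h after sunrise+2, default 2),
#'   `run_length` (h, default 8), `onshore_ws` (default 1.1 m s-1),
#'   `offshore_ws` (default 1.0), `delta_t` (C, default 5).
#' @param emission_events List of emission boosts, each a list with `dates`
#'   and `factor` (multiplier on `emission`).
#' @param secondary_episodes List of secondary-aerosol perturbations, each a
#'   list with `dates` and optionally `pm_boost` (default 0.3),
#'   `nox_depletion` (default 0.2), `so2_depletion` (default 0.2).
#' @param noise_sd Named list of hourly measurement-noise standard
#'   deviations; defaults: pm25 2, co 0.02, nox 2, so2 0.1, temp 0.3, rh 2,
#'   ws 0.1, wd 5, gr 15, cc 0.
#' @param geometry [coast_geometry()] used for planted wind sectors.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(start = as.Date("2021-12-01"),
                            end = as.Date("2022-02-28"),
                            n_stations = 5, seed = 1L,
                            temp_mean = 28, temp_amp = 4,
                            rh_mean = 60, rh_amp = 10,
                            background_pm25 = 20, emission = 4,
                            k_vent = 0.1, base_ws = 2.5, base_wd = 30,
                            co_background = 0.3, co_emission_ratio = 0.025,
                            nox_per_co = 55, so2_per_co = 2.5,
                            sst_default = 26,
                            cs_events = list(), sb_days = list(),
                            emission_events = list(),
                            secondary_episodes = list(),
                            noise_sd = list(), geometry = coast_geometry()) {
  start <- as.Date(start)
  end <- as.Date(end)
  problems <- character(0)
  if (end < start) problems <- c(problems, "end precedes start")
  if (n_stations < 1) problems <- c(problems, "n_stations must be >= 1")
  if (any(emission < 0)) problems <- c(problems, "emission must be >= 0")
  if (k_vent < 0) problems <- c(problems, "k_vent must be >= 0")
  for (ev in cs_events)
    if (as.Date(ev$start) < start || as.Date(ev$start) > end)
      problems <- c(problems, paste("cs_event outside span:", ev$start))
  for (sb in sb_days)
    if (as.Date(sb$date) < start || as.Date(sb$date) > end)
      problems <- c(problems, paste("sb_day outside span:", sb$date))
  if (length(problems))
    stop("invalid scenario config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  ns <- list(pm25 = 2, co = 0.02, nox = 2, so2 = 0.1, temp = 0.3, rh = 2,
             ws = 0.1, wd = 5, gr = 15, cc = 0)
  ns[names(noise_sd)] <- noise_sd
  structure(list(start = start, end = end, n_stations = n_stations,
                 seed = as.integer(seed), temp_mean = temp_mean,
                 temp_amp = temp_amp, rh_mean = rh_mean, rh_amp = rh_amp,
                 background_pm25 = background_pm25,
                 emission = rep_len(emission, n_stations), k_vent = k_vent,
                 base_ws = base_ws, base_wd = base_wd,
                 co_background = co_background,
                 co_emission_ratio = co_emission_ratio,
                 nox_per_co = nox_per_co, so2_per_co = so2_per_co,
                 sst_default = sst_default, cs_events = cs_events,
                 sb_days = sb_days, emission_events = emission_events,
                 secondary_episodes = secondary_episodes, noise_sd = ns,
                 geometry = geometry),
            class = "scenario_config")
}

# direction at the centre of a sector (wrapping sectors supported)
sector_centre <- function(sector) {
  if (sector[1] <= sector[2]) mean(sector)
  else ((sector[1] + sector[2] + 360) / 2) %% 360
}

#' Generate a synthetic multi-station scenario
#'
#' Builds hourly series for every station from the planted schedule in the
#' configuration: default mild offshore synoptic wind; cold-surge events as
#' one or two windy, cool onset days followed by calm stagnation; sea-breeze
#' days as nocturnal offshore flow, a daytime onshore run placed inside the
#' detection window using the same solar routine the classifier uses, and a
#' planted land-sea thermal contrast; PM2.5 from the first-order box model
#' (see [scenario_config()]); CO co-emitted, NOx and SO2 proportional to CO
#' with planted depletions and PM boosts during secondary-aerosol episodes;
#' independent Gaussian measurement noise per variable. Pollution dynamics
#' run on the noise-free wind, so ground truth is independent of the
#' measurement noise.
#'
#' Ground truth is derived, not asserted: haze days and episodes are computed
#' by running the detection stages on the noise-free series, and planted
#' episode types follow the cold-surge/sea-breeze truth table on the planted
#' flags.
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `scenario`: `stations` (list of
#'   [station_series()]), `sst` (data frame `date`, `sst`), `cs_calendar`
#'   (`date`, `cs_flag`), `truth` (list: `sb`, `cs_dates`, `haze_calendar`,
#'   `episodes` with planted types, `secondary_episode_ids`), `config`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(cfg$seed)

  dates <- seq(cfg$start, cfg$end, by = "day")
  time <- seq(as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(cfg$end, "23:00:00"), tz = "UTC"),
              by = "hour")
  n <- length(time)
  day <- as.Date(format(time, "%Y-%m-%d"))
  hr <- as.integer(format(time, "%H"))

  # station metadata spread around the reference coordinates
  metas <- lapply(seq_len(cfg$n_stations), function(i)
    station_meta(sprintf("S%02d", i),
                 13.67 + 0.02 * (i - 1) * (-1)^i,
                 100.61 - 0.07 * (i - 1), "Synthetic", "General area", 7))
  sun <- solar_times(metas[[1]]$latitude, metas[[1]]$longitude, dates, 7)

  # --- planted wind schedule (truth, shared across stations) -------------
  ws <- rep(cfg$base_ws, n)
  wd <- rep(cfg$base_wd, n)
  on_dir <- sector_centre(cfg$geometry$onshore)
  off_dir <- sector_centre(cfg$geometry$offshore)
  temp_adj <- rep(0, n)
  rh_adj <- rep(0, n)
  cs_dates <- as.Date(character(0))
  for (ev in cfg$cs_events) {
    ev_start <- as.Date(ev$start)
    len <- ev$length
    surge_days <- if (is.null(ev$surge_days)) 1L else ev$surge_days
    surge_ws <- if (is.null(ev$surge_ws)) 6 else ev$surge_ws
    stag_ws <- if (is.null(ev$stagnation_ws)) 0.3 else ev$stagnation_ws
    dT <- if (is.null(ev$dT_drop)) 4 else ev$dT_drop
    dRH <- if (is.null(ev$dRH_drop)) 15 else ev$dRH_drop
    ev_days <- seq(ev_start, by = "day", length.out = len)
    cs_dates <- c(cs_dates, ev_days)
    idx <- day %in% ev_days
    ws[idx] <- stag_ws
    surge_idx <- day %in% ev_days[seq_len(min(surge_days, len))]
    ws[surge_idx] <- surge_ws
    wd[idx] <- off_dir
    temp_adj[idx] <- temp_adj[idx] - dT
    rh_adj[idx] <- rh_adj[idx] - dRH
  }
  sb_truth <- data.frame(date = dates, is_sb = FALSE, onset = NA_real_,
                         duration_h = NA_real_, delta_t = NA_real_)
  sst <- data.frame(date = dates, sst = cfg$sst_default)
  for (sb in cfg$sb_days) {
    d <- as.Date(sb$date)
    i <- match(d, dates)
    onset_off <- if (is.null(sb$onset_offset)) 2 else sb$onset_offset
    run_len <- if (is.null(sb$run_length)) 8 else sb$run_length
    on_ws <- if (is.null(sb$onshore_ws)) 1.1 else sb$onshore_ws
    off_ws <- if (is.null(sb$offshore_ws)) 1.0 else sb$offshore_ws
    dT <- if (is.null(sb$delta_t)) 5 else sb$delta_t
    sr_h <- sun$sunrise_h[i]
    ss_h <- sun$sunset_h[i]
    onset_h <- ceiling(sr_h + 2) + onset_off
    run_hours <- onset_h:(onset_h + run_len - 1L)
    didx <- which(day == d)
    # night and morning offshore, gap calm, onshore run, evening offshore
    morning <- didx[hr[didx] <= floor(sr_h + 2)]
    gap <- didx[hr[didx] > floor(sr_h + 2) & hr[didx] < onset_h]
    run <- didx[hr[didx] %in% run_hours]
    evening <- didx[hr[didx] > max(run_hours)]
    ws[morning] <- off_ws; wd[morning] <- off_dir
    ws[gap] <- 0.2; wd[gap] <- off_dir
    ws[run] <- on_ws; wd[run] <- on_dir
    ws[evening] <- off_ws; wd[evening] <- off_dir
    sb_truth$is_sb[i] <- TRUE
    sb_truth$onset[i] <- onset_h
    sb_truth$duration_h[i] <- run_len
    # planted contrast: daytime land mean minus SST equals delta_t
    land_day <- cfg$temp_mean +
      mean(cfg$temp_amp * cos(2 * pi * (seq(ceiling(sr_h), floor(ss_h)) - 14)
                              / 24)) + mean(temp_adj[didx])
    sst$sst[i] <- land_day - dT
  }

  # emission multiplier per day
  emis_mult <- rep(1, length(dates))
  for (ev in cfg$emission_events)
    emis_mult[dates %in% as.Date(ev$dates)] <- ev$factor

  # secondary perturbation per hour
  pm_boost <- rep(0, n)
  nox_dep <- rep(0, n)
  so2_dep <- rep(0, n)
  for (sp in cfg$secondary_episodes) {
    idx <- day %in% as.Date(sp$dates)
    pm_boost[idx] <- if (is.null(sp$pm_boost)) 0.3 else sp$pm_boost
    nox_dep[idx] <- if (is.null(sp$nox_depletion)) 0.2 else sp$nox_depletion
    so2_dep[idx] <- if (is.null(sp$so2_depletion)) 0.2 else sp$so2_depletion
  }

  # shared met fields (noise-free)
  temp0 <- cfg$temp_mean + cfg$temp_amp * cos(2 * pi * (hr - 14) / 24) +
    temp_adj
  rh0 <- pmin(100, pmax(5, cfg$rh_mean - cfg$rh_amp *
                          cos(2 * pi * (hr - 14) / 24) + rh_adj))
  gr0 <- pmax(0, 850 * sin(pi * (hr - 6) / 12)) * (hr >= 6 & hr <= 18)
  cc0 <- rep(5, n) + ifelse(temp_adj < 0, -2, 0)

  box_model <- function(E_hourly, k, wind, bg) {
    C <- numeric(n)
    C[1] <- bg
    for (t in seq_len(n - 1L))
      C[t + 1L] <- max(bg, C[t] + E_hourly[t] - k * wind[t] * (C[t] - bg))
    C
  }

  noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else 0

  stations <- lapply(seq_len(cfg$n_stations), function(s) {
    E <- cfg$emission[s] * emis_mult[match(day, dates)]
    pm0 <- box_model(E, cfg$k_vent, ws, cfg$background_pm25)
    co0 <- box_model(E * cfg$co_emission_ratio, cfg$k_vent, ws,
                     cfg$co_background)
    pm_obs <- pm0 * (1 + pm_boost)
    nox0 <- cfg$nox_per_co * co0 * (1 - nox_dep)
    so20 <- cfg$so2_per_co * co0 * (1 - so2_dep)
    vals <- data.frame(
      pm25 = pmax(0, pm_obs + noise(cfg$noise_sd$pm25)),
      pm10 = pmax(0, pm_obs * 1.6 + noise(cfg$noise_sd$pm25)),
      co = pmax(0.01, co0 + noise(cfg$noise_sd$co)),
      nox = pmax(0, nox0 + noise(cfg$noise_sd$nox)),
      so2 = pmax(0, so20 + noise(cfg$noise_sd$so2)),
      temp = temp0 + noise(cfg$noise_sd$temp),
      rh = pmin(100, pmax(0, rh0 + noise(cfg$noise_sd$rh))),
      ws = pmax(0, ws + noise(cfg$noise_sd$ws)),
      wd = (wd + noise(cfg$noise_sd$wd)) %% 360,
      gr = pmax(0, gr0 + noise(cfg$noise_sd$gr)),
      cc = pmin(10, pmax(0, cc0 + noise(cfg$noise_sd$cc))))
    list(series = station_series(metas[[s]], time, vals), pm_truth = pm_obs)
  })

  # --- derived ground truth from the noise-free fields -------------------
  truth_daily <- do.call(rbind, lapply(seq_along(stations), function(s) {
    x <- stations[[s]]$pm_truth
    m <- tapply(x, day, mean)
    data.frame(date = as.Date(names(m)), station_id = metas[[s]]$station_id,
               variable = "pm25", mean = as.numeric(m),
               n_valid = 24L, completeness = 1)
  }))
  cal <- compute_haze_days(truth_daily)
  eps <- segment_episodes(cal)
  cs_calendar <- data.frame(date = dates, cs_flag = dates %in% cs_dates)
  truth_sb <- data.frame(date = dates, classifiable = TRUE,
                         is_sb = sb_truth$is_sb)
  if (nrow(eps)) {
    # pad the CS calendar backwards so the pre-haze window is covered
    pad <- data.frame(date = seq(min(dates) - 7, min(dates) - 1, by = "day"),
                      cs_flag = FALSE)
    eps <- classify_episodes(eps, rbind(pad, cs_calendar), truth_sb)
    sec_dates <- as.Date(unlist(lapply(cfg$secondary_episodes,
                                       function(sp) as.character(sp$dates))))
    eps$secondary <- vapply(seq_len(nrow(eps)), function(i)
      any(seq(eps$start[i], eps$end[i], by = "day") %in% sec_dates),
      logical(1))
  }
  structure(list(stations = lapply(stations, `[[`, "series"), sst = sst,
                 cs_calendar = cs_calendar,
                 truth = list(sb = sb_truth, cs_dates = cs_dates,
                              haze_calendar = cal, episodes = eps),
                 config = cfg),
            class = "scenario")
}

#' Write a scenario to the CSV dialects the pipeline reads
#'
#' One station CSV per station (via [write_station_csv()]), `sst.csv`
#' (`date,sst`), `cs_calendar.csv` (`date,cs_flag`), `stations.csv`
#' (metadata), and `truth.json` with the planted ground truth.
#'
#' @param scenario A `scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_rows <- list()
  for (st in scenario$stations) {
    write_station_csv(st, file.path(dir, paste0(st$meta$station_id, ".csv")))
    meta_rows[[length(meta_rows) + 1L]] <-
      data.frame(station_id = st$meta$station_id, lat = st$meta$latitude,
                 lon = st$meta$longitude, province = st$meta$province,
                 background = st$meta$background,
                 utc_offset = st$meta$utc_offset)
  }
  utils::write.csv(do.call(rbind, meta_rows),
                   file.path(dir, "stations.csv"), row.names = FALSE)
  utils::write.csv(scenario$sst, file.path(dir, "sst.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$cs_calendar, file.path(dir, "cs_calendar.csv"),
                   row.names = FALSE)
  tr <- scenario$truth
  jsonlite::write_json(
    list(sb_dates = format(tr$sb$date[tr$sb$is_sb]),
         cs_dates = format(tr$cs_dates),
         haze_dates = format(tr$haze_calendar$date[tr$haze_calendar$haze]),
         episodes = if (nrow(tr$episodes))
           data.frame(start = format(tr$episodes$start),
                      end = format(tr$episodes$end),
                      type = tr$episodes$type,
                      secondary = tr$episodes$secondary)
         else list()),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Compare pipeline output against planted ground truth
#'
#' Per-stage confusion summaries: sea-breeze sensitivity and specificity
#' over classifiable days, haze-day exactness, episode-day Jaccard overlap,
#' type accuracy over matched episodes (matched by day overlap), and
#' secondary-flag accuracy.
#'
#' @param truth The `truth` element of a `scenario`.
#' @param sb_days Detected `sea_breeze_days` (or NULL to skip).
#' @param cal Detected `haze_calendar` (or NULL).
#' @param episodes Detected typed `haze_episodes` (or NULL).
#' @return A list of recovery statistics.
#' @export
evaluate_recovery <- function(truth, sb_days = NULL, cal = NULL,
                              episodes = NULL) {
  out <- list()
  if (!is.null(sb_days)) {
    m <- match(as.Date(sb_days$date), truth$sb$date)
    if (anyNA(m)) stop("sb_days dates outside scenario span", call. = FALSE)
    keep <- sb_days$classifiable
    det <- sb_days$is_sb[keep]
    pl <- truth$sb$is_sb[m][keep]
    out$sb_sensitivity <- if (any(pl)) sum(det & pl) / sum(pl) else NA_real_
    out$sb_specificity <- if (any(!pl)) sum(!det & !pl) / sum(!pl)
    else NA_real_
  }
  if (!is.null(cal)) {
    m <- match(cal$date, truth$haze_calendar$date)
    if (anyNA(m)) stop("calendar dates outside scenario span", call. = FALSE)
    out$haze_day_agreement <-
      mean(cal$haze == truth$haze_calendar$haze[m])
  }
  if (!is.null(episodes)) {
    span_days <- function(e) if (!nrow(e)) as.Date(character(0)) else
      do.call(c, lapply(seq_len(nrow(e)), function(i)
        seq(e$start[i], e$end[i], by = "day")))
    dd <- span_days(episodes)
    dt <- span_days(truth$episodes)
    out$episode_day_jaccard <-
      if (length(union(dd, dt)) == 0) NA_real_
      else length(intersect(dd, dt)) / length(union(dd, dt))
    if (nrow(truth$episodes) && "type" %in% names(episodes)) {
      matched <- vapply(seq_len(nrow(truth$episodes)), function(i) {
        tdays <- seq(truth$episodes$start[i], truth$episodes$end[i],
                     by = "day")
        ov <- vapply(seq_len(nrow(episodes)), function(j)
          length(intersect(seq(episodes$start[j], episodes$end[j],
                               by = "day"), tdays)), integer(1))
        if (!length(ov) || max(ov) == 0) NA_integer_ else which.max(ov)
      }, integer(1))
      ok <- !is.na(matched)
      out$type_accuracy <- if (!any(ok)) NA_real_ else
        mean(episodes$type[matched[ok]] == truth$episodes$type[ok])
      if ("secondary" %in% names(episodes) &&
          "secondary" %in% names(truth$episodes))
        out$secondary_accuracy <- if (!any(ok)) NA_real_ else
          mean(episodes$secondary[matched[ok]] ==
                 truth$episodes$secondary[ok])
    }
  }
  out
}
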