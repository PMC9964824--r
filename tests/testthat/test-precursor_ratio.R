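test_that("daily ratios are ratios of daytime means", {
  # constant pm25 60, co 1 -> pm25_co 60
  s <- constant_days(1, pm25 = 60, co = 1, nox = 50, so2 = 2)
  rd <- daytime_ratios(s)
  expect_true(rd$valid)
  expect_equal(rd$pm25_co, 60)
  expect_equal(rd$nox_co, 50)

  # alternating hours distinguish ratio-of-means from mean-of-ratios:
  # pm25 {40, 80}, co {0.5, 1.5} -> 60/1 = 60 (mean of ratios would be 66.7)
  pm <- rep(c(40, 80), 12)
  co <- rep(c(0.5, 1.5), 12)
  s2 <- make_series(list(pm25 = pm, co = co))
  rd2 <- daytime_ratios(s2, window = c(6, 7))
  expect_equal(rd2$pm25_co, 60)

  # all CO missing -> invalid day
  s3 <- make_series(list(pm25 = rep(60, 24), co = rep(NA_real_, 24)))
  expect_false(daytime_ratios(s3)$valid)
})

test_that("ratios survive a common emission scaling, flags unchanged", {
  set.seed(41)
  base <- list(pm25 = runif(24, 30, 90), co = runif(24, 0.4, 1.2),
               nox = runif(24, 20, 60), so2 = runif(24, 1, 4))
  r1 <- daytime_ratios(make_series(base))
  r3 <- daytime_ratios(make_series(lapply(base, `*`, 3)))
  expect_equal(r3$pm25_co, r1$pm25_co, tolerance = 1e-12)
  expect_equal(r3$nox_co, r1$nox_co, tolerance = 1e-12)
  expect_equal(r3$so2_co, r1$so2_co, tolerance = 1e-12)
})

test_that("season year maps November onward to the next named year", {
  expect_equal(season_year(as.Date(c("2019-11-01", "2019-12-31",
                                     "2020-01-15", "2020-10-31"))),
               rep(2020L, 4))
  expect_equal(season_year(as.Date("2019-10-31")), 2019L)
})

test_that("clean baseline averages DJF non-haze days of the season year", {
  dates <- seq(as.Date("2019-12-01"), as.Date("2020-02-28"), by = "day")
  rd <- data.frame(date = dates, pm25_co = 50, nox_co = 40, so2_co = 2,
                   valid = TRUE)
  rd$pm25_co[1:2] <- c(50, 63)
  haze_dates <- dates[10:20]
  cal <- data.frame(date = dates, haze = dates %in% haze_dates)
  base <- season_clean_baseline(rd, cal, 2020)
  expect_equal(base$n_clean_days, length(dates) - 11)
  # two-day toy check of the averaging itself
  rd2 <- rd[1:12, ]
  rd2$valid <- c(TRUE, TRUE, rep(FALSE, 10))
  expect_error(season_clean_baseline(rd2, cal, 2020), "clean days")
  b2 <- season_clean_baseline(rd2, cal, 2020, min_clean_days = 2)
  expect_equal(b2$pm25_co, 56.5)

  # an episode in Jan 2020 is compared against DJF of season year 2020;
  # Dec 2020 days belong to season year 2021 and are excluded
  rd3 <- rbind(rd, data.frame(date = as.Date("2020-12-01") + 0:30,
                              pm25_co = 999, nox_co = 999, so2_co = 999,
                              valid = TRUE))
  cal3 <- data.frame(date = rd3$date, haze = rd3$date %in% haze_dates)
  b3 <- season_clean_baseline(rd3, cal3, 2020)
  expect_lt(b3$pm25_co, 60)
})

test_that("comparison rule: strict increases/decreases, ties are no change", {
  # episode with both precursors falling
  cmp <- compare_ratio_means(list(pm25_co = 56.5, nox_co = 55.9,
                                  so2_co = 2.9),
                             list(pm25_co = 57.2, nox_co = 53.1,
                                  so2_co = 2.5))
  expect_true(cmp$pm_up && cmp$nox_down && cmp$so2_down)
  expect_true(cmp$secondary_flag)
  expect_equal(cmp$category, "sulfate+nitrate")

  # SO2 tie is not a decrease -> nitrate-only
  cmp2 <- compare_ratio_means(list(pm25_co = 52.8, nox_co = 50.3,
                                   so2_co = 1.7),
                              list(pm25_co = 63.7, nox_co = 44.8,
                                   so2_co = 1.7))
  expect_false(cmp2$so2_down)
  expect_equal(cmp2$category, "nitrate-only")

  # identical means -> nothing flagged
  same <- list(pm25_co = 50, nox_co = 40, so2_co = 2)
  cmp3 <- compare_ratio_means(same, same)
  expect_false(cmp3$pm_up)
  expect_false(cmp3$secondary_flag)
  expect_equal(cmp3$category, "none")

  # missing episodic SO2 can never count as a decrease
  cmp4 <- compare_ratio_means(list(pm25_co = 47, nox_co = 36.7,
                                   so2_co = 2.1),
                              list(pm25_co = 51.7, nox_co = 31.2,
                                   so2_co = NA_real_))
  expect_false(cmp4$so2_down)
  expect_equal(cmp4$category, "nitrate-only")
})

test_that("secondary flag is never raised without a PM2.5/CO increase", {
  set.seed(42)
  for (i in 1:100) {
    clean <- list(pm25_co = runif(1, 40, 70), nox_co = runif(1, 30, 60),
                  so2_co = runif(1, 1, 4))
    episodic <- list(pm25_co = clean$pm25_co - runif(1, 0, 10),
                     nox_co = runif(1, 30, 60), so2_co = runif(1, 1, 4))
    expect_false(compare_ratio_means(clean, episodic)$secondary_flag)
  }
})

test_that("episode screening averages episode days and applies the rule", {
  dates <- seq(as.Date("2019-12-01"), as.Date("2020-01-31"), by = "day")
  rd <- data.frame(date = dates, pm25_co = 50, nox_co = 40, so2_co = 2,
                   valid = TRUE)
  ep_days <- as.Date("2020-01-20") + 0:2
  rd$pm25_co[rd$date %in% ep_days] <- c(60, 64, 62)
  rd$nox_co[rd$date %in% ep_days] <- c(35, 33, 37)
  cal <- data.frame(date = dates, haze = dates %in% ep_days)
  ep <- data.frame(episode_id = 9L, start = ep_days[1], end = ep_days[3])
  base <- season_clean_baseline(rd, cal, 2020)
  out <- compare_episode_ratios(ep, rd, base)
  expect_equal(out$pm25_co_episodic, 62)
  expect_equal(out$nox_co_episodic, 35)
  expect_true(out$pm_up && out$nox_down && !out$so2_down)
  expect_equal(out$category, "nitrate-only")
  expect_true(out$secondary_flag)
})
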