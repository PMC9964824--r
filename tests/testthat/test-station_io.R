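test_that("reading a station CSV completes the hourly grid", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,pm25",
               "2022-01-01T00:00:00,10",
               "2022-01-01T01:00:00,12",
               "2022-01-01T03:00:00,14"), path)
  s <- read_station_csv(path, bkk_meta())
  expect_length(s$time, 4L)
  expect_equal(s$values$pm25, c(10, 12, NA, 14))
  expect_equal(s$qc$pm25, c("valid", "valid", "missing", "valid"))
})

test_that("duplicate timestamps and bad datetimes are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,pm25",
               "2022-01-01T05:00:00,10",
               "2022-01-01T05:00:00,11"), path)
  expect_error(read_station_csv(path, bkk_meta()), "duplicate")
  writeLines(c("datetime,pm25", "not-a-date,10"), path)
  expect_error(read_station_csv(path, bkk_meta()), "datetime")
})

test_that("CSV round-trip preserves values and missingness", {
  s <- make_series(list(pm25 = c(10.123456789, NA, 30.5, 1000.25),
                        temp = c(25.1, 26.2, NA, 24.4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_station_csv(s, path)
  s2 <- read_station_csv(path, s$meta)
  expect_identical(s2$values$pm25, s$values$pm25)
  expect_identical(s2$values$temp, s$values$temp)
})

test_that("range screening masks only out-of-range values and is idempotent", {
  s <- make_series(list(temp = c(55, 25, -10, 50),
                        rh = c(100, 0, 101, 50),
                        ws = c(-1, 0, 3, 60)))
  q <- suppressMessages(apply_qc(s))
  expect_equal(q$values$temp, c(NA, 25, NA, 50))   # closed [-5, 50]
  expect_equal(q$values$rh, c(100, 0, NA, 50))     # 100% retained
  expect_equal(q$values$ws, c(NA, 0, 3, NA))
  expect_equal(q$qc$temp, c("out_of_range", "valid", "out_of_range", "valid"))
  q2 <- suppressMessages(apply_qc(q))
  expect_identical(q2$values, q$values)
  expect_identical(q2$qc, q$qc)
})

test_that("donor regression reproduces an exact affine relation", {
  set.seed(7)
  n <- 100
  du <- rnorm(n, 0, 2)
  dv <- rnorm(n, 1, 2)
  donor <- series_from_uv(du, dv)
  tu <- 2 * du + 1
  tv <- -0.5 * dv + 2
  target <- series_from_uv(tu, tv)
  gap <- c(40, 60)  # isolated missing hours
  target$values$ws[gap] <- NA
  target$values$wd[gap] <- NA
  filled <- gap_fill_wind_from_donor(target, donor)
  got <- hazemet:::wind_to_uv(filled$values$ws[gap], filled$values$wd[gap])
  expect_equal(got$u, 2 * du[gap] + 1, tolerance = 1e-8)
  expect_equal(got$v, -0.5 * dv[gap] + 2, tolerance = 1e-8)
  expect_equal(filled$qc$ws[gap], c("gap_filled", "gap_filled"))
})

test_that("gap filling never alters valid hours; identity donor copies values", {
  set.seed(8)
  u <- rnorm(60)
  v <- rnorm(60)
  donor <- series_from_uv(u, v)
  target <- series_from_uv(u, v)
  miss <- c(10, 20, 30, 40, 50)
  target$values$ws[miss] <- NA
  target$values$wd[miss] <- NA
  before <- target$values
  filled <- gap_fill_wind_from_donor(target, donor)
  expect_equal(filled$values$ws[miss], donor$values$ws[miss],
               tolerance = 1e-8)
  expect_equal(filled$values$wd[miss], donor$values$wd[miss],
               tolerance = 1e-8)
  expect_identical(filled$values$ws[-miss], before$ws[-miss])
  expect_identical(filled$values$wd[-miss], before$wd[-miss])
})

test_that("insufficient donor overlap is a fitting error", {
  u <- rnorm(60)
  donor <- series_from_uv(u, u)
  target <- series_from_uv(u, u)
  target$values$ws[11:60] <- NA   # only 10 overlapping valid hours
  target$values$wd[11:60] <- NA
  expect_error(gap_fill_wind_from_donor(target, donor), "overlap")
})

test_that("short gaps are interpolated in components, long gaps left alone", {
  u <- rep(2, 48)
  v <- rep(0, 48)
  u[10:12] <- NA  # 3-hour gap: interpolable
  u[30:35] <- NA  # 6-hour gap: too long
  donor <- series_from_uv(rep(1, 48), rep(1, 48))
  target <- series_from_uv(u, v)
  target$values$ws[c(10:12, 30:35)] <- NA
  target$values$wd[c(10:12, 30:35)] <- NA
  donor$values$ws[c(10:12, 30:35)] <- NA   # donor also missing there
  donor$values$wd[c(10:12, 30:35)] <- NA
  filled <- gap_fill_wind_from_donor(target, donor, min_overlap = 30)
  expect_equal(filled$values$ws[10:12], rep(2, 3), tolerance = 1e-8)
  expect_true(all(is.na(filled$values$ws[30:35])))
})

test_that("daily aggregation applies the completeness threshold", {
  # 24 valid hours at 50
  s <- constant_days(1, pm25 = 50)
  d <- daily_aggregate(s)
  expect_equal(d$mean[d$variable == "pm25"], 50)
  expect_equal(d$completeness[d$variable == "pm25"], 1)

  # 17 valid hours -> absent under the 0.75 default
  s17 <- make_series(list(pm25 = c(rep(60, 17), rep(NA, 7))))
  d17 <- daily_aggregate(s17)
  expect_true(is.na(d17$mean))
  expect_equal(d17$n_valid, 17L)

  # 18 valid hours alternating 40/60 -> mean 50 at completeness 0.75
  s18 <- make_series(list(pm25 = c(rep(c(40, 60), 9), rep(NA, 6))))
  d18 <- daily_aggregate(s18)
  expect_equal(d18$mean, 50)
  expect_equal(d18$completeness, 0.75)
})

test_that("aggregating a constant series returns the constant every day", {
  s <- constant_days(5, pm25 = 42, temp = 30)
  d <- daily_aggregate(s)
  expect_equal(d$mean[d$variable == "pm25"], rep(42, 5))
  expect_equal(d$mean[d$variable == "temp"], rep(30, 5))
})
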