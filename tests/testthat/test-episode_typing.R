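# minimal typed-episode scaffolding
mk_episode <- function(start, duration, id = 1L) {
  start <- as.Date(start)
  data.frame(episode_id = id, start = start,
             end = start + duration - 1L, duration = as.integer(duration))
}
mk_cs <- function(span_start, span_end, cs_dates = as.Date(character(0))) {
  d <- seq(as.Date(span_start), as.Date(span_end), by = "day")
  data.frame(date = d, cs_flag = d %in% as.Date(cs_dates))
}
mk_sb <- function(span_start, span_end, sb_dates = as.Date(character(0))) {
  d <- seq(as.Date(span_start), as.Date(span_end), by = "day")
  data.frame(date = d, classifiable = TRUE, is_sb = d %in% as.Date(sb_dates))
}

test_that("the four types follow the cold-surge/sea-breeze truth table", {
  # CS two days before start, no SB -> Type I
  ep <- mk_episode("2022-01-10", 5)
  out <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31",
                                     "2022-01-08"),
                           mk_sb("2022-01-01", "2022-01-31"))
  expect_equal(out$type, "I")

  # no CS, SB on 4 of 5 days -> Type II (confident: most of the days)
  out2 <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31"),
                            mk_sb("2022-01-01", "2022-01-31",
                                  as.Date("2022-01-10") + 0:3))
  expect_equal(out2$type, "II")
  expect_false(grepl("low confidence", out2$rationale))

  # CS in the pre-haze window and SB on 5 of 10 days -> Type III
  ep10 <- mk_episode("2022-01-10", 10)
  out3 <- classify_episodes(ep10,
                            mk_cs("2022-01-01", "2022-01-31", "2022-01-09"),
                            mk_sb("2022-01-01", "2022-01-31",
                                  as.Date("2022-01-12") + 0:4))
  expect_equal(out3$type, "III")

  # neither influence on a 1-day episode -> Type IV
  ep1 <- mk_episode("2022-01-10", 1)
  out4 <- classify_episodes(ep1, mk_cs("2022-01-01", "2022-01-31"),
                            mk_sb("2022-01-01", "2022-01-31"))
  expect_equal(out4$type, "IV")
})

test_that("CS days count only inside the pre-haze-to-mid-episode scan", {
  ep <- mk_episode("2022-01-10", 6)  # scan = [Jan 7, Jan 12]
  before <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31",
                                        "2022-01-06"),
                              mk_sb("2022-01-01", "2022-01-31"))
  expect_equal(before$type, "IV")  # CS 4 days before start: outside window
  late <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31",
                                      "2022-01-14"),
                            mk_sb("2022-01-01", "2022-01-31"))
  expect_equal(late$type, "IV")    # CS in the episode's second half
  inside <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31",
                                        "2022-01-12"),
                              mk_sb("2022-01-01", "2022-01-31"))
  expect_equal(inside$type, "I")
})

test_that("a sparse sea-breeze Type II carries a low-confidence note", {
  ep <- mk_episode("2022-01-10", 6)  # 2 SB days of 6: fraction 1/3
  out <- classify_episodes(ep, mk_cs("2022-01-01", "2022-01-31"),
                           mk_sb("2022-01-01", "2022-01-31",
                                 as.Date("2022-01-10") + 0:1))
  expect_equal(out$type, "II")
  expect_true(grepl("low confidence", out$rationale))
})

test_that("types partition episodes and respond monotonically to added days", {
  set.seed(31)
  for (i in 1:40) {
    dur <- sample(1:12, 1)
    ep <- mk_episode("2022-01-10", dur)
    cs_d <- as.Date("2022-01-01") + sample(0:30, sample(0:3, 1))
    sb_d <- as.Date("2022-01-01") + sample(0:30, sample(0:6, 1))
    cs <- mk_cs("2022-01-01", "2022-01-31", cs_d)
    sb <- mk_sb("2022-01-01", "2022-01-31", sb_d)
    t0 <- classify_episodes(ep, cs, sb)$type
    expect_true(t0 %in% c("I", "II", "III", "IV"))
    # adding a CS day inside the scan keeps or gains CS influence
    cs2 <- cs
    cs2$cs_flag[cs2$date == ep$start] <- TRUE
    t_cs <- classify_episodes(ep, cs2, sb)$type
    expect_true(t_cs %in% c("I", "III"))
    if (t0 %in% c("II", "III")) expect_equal(t_cs, "III")
    # adding SB days keeps or gains SB influence
    sb2 <- sb
    sb2$is_sb[sb2$date >= ep$start & sb2$date <= ep$end] <- TRUE
    t_sb <- classify_episodes(ep, cs, sb2)$type
    expect_true(t_sb %in% c("II", "III"))
    if (t0 %in% c("I", "III")) expect_equal(t_sb, "III")
  }
})

test_that("per-type summary pools days, reports NA SB stats for SB-free types", {
  dates <- as.Date("2022-01-01") + 0:19
  daily <- daily_pm25(dates, list(A = c(rep(30, 5), rep(60, 5), rep(30, 5),
                                        rep(70, 5)),
                                  B = c(rep(30, 5), rep(60, 5), rep(30, 5),
                                        rep(70, 5))))
  cal <- compute_haze_days(daily)
  eps <- segment_episodes(cal)
  eps <- episode_stats(eps, daily)
  cs <- mk_cs("2021-12-25", "2022-01-31", "2022-01-05")
  sb <- mk_sb("2022-01-01", "2022-01-31", as.Date("2022-01-16") + 0:4)
  sb$duration_h <- ifelse(sb$is_sb, 8, NA)
  sb$penetration_km <- ifelse(sb$is_sb, 30, NA)
  eps <- classify_episodes(eps, cs, sb)
  expect_equal(eps$type, c("I", "II"))
  rf <- data.frame(date = dates, RF = rep(0.2, 20))
  ts <- type_summary(eps, daily, rf, sb, cal)
  pm_mean <- ts[ts$variable == "pm25" & ts$stat == "mean", ]
  expect_equal(pm_mean$type_I, 60)
  expect_equal(pm_mean$type_II, 70)
  expect_equal(pm_mean$clean, 30)
  sbd <- ts[ts$variable == "sb_duration_h" & ts$stat == "mean", ]
  expect_true(is.na(sbd$type_I))   # no SB days under Type I
  expect_equal(sbd$type_II, 8)
})
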