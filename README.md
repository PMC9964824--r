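# hazemet

Detection and meteorological typing of urban PM2.5 haze episodes for a
coastal city, with sea-breeze classification, wind recirculation, and a
CO-normalized precursor-ratio screen for secondary aerosols.

## The problem

Winter haze over a tropical coastal megacity is driven less by changes in
emissions than by how the local meteorology traps or recycles them. Two
synoptic/mesoscale actors dominate: **cold surges** (CS) — intrusions of
cool, dry air from the Siberian–Mongolian high that arrive windy and then
leave days of calm, stagnant air — and the **sea breeze** (SB), whose
daytime onshore flow both recirculates pollutants back over the city and
caps vertical mixing under a thermal internal boundary layer. `hazemet`
turns that analysis into a reusable, tested pipeline for hourly
multi-station air-quality and surface-weather records, for air-quality
scientists and environmental-health analysts who need episode-level
classifications rather than raw time series.

## What it computes

* **Haze days and episodes.** A *haze day* is a local calendar day whose
  24-h mean PM2.5 exceeds 50 µg m⁻³ (strictly) at ≥ 2 stations. Episodes
  are maximal runs of haze days, optionally bridging 1–2 intervening clean
  days; an episode longer than 7 days is *persistent*. Each episode carries
  the mean, sample SD and coefficient of variation (cv = σ/μ) of the daily
  cross-station PM2.5.
* **Sea-breeze days.** Four surface criteria on a coastal station: (a)
  offshore/calm majority from 6 h before to 2 h after sunrise, (b) ≥ 2
  consecutive onshore hours between sunrise+2 h and sunset+2 h, (c)
  offshore/calm majority in the post-breeze evening window, and (d)
  daytime land–sea temperature contrast ΔT > 3 °C. Sunrise/sunset come
  from the standard solar-position algorithm. SB duration is the longest
  onshore run; penetration is its integrated inland displacement (km).
* **Recirculation factor.** Over the 10:00–18:00 LT window,
  RF = 1 − √(X² + Y²) / WR with X = T·Σuᵢ, Y = T·Σvᵢ and wind run
  WR = T·Σ√(uᵢ² + vᵢ²): 0 for straight-line transport, 1 for a closed
  loop.
* **Episode types.** Type I "cold-surge influenced" (CS, no SB), Type II
  "sea-breeze influenced" (SB, no CS), Type III "synergistic" (both),
  Type IV (neither) — a truth table over CS presence in the pre-haze-to-
  mid-episode scan and the episode's SB-day fraction.
* **Secondary-aerosol screen.** Daytime (06–18 LT) ratios PM2.5/CO,
  NOx/CO, SO2/CO per day (ratio of means, CO as the primary-emission
  tracer); an episode whose PM2.5/CO rises against its season-year
  clean-day (DJF) baseline while NOx/CO and/or SO2/CO fall is flagged for
  potential nitrate/sulfate formation.
* **Synthetic scenarios.** A seeded generator plants cold surges,
  sea-breeze days, emission events and secondary-aerosol perturbations on
  top of first-order box-model PM dynamics
  `C(t+1) = C(t) + E − k_vent·ws·(C − background)`, and derives ground
  truth by running the detection stages on the noise-free fields — so every
  pipeline stage can be validated end-to-end without any external data.

## Worked example

A noiseless 51-day synthetic winter with two planted cold surges, nine
sea-breeze days and one emission event:

```r
library(hazemet)
cfg <- scenario_config(
  start = "2022-01-01", end = "2022-02-20", seed = 11,
  noise_sd = list(pm25 = 0, co = 0, nox = 0, so2 = 0, temp = 0, rh = 0,
                  ws = 0, wd = 0, gr = 0, cc = 0),
  cs_events = list(list(start = "2022-01-05", length = 5),
                   list(start = "2022-02-01", length = 4)),
  sb_days = lapply(format(c(as.Date("2022-01-15") + 0:3,
                            as.Date("2022-02-04") + 0:4)),
                   function(d) list(date = d)),
  emission_events = list(list(dates = format(as.Date("2022-01-25") + 0:1),
                              factor = 3.5)))
scn <- generate_scenario(cfg)
report <- run_pipeline(stations = scn$stations, sst = scn$sst,
                       cs_calendar = scn$cs_calendar,
                       config = list(months = c(1, 2)))
report$episodes[, c("episode_id", "start", "end", "duration", "type",
                    "mean_pm25", "cv_pm25", "sb_day_fraction")]
```

```
stage detect: 18 haze days, 4 episodes
stage seabreeze: 9 SB days of 49 classifiable (station S01)
stage classify: types I=1 II=1 III=1 IV=1

  episode_id      start        end duration type mean_pm25 cv_pm25 sb_day_fraction
1          1 2022-01-06 2022-01-10        5    I     100.3  0.4022           0.000
2          2 2022-01-15 2022-01-18        4   II      58.7  0.0796           1.000
3          3 2022-01-25 2022-01-26        2   IV      72.7  0.0647           0.000
4          4 2022-02-02 2022-02-08        7  III      72.3  0.2602           0.714
```

Episode 1 is the cold-surge stagnation buildup (PM2.5 climbing past
100 µg m⁻³ with a large day-to-day cv), episode 2 the sea-breeze episode
(every day an SB day, modest PM near 59), episode 3 the emission spike
with neither driver, and episode 4 the synergistic surge-then-breeze
episode. Comparing against the planted truth:

```r
evaluate_recovery(scn$truth, report$sb_days, report$haze_calendar,
                  report$episodes)
#> $sb_sensitivity   [1] 1
#> $sb_specificity   [1] 1
#> $haze_day_agreement [1] 1
#> $episode_day_jaccard [1] 1
#> $type_accuracy    [1] 1
#> $secondary_accuracy [1] 1
```

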