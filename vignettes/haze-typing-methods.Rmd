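---
title: "Methods: haze episode detection, sea-breeze typing, and the precursor-ratio screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haze episode detection, sea-breeze typing, and the precursor-ratio screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazemet)
```

`hazemet` implements an episode-level analysis of urban winter haze at a
tropical coastal city: haze days are detected from multi-station daily
PM2.5, segmented into episodes, attributed to cold-surge and/or sea-breeze
influence, and screened for secondary-aerosol formation. This vignette is
the package's account of the methods, the assumptions behind them, and the
choices made where the underlying procedure was ambiguous.

## Data model and quality control

Hourly station records live on a complete, strictly increasing local-time
grid (`station_series`). Every value carries a QC flag (`valid`,
`missing`, `out_of_range`, `gap_filled`). Screening uses closed
probable-range intervals per variable (`qc_ranges()`): e.g. temperature
−5…50 °C, RH 0…100 %, wind speed 0…50 m s⁻¹. Values outside their range
are masked for all computation; screening is idempotent and never fails.
The study region observes no daylight saving, so local clock times are
stored in a fixed-offset frame and date arithmetic is trivial.

Wind gaps at the pollutant reference station can be filled from a donor
station. Because wind direction is circular, regressing speed and
direction directly produces artifacts at the 0°/360° seam; we therefore
regress the east/north components u = −ws·sin(wd·π/180),
v = −ws·cos(wd·π/180) separately (target on donor, ordinary least
squares over ≥ 48 overlapping valid hours), fill from the fits where the
donor is valid, and close remaining interior gaps of at most 3 h by
linear interpolation in u,v. Three hours is short relative to the diurnal
wind reversal we later classify, so interpolation cannot manufacture a
sea-breeze signature; longer gaps are only ever filled by the donor.

Daily means require 75 % completeness (18 of 24 valid hours). The daily
threshold rule below is sensitive to biased day coverage — a day sampled
only at the afternoon peak would overstate the mean — and 0.75 is the
conventional compromise between bias and data loss.

## Haze days, episodes, and bridging

A date is a haze day when **strictly more than** 50 µg m⁻³ of daily mean
PM2.5 occurs at **two or more** stations. The strict inequality means a
printed 50.0 is clean; the two-station minimum guards against a single
malfunctioning or hyper-local monitor. Days with fewer than two valid
station values cannot qualify and are flagged `data_poor`.

Episodes are maximal runs of haze days; two runs separated by at most two
clean days are merged, the gap recorded as *bridged* (haze conditions
rarely fully reset over one or two days, and the original analysis
includes such days in episodes — its episode-day total exceeds its
haze-day total). Episodes never start or end on a bridged day. Episode
statistics — mean, sample (n−1) SD and coefficient of variation of the
daily cross-station mean PM2.5 — are computed over **all** span days,
bridged included, consistent with that convention; a single-day episode
has SD (and cv) 0 by convention. Two deliberate simplifications:

* Merging is decided on gap length only. The original description also
  required the merged runs to share "a similar kind" of meteorological
  character, but typing depends on segmentation, so conditioning the
  segmentation on the type would be circular. We segment once, then type.
* Calendars restricted to analysis months are segmented within each
  contiguous block of dates, so an episode can never bridge a season
  boundary.

The segmentation core is validated two ways: against a fixpoint oracle
that repeatedly merges adjacent spans, and — exhaustively, for every
calendar of up to 20 days — against an independent nearest-neighbour
formulation (a clean day is bridged iff its nearest haze days on both
sides leave a gap ≤ 2).

## Solar geometry and the sea-breeze criteria

Sunrise and sunset are computed (declination and equation-of-time series,
hour angle at −0.833° solar altitude) rather than looked up, for
reproducibility; the ±3 min accuracy is immaterial against hourly data.

A sea-breeze (SB) day must pass four criteria at the coastal reference
station:

| criterion | window | rule |
|---|---|---|
| (a) | sunrise − 6 h … sunrise + 2 h | offshore or calm for a strict majority of valid hours |
| (b) | sunrise + 2 h … sunset + 2 h | ≥ 2 consecutive onshore hours |
| (c) | sunset + 2 h … sunset + 8 h | offshore or calm for a strict majority |
| (d) | sunrise … sunset | mean land T − daily SST > 3 °C |

Ambiguities resolved here: "majority" is strictly more than half of the
valid hours; "calm" is below 0.5 m s⁻¹ (a common anemometer stall
threshold); and the criterion (c) window as originally worded ("two hours
after **sunrise** to eight hours after sunset") overlaps criterion (b)
and would ask the breeze itself to blow offshore — we read it as a typo
for the sunset-anchored window above, and both anchors remain
configurable (`c_window`). Wind sectors depend on the coastline and are
configuration, not inference; the defaults (onshore 135–255°, offshore
315–75°, coast normal 15°) suit a south-facing gulf coastline. Each
criterion window requires 75 % valid wind hours, otherwise the day is
unclassifiable and excluded from statistics.

SB **duration** is the length of the longest onshore run in the (b)
window (the original does not say how multiple runs are handled; the
longest run is the breeze, shorter ones are transients). **Penetration**
is the run's integrated inland displacement: the positive part of each
hourly wind vector projected on the inland coast normal, summed, × 3.6 km
per (m s⁻¹ h). No penetration formula is given in the original; this
integrated-displacement estimate reproduces the right magnitude (an 8-h
run near 1.1 m s⁻¹ gives ≈ 32 km, matching the reported ~31.6 km mean).

## Recirculation factor

Over the daytime window 10:00–18:00 LT (nine hourly samples, T = 1 h):

$$X = T\sum u_i,\quad Y = T\sum v_i,\quad WR = T\sum\sqrt{u_i^2+v_i^2},
\quad RF = 1 - \frac{\sqrt{X^2+Y^2}}{WR}.$$

One transcription note: the wind-run formula is sometimes printed as
$WR = T\sum\sqrt{X^2+Y^2}$, which would make RF identically zero; the
total wind run is of course the summed hourly travel distance, as
implemented. By the triangle inequality 0 ≤ RF ≤ 1, RF is invariant to
rotation of the coordinate frame and to uniform speed scaling, and it is
undefined when the wind run is zero or fewer than 75 % of window hours
are valid — all property-tested on random wind days.

## Episode typing

The four types form a truth table over two influences:

* **CS influence**: ≥ 1 cold-surge day between 3 days before the episode
  start and the end of the episode's first half. Cold surges precede the
  stagnation that builds haze — hence the pre-haze window — but reversed
  episodes exist in which the surge arrives after a sea-breeze onset, so
  the scan extends into (half of) the episode.
* **SB influence**: SB days on at least one third of episode days.

Type I = CS only, II = SB only, III = both, IV = neither. "Most of the
days", the narrative bar for a confident pure sea-breeze type, is ½; a
Type II episode whose SB fraction sits in [⅓, ½) keeps the type with a
low-confidence note rather than being forced into Type IV. All four
thresholds (`typing_config()`) are explicit configuration because the
original definitions are narrative; the defaults are the judgment calls
that reproduce its behaviour on planted scenarios. Cold-surge days are an
**input** calendar — they were identified by synoptic-chart inspection,
which this package does not attempt to automate.

Classification is deterministic, partitions episodes (exactly one type
each), and is monotone: adding a CS day can only move an episode toward
{I, III}, adding SB days only toward {II, III} — both property-tested.

## Precursor-ratio screen

CO is a primary-emission tracer: co-emitted with PM and NOx/SO2 by
combustion but chemically long-lived on episode time scales. Per day, the
daytime (06:00–18:00 LT, when fresh morning emissions and later
photochemistry are both sampled) ratios PM2.5/CO, NOx/CO and SO2/CO are
computed as **ratios of means** — the mean of the numerator over the
window divided by the mean CO — not means of hourly ratios, which would
be dominated by low-CO hours. An episode is screened positive when its
mean PM2.5/CO strictly exceeds the clean-day baseline while NOx/CO
and/or SO2/CO strictly fall (gas-to-particle conversion to nitrate and/or
sulfate). Ties are "no change", and a missing episodic SO2 never counts
as a decrease — both conventions are required to reproduce the published
13-episode screening outcome (5 sulfate+nitrate, 8 nitrate-only) that the
acceptance suite recomputes. The baseline is the mean over clean
(non-haze, non-bridged) December–February days of the episode's *season
year* (November of the preceding year through October); "clean days of
the year" is ambiguous in the original, and DJF-only matches the months
actually analysed. A baseline needs ≥ 10 valid clean days.

## The synthetic generator

`generate_scenario()` emulates the statistical structure the detectors
assume, not the atmosphere. PM follows a first-order box model per
station,

$$C(t+1) = C(t) + E - k_\mathrm{vent}\,ws(t)\,(C(t) - C_b),$$

floored at the background $C_b$: emission fills the box, ventilation
empties it in proportion to wind speed. Defaults — background
20 µg m⁻³, emission 4 µg m⁻³ h⁻¹, k_vent 0.1 (m s⁻¹ h)⁻¹ — were fixed
once from iterating the update rule by hand: the 2.5 m s⁻¹ synoptic wind
gives a clean-day equilibrium near 36 µg m⁻³, a ~1 m s⁻¹ sea-breeze day
near 60, and 0.3 m s⁻¹ stagnation climbs through 50 within a day and past
100 in three — the regimes the pipeline must separate. Cold surges are
planted as one to two windy cool onset days followed by calm stagnation
with temperature and humidity drops; sea-breeze days as nocturnal
offshore flow, a daytime onshore run placed inside the criterion (b)
window using the *same* solar routine the classifier uses (so planted
days satisfy criteria (a)–(d) exactly when noise is zero), and an SST
chosen to realise the planted land–sea contrast. CO shares the box
dynamics with proportional emission; NOx and SO2 are proportional to CO,
with planted depletions and PM boosts on secondary-aerosol days.
Measurement noise is Gaussian, independent per variable and station, and
applied after the dynamics, so ground truth — derived by running the
detection stages on the noise-free fields, never asserted — does not
depend on the noise realisation. A seed fixes everything.

What the generator does **not** emulate: advection between stations
(stations differ only in emission and noise), humidity-dependent aerosol
chemistry, boundary-layer depth, synoptic variability beyond the planted
events, or instrument drift and autocorrelated error. Passing recovery
tests therefore demonstrates the pipeline's internal consistency and its
robustness to independent noise — not skill on real records, where the
configuration surface (sectors, thresholds, windows) exists precisely
because those un-modelled effects matter.

## Numerical conventions and degenerate inputs

* Strict inequalities throughout (haze exceedance, ratio comparisons,
  ΔT > 3 °C, majority rules); ties never trigger a detection.
* Sample (n−1) standard deviations; single-day episodes have sd = cv = 0.
* A day with zero valid stations inside an episode is dropped from the
  episode statistics with a warning; an episode day count never includes
  days outside the calendar.
* Wind direction is the direction the wind blows *from*; u,v point where
  the air moves *to*. Calm hours (ws = 0) get wd = 0 on re-derivation.
* RF with zero wind run, baselines with < 10 clean days, and sea-breeze
  days with insufficient valid hours are absent (NA), never zero.

## Problem sizes in the test suite

The shipped tests run synthetic winters of 20–51 days at 2–5 stations,
50 jittered replicates for sea-breeze sensitivity, 1000 random wind days
for the RF properties, and the exhaustive segmentation check over all
2¹ + … + 2²⁰ short calendars — sizes chosen so the full suite completes
in about two minutes on one CPU while still exercising every rule path.

## Known limitations

* Cold-surge identification is consumed, not computed; the pipeline is
  only as good as the supplied CS calendar.
* Typing thresholds are calibrated to planted scenarios, not fitted to
  observations; on real data they are starting points.
* The precursor-ratio method is a screening heuristic — it cannot
  distinguish chemistry from transport, and a single reference station
  carries the whole pollutant suite.
* Episode re-splitting after typing is deliberately not performed; a
  long bridged episode spanning two meteorological regimes is reported
  as one (Type III) episode.
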