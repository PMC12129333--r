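---
title: "Threshold geolocation and migration analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold geolocation and migration analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxtrack)
```

`luxtrack` analyses archival light-logger data from small migratory birds
with the threshold method, from raw light records through to
population-level movement statistics. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## 1. Solar model

Twilight geometry uses a documented low-precision solar series: days since
the J2000 epoch give the sun's mean longitude and mean anomaly as linear
functions of time; two periodic terms yield the ecliptic longitude, and
rotation by the obliquity gives declination and right ascension, hence the
equation of time. This series is accurate to well under 0.1 degrees of
declination and a few seconds of the equation of time — orders of magnitude
finer than threshold geolocation itself, which is good to roughly
100–500 km. The test suite cross-checks it against the independent Spencer
(1971) Fourier series.

Times are decimal hours UTC throughout, dates are calendar days, and a
twilight pair keeps `sunset > sunrise` even when that pushes sunset past
24 h, which avoids midnight-crossing ambiguity at far-eastern longitudes.

Inverting day length for latitude reduces to `A sin φ + B cos φ = C`,
solved in closed form. Two genuine subtleties are handled explicitly:

* **Equinox degeneracy.** Within about nine days of each equinox
  (|declination| < 3.5°, the `equinox_decl` parameter) day length is nearly
  12 h at every latitude; those days are flagged `equinox_degenerate` and
  excluded from latitude work rather than amplified into wild estimates.
  The analysis-level exclusion window (one week either side, Mar 13–27 and
  Sep 15–29) is applied downstream by `flag_equinox()`.
* **Two-root ambiguity.** For sun elevations below the horizon the
  day-length equation can have two latitude solutions on the same date.
  When both fall inside the search band the day is flagged `ambiguous`
  (or resolved by an explicit hemisphere hint), never guessed. The default
  search band, [−40°, 80°], is the plausible envelope of an
  Afro-Palearctic system and is configurable.

## 2. What the tag sees, and the noise model

The simulator (`simulate_track()`, `simulate_twilights()`) generates an
annual cycle patterned on a tagging study of a sub-Saharan-wintering
passerine: a tagging site at 8–10° N in West Africa; with probability 0.25
a secondary sub-Saharan non-breeding site ~500 km away (northward for the
westernmost population, mostly southwest for the other, matching the
geography of land availability); spring departure drawn around 5 April
(SD 6 days); 2–3 stopovers per season spaced roughly evenly along the
great-circle route so legs land on the ~2000-km scale this system shows;
a breeding site at 45–70° N and 16–40° east of the tagging longitude
(Scandinavia and eastern Europe through south-west Russia); ~75 days of
breeding residence; and return by late September/October. Legs travel at a
constant 27 km/h ground speed, so ~2000 km takes ~3.1 days; durations are
kept at half-day resolution. An optional eastward shift of the autumn
stopovers (`loop_shift_lon`) plants a loop migration; an optional failure
date truncates the series as a dying tag would.

Shading — vegetation or the bird's own posture blocking the sensor — can
only *delay* apparent sunrise, *advance* apparent sunset, and hence
*shorten* the apparent day. The noise model is therefore one-sided:
exponential shading with mean 8 min on each twilight, plus symmetric
Gaussian jitter (SD 2 min) for sensor and sampling effects, a 2% chance of
losing a day, and optional linear clock drift. The field literature gives
no quantitative shading distribution; these defaults are the package's own
choice of a realistic regime, not an empirical claim. What the simulator
does **not** emulate: weather systems (correlated multi-day shading),
wind-dependent flight speeds, fuel-dependent behaviour, or light-curve
shape within twilight. Passing tests on synthetic data therefore shows the
pipeline's arithmetic and logic are right under a plausible noise regime,
not that real tags are this well behaved.

## 3. Segmentation

The classic practice is visual: a consistent run of similar sunrise and
sunset times means the bird is stationary; a sudden, consistent change
means it moved. `detect_stationary_periods()` formalises this as a
change-point analysis:

1. a 3-day moving minimum on sunrise and maximum on sunset strips most of
   the one-sided shading (the least-shaded day in the window is closest to
   truth) at the cost of at most one day of smearing;
2. binary segmentation splits the filtered series where the contrast
   between the 5-day medians either side of a candidate day exceeds
   `shift_threshold`, after removing the locally estimated seasonal slope
   — without that detrending, the smooth seasonal change in twilight times
   (up to several min/day at high boreal latitudes) masquerades as
   movement on long residences;
3. segments are labelled migration when their robust twilight velocity
   exceeds what season can explain, judged in the midpoint / day-length
   basis (the midpoint tracks longitude only and drifts < 0.5 min/day; day
   length drifts much faster at high latitude and gets a looser bound), or
   when shorter than `min_stationary` days;
4. adjacent stationary runs a few days apart whose slope-adjusted levels
   agree over wide flanking windows are re-joined: a cluster of heavily
   shaded days can mimic a relocation, but its pseudo-step averages out
   over ten days while a true relocation persists;
5. boundaries are refined day by day: a transition-zone day is claimed by
   the period whose level it matches (midpoint within 2/3 of the
   threshold; least-shaded two-day day length within the threshold), with
   a single unmatched day tolerated inside a period edge as shading.

Defaults: `shift_threshold` = 15 min (a 3.75° longitude shift, just below
the ~17-min twilight shift of the smallest relocation a practised eye
reliably picks out), `cum_threshold` = 30 min for week-scale cumulative
drift, `min_stationary` = 2 days (the detection limit for stopovers).
Migration start/end dates are kept at half-day resolution: departure at
the last stationary sunset (+0.5), arrival by the first stationary sunrise
(+0.0). Days without twilights (missing or polar) inherit the state of the
nearest classified day, except that a gap between migration and a
following stationary run joins that run — an Arctic breeding residence
whose midsummer simply has no twilights.

**Known limitation.** Under the default noise regime the detector recovers
roughly half of true ≥ 3-day residences with both boundaries within one
day (about three quarters with noise-free data); most of the rest are off
by 2–3 days, and relocations whose twilight signature is below threshold —
mostly north–south legs near the equinox and some ~500-km southwest
secondary-site moves, whose longitude component is ~13 min — cannot be
seen at all by any threshold rule. Boundary precision at the ±1-day level
is intrinsically hard when a single heavily shaded day is indistinguishable
from a travel day; treat automated boundaries as ±2–3 days unless confirmed
by inspection.

## 4. Calibration and geolocation

The sun elevation angle is calibrated by grid search (−9° to +3° in 0.1°
steps): the angle whose daily threshold positions minimise the median
great-circle distance to the tagging site, using non-equinox days of the
first stationary period. Because shading shortens the apparent day, the
calibrated angle sits above the geometric twilight angle of the sensor;
that is intended — it absorbs the deployment's average shading into the
angle instead of into a latitude bias. A single angle is applied to the
whole deployment, so between-bird comparisons suffer imprecision but not
systematic bias.

Each stationary period's location is the **median** of its daily threshold
positions (median, not mean, for robustness to residual shading outliers —
a package choice where practice varies), with per-axis standard errors
sd/√n. Polar-day days are excluded from all location arithmetic (an Arctic
residence is located from its shoulder days); equinox-degenerate and
ambiguous days are excluded from latitude only, so longitude keeps its full
sample. Longitude is essentially unbiased under one-sided shading because
shading moves the two twilights toward each other, preserving the midpoint
in expectation; on default-noise simulations the median longitude error is
~0.2° and the median off-equinox latitude error ~1°, consistent with the
100–500 km working accuracy of the method.

## 5. Event table and classification

Movements between consecutive located periods form the event table: one
row per leg with distance (great-circle, Earth radius 6371 km), half-day
duration, speed = distance/(24 × duration), season and equinox flag.
Classification of periods follows the study design:

* *main non-breeding*: within 250 km (`min_displacement`) of the tagging
  site south of 18° N (`sahara_lat`) — covering both the deployment period
  and the post-autumn return;
* *secondary non-breeding*: any other sub-Saharan stationary period of
  ≥ 2 days before the spring Sahara crossing, displaced ≥ 250 km;
* *breeding*: the longest stationary period north of 35° N
  (`breeding_lat_min`, configurable; the floor is the package's own
  reading of a European breeding range) that overlaps boreal summer — the
  summer condition stops a long spring stopover on a truncated track from
  being mistaken for breeding;
* everything else is a *stopover*.

Spring runs from the departure from the last sub-Saharan site to breeding
arrival; autumn from breeding departure to the final non-breeding arrival;
earlier sub-Saharan moves are *intra-African* and can be folded into
spring with the `exclude_subsaharan` toggle, mirroring the
with/without-additional-non-breeding-sites analyses. Stopover counts are
stationary periods strictly between a season's endpoints; the breeding
period is never a stopover. Phenology dates are Julian days (Jan 1 = 1,
leap years honoured). Completeness of a track (full / to breeding / failed
in spring / failed in autumn) is inferred from which endpoints exist.

## 6. Population statistics

*Migratory spread* is the mean great-circle distance over all unordered
pairs of (typically breeding) locations; its interval comes from 10,000
random pairs drawn with replacement from the distinct unordered pairs,
taking the 250th and 9,750th order statistics — a quantile band of the
pairwise-distance distribution, seeded and reproducible.

*Ranges* are minimum convex polygons computed on a Lambert azimuthal
equal-area projection centred on the points' centroid, so planar areas are
spherical areas in km²; overlaps come from Sutherland–Hodgman clipping of
the two convex hulls on a common projection (exact for convex polygons).
An equal-area projection was chosen over spherical-polygon machinery
because the study scale (single-digit millions of km²) makes the
projection error negligible against the location error.

*Loop migration* is the per-bird difference in mean stopover longitude,
autumn minus spring, averaged over birds. Significance comes from a
within-bird permutation test (season labels shuffled within each bird's
own stopovers, preserving sample sizes; add-one-corrected two-sided p),
chosen over a mixed model to keep the statistic assumption-free; the
estimand is unchanged. Its size is verified by a null calibration study.

*Flight-time and fuel arithmetic* are closed-form: hours per migration-leg
day on the ground given a 43 km/h airborne speed; fuel from the linear
rule of ~25 g of reserves per 5000 km, with daily gain spread over the
journey and a deposition rate relative to lean mass. Lean mass has no
default — the literature value this system implies (~13 g) is never stated
explicitly, so it is a required input where used.

## 7. Numerical choices and degenerate inputs

* Latitude inversion: closed form, residual tolerance 1e-8; ambiguity and
  polar/no-solution cases flagged, never guessed.
* Calibration grid step 0.1°, matching the precision with which the angle
  is meaningfully identified; fewer than 10 usable days is an error.
* Sunset may exceed 24 h; longitudes wrap into (−180°, 180°].
* Collinear points are a hard error for convex ranges (with the count of
  distinct points); disjoint polygons give zero overlap, not an error.
* Negative stationary time (observed leg shorter than the flight itself)
  clips to zero with a warning.
* All randomness (simulator, spread resampling, permutations) is seeded;
  reruns are bit-identical.

## 8. Problem sizes used in validation

The shipped tests validate parameter recovery at sizes chosen to keep the
full suite to a few minutes: 100 simulated tracks for segmentation
recovery, 12 birds (~100 stationary periods) for geolocation error, a
16-point cloud for spread, 12 birds for the planted 7.8° loop shift, and
500 null runs at 199 permutations for the test-size calibration. The
vignette's statements about recovery rates are exactly what those runs
measure, no more.
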