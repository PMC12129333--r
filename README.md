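# luxtrack

Light-level geolocation and migration analysis for archival tags
(geolocators) on small migratory birds.

A geolocator records ambient light against time. From the daily sunrise and
sunset it implies, the **threshold method** estimates position: longitude
from the midpoint of the twilight pair (local solar noon, offset from 12:00
UTC by 4 min per degree after correcting for the equation of time), and
latitude from day length, by inverting

    sin a = sin φ sin δ + cos φ cos δ cos H,    H = 7.5°/h × day length

for the latitude φ, given the solar declination δ and a **sun elevation
angle** *a* — the solar altitude at which the particular tag registers
twilight. Because *a* depends on the sensor, the habitat and the bird's
behaviour, it is calibrated where the bird's position is known: the tagging
site, the only place location is certain. Around each equinox day length is
~12 h everywhere, so latitude is unidentifiable for about a week either
side, while longitude stays reliable.

`luxtrack` implements the full analysis pipeline for an annual tracking
study of an Afro-Palearctic passerine (e.g. whinchats tagged at sub-Saharan
non-breeding sites):

* twilight extraction from raw light logs and linear clock-drift correction;
* change-point segmentation of the twilight series into **stationary
  periods** (≥ 2 days) and **migration legs**, robust to the one-sided
  shading error (shading can only delay apparent sunrise and advance
  apparent sunset);
* sun-elevation calibration and threshold geolocation of every stationary
  period, with equinox and polar-day handling;
* a per-leg migration event table: site classification (main/secondary
  non-breeding, stopover, breeding), season assignment, great-circle
  distances, half-day durations, speeds and phenology dates;
* population statistics: **migratory spread** (mean pairwise distance
  between breeding sites, with a randomization CI from 10,000 sampled
  pairs), minimum convex polygon breeding ranges and their overlap,
  loop-migration longitude contrasts with a permutation test, flight-time
  partitioning and fuel-deposition arithmetic;
* a synthetic-track simulator producing twilight series with realistic
  one-sided shading noise and full ground truth, used to validate every
  stage.

## Worked example

Simulate one bird, then run the analysis exactly as for a real tag:

```r
library(luxtrack)

tr  <- simulate_track(bird_id = "whinchat01", country = "Nigeria", seed = 42)
sim <- simulate_twilights(tr, sun_elevation = -3.5,
                          noise = noise_model(), seed = 42)
main <- tr$sites[1, ]   # the tagging site (known)

res <- process_bird(sim$twilights, main$lat, main$lon,
                    bird_id = "whinchat01", country = "Nigeria")

res$calibration$sun_elevation
#> [1] -2.4
head(res$periods[, c("start_date", "end_date", "lat", "lon",
                     "classification")], 3)
#>   start_date   end_date    lat    lon   classification
#> 1 2018-12-01 2019-04-07 11.176  9.113 main_nonbreeding
#> 2 2019-04-12 2019-04-19 20.046 15.159         stopover
#> 3 2019-04-20 2019-04-27 32.047 21.481         stopover
res$summary[, c("completeness", "total_distance_spring",
                "depart_nonbreeding", "arrive_breeding")]
#>   completeness total_distance_spring depart_nonbreeding arrive_breeding
#> 1         full                5592.4                 97             133
```

The calibrated angle (−2.4°) sits above the generating −3.5° because the
calibration deliberately absorbs the average shading of the deployment; the
bird departs its non-breeding site on Julian day 97 (early April), arrives
on the breeding grounds on day 133 and covers ~5600 km in spring, all
within the magnitudes this study system shows. The closed-form movement
arithmetic is available directly:

```r
leg_speed(2043, 3.1)                # km/h ground speed of an average leg
#> [1] 27.45968
stationary_hours_per_day(2008, 3.1) # h/day on the ground at 43 km/h flight
#> [1] 8.936234
```

Cohort-level runs (`run_pipeline()`) add migratory spread, range polygons
and overlap, and the loop-migration contrast, and write CSV/GeoJSON/JSON
artifacts.

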