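# Synthetic annual migration tracks and the twilight series a light logger
# would record along them.  The simulator emulates the study design of an
# Afro-Palearctic passerine tagged at a sub-Saharan non-breeding site
# (8-10 deg N): optional secondary non-breeding sites, a spring departure in
# early April, a handful of stopovers up to a breeding site at 45-70 deg N,
# a breeding residence of ~2.5 months, and a return by the end of
# September.  Every day carries a ground-truth label so each downstream
# stage (segmentation, geolocation, tables, statistics) can be validated
# against known truth.

# spherical linear interpolation along the great circle from p1 to p2
# (lat/lon degrees), fraction f in [0,1]
.gc_interpolate <- function(lat1, lon1, lat2, lon2, f) {
  tovec <- function(lat, lon) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- tovec(lat1, lon1); b <- tovec(lat2, lon2)
  omega <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (omega < 1e-12) return(c(lat = lat1, lon = lon1))
  v <- (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
  c(lat = asin(v[3]) * 180 / pi, lon = atan2(v[2], v[1]) * 180 / pi)
}

.round_half <- function(x) round(x * 2) / 2

#' Default noise model for simulated twilights
#'
#' Shading only ever delays the apparent sunrise and advances the apparent
#' sunset (a bird roosting in cover sees less light, never more), so the
#' shading error is one-sided: exponential with mean `shade_mean` minutes,
#' plus a small symmetric Gaussian jitter for sensor/sampling noise.
#'
#' @param shade_mean mean one-sided shading delay, minutes (default 8).
#' @param jitter_sd symmetric jitter sd, minutes (default 2).
#' @param missing_day_prob probability a day's twilights are lost
#'   (default 0.02).
#' @param clock_drift total linear clock drift over the deployment, minutes
#'   (default 0).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(shade_mean = 8, jitter_sd = 2,
                        missing_day_prob = 0.02, clock_drift = 0) {
  stopifnot(shade_mean >= 0, jitter_sd >= 0,
            missing_day_prob >= 0, missing_day_prob < 1)
  structure(list(shade_mean = shade_mean, jitter_sd = jitter_sd,
                 missing_day_prob = missing_day_prob,
                 clock_drift = clock_drift),
            class = "noise_model")
}

#' Simulate one annual migration track
#'
#' Generates an ordered sequence of sites (main non-breeding, optional
#' secondary non-breeding, spring stopovers, breeding, autumn stopovers,
#' return to the main site) with arrival/departure times at half-day
#' resolution, plus the implied great-circle legs and a per-leg truth table.
#'
#' Defaults emulate the study system: tagging site near 8-10 deg N (west
#' African longitudes), about a quarter of birds using a secondary
#' sub-Saharan site ~500 km away before the Sahara crossing, spring
#' departure in early April, 2-3 stopovers per season, breeding at
#' 45-70 deg N, and return by late September.  Legs travel at a constant
#' ground speed of ~27 km/h (so ~2000 km takes ~3.1 days).
#'
#' @param bird_id identifier stored in the track.
#' @param country `"Liberia"`, `"Nigeria"` or any synthetic label; sets the
#'   default tagging-site coordinates.
#' @param seed integer; every random choice is drawn after `set.seed(seed)`,
#'   so a fixed seed reproduces the track exactly.
#' @param p_secondary probability of a secondary sub-Saharan non-breeding
#'   site (default 0.25).
#' @param secondary_km mean displacement of the secondary site, km
#'   (default 500).
#' @param n_stopovers integer range (min, max) of stopovers per season
#'   (default c(2, 3)).
#' @param breeding_lat_range latitude range for the breeding site
#'   (default c(45, 70)).
#' @param spring_departure mean spring departure date (default "2019-04-05").
#' @param departure_sd sd of the departure date, days (default 6).
#' @param ground_speed leg ground speed, km/h (default 27).
#' @param stopover_mean,stopover_sd stopover duration, days (default 6, 2;
#'   floored at the 2-day detection limit).
#' @param breeding_days mean breeding residence, days (default 75).
#' @param loop_shift_lon eastward shift of autumn stopovers relative to
#'   spring ones, degrees (default 0 = no loop migration).
#' @param fail_date optional `Date`; the tag dies and the series truncates
#'   there.
#' @param deployment_start tagging date (default "2018-12-01").
#' @return object of class `sim_track`: list with `bird_id`, `country`,
#'   `origin` (deployment start date), `sites` (data.frame label, lat, lon,
#'   arrive, depart in days since origin), `legs` (truth table: from, to,
#'   start, end, distance_km, duration_days), `fail_day` (days since
#'   origin or NA).
#' @export
simulate_track <- function(bird_id = "bird01", country = "Nigeria",
                           seed = 1, p_secondary = 0.25,
                           secondary_km = 500, n_stopovers = c(2, 3),
                           breeding_lat_range = c(45, 70),
                           spring_departure = as.Date("2019-04-05"),
                           departure_sd = 6, ground_speed = 27,
                           stopover_mean = 6, stopover_sd = 2,
                           breeding_days = 75, loop_shift_lon = 0,
                           fail_date = NULL,
                           deployment_start = as.Date("2018-12-01")) {
  stopifnot(n_stopovers[1] >= 0, n_stopovers[2] >= n_stopovers[1],
            breeding_lat_range[1] < breeding_lat_range[2],
            ground_speed > 0)
  set.seed(seed)
  origin <- as.Date(deployment_start)

  main <- switch(country,
                 Liberia = c(lat = 8.1, lon = -9.98),
                 Nigeria = c(lat = 9.87, lon = 8.97),
                 c(lat = stats::runif(1, 8, 10),
                   lon = stats::runif(1, -12, 12)))
  main["lat"] <- min(10, max(8, main["lat"] + stats::rnorm(1, 0, 0.3)))

  # breeding grounds lie well to the north-east of the West African
  # non-breeding sites (Scandinavia and eastern Europe through south-west
  # Russia), so routes span substantial longitude as well as latitude
  breeding <- c(lat = stats::runif(1, breeding_lat_range[1],
                                   breeding_lat_range[2]),
                lon = main[["lon"]] + stats::runif(1, 16, 40))

  depart_main <- .round_half(as.numeric(as.Date(spring_departure) - origin) +
                               stats::rnorm(1, 0, departure_sd))

  sites <- list()
  add_site <- function(label, lat, lon, arrive, depart)
    sites[[length(sites) + 1]] <<- data.frame(
      label = label, lat = lat, lon = lon, arrive = arrive, depart = depart)

  leg_duration <- function(km) max(0.5, .round_half(km / (ground_speed * 24)))
  stopover_duration <- function()
    max(2, .round_half(stats::rnorm(1, stopover_mean, stopover_sd)))

  # --- non-breeding season -------------------------------------------------
  has_secondary <- stats::runif(1) < p_secondary
  if (has_secondary) {
    # Liberian birds tend to move north (shortening the migration);
    # Nigerian birds mostly southwest
    bearing <- if (country == "Liberia") stats::runif(1, -20, 20) * pi / 180
    else stats::runif(1, 215, 255) * pi / 180
    km <- max(300, stats::rnorm(1, secondary_km, 50))
    dlat <- km * cos(bearing) / 111.2
    dlon <- km * sin(bearing) / (111.2 * cos(main[["lat"]] * pi / 180))
    sec <- c(lat = main[["lat"]] + dlat, lon = main[["lon"]] + dlon)
    sec_days <- max(13, .round_half(stats::rnorm(1, 28, 5)))
    leg1 <- leg_duration(haversine(main["lat"], main["lon"],
                                   sec["lat"], sec["lon"]))
    depart_sec <- depart_main
    arrive_sec <- depart_sec - sec_days
    add_site("main_nonbreeding", main[["lat"]], main[["lon"]],
             0, arrive_sec - leg1)
    add_site("secondary_nonbreeding", sec[["lat"]], sec[["lon"]],
             arrive_sec, depart_sec)
    from <- sec
  } else {
    add_site("main_nonbreeding", main[["lat"]], main[["lon"]], 0, depart_main)
    from <- main
  }

  # --- spring migration ----------------------------------------------------
  n_sp <- sample(seq(n_stopovers[1], n_stopovers[2]), 1)
  t <- sites[[length(sites)]]$depart
  # stopovers spaced roughly evenly along the great-circle route, so leg
  # lengths land near the ~2000-km scale this study system shows; jitter
  # keeps them off the exact route without ever stacking two stopovers
  # within a single leg's detection limit
  place_stopovers <- function(from, to, n, lon_shift = 0) {
    if (n == 0) return(NULL)
    f <- (seq_len(n)) / (n + 1) + stats::runif(n, -0.06, 0.06)
    do.call(rbind, lapply(f, function(ff) {
      p <- .gc_interpolate(from[["lat"]], from[["lon"]],
                           to[["lat"]], to[["lon"]], ff)
      data.frame(lat = p[["lat"]] + stats::rnorm(1, 0, 1),
                 lon = p[["lon"]] + stats::rnorm(1, 0, 1.5) + lon_shift)
    }))
  }
  sp_stops <- place_stopovers(from, breeding, n_sp)
  prev <- from
  if (!is.null(sp_stops)) for (k in seq_len(nrow(sp_stops))) {
    s <- c(lat = sp_stops$lat[k], lon = sp_stops$lon[k])
    dur <- leg_duration(haversine(prev["lat"], prev["lon"], s["lat"], s["lon"]))
    arrive <- t + dur
    depart <- arrive + stopover_duration()
    add_site("stopover", s[["lat"]], s[["lon"]], arrive, depart)
    t <- depart; prev <- s
  }
  dur <- leg_duration(haversine(prev["lat"], prev["lon"],
                                breeding["lat"], breeding["lon"]))
  arrive_breeding <- t + dur
  depart_breeding <- arrive_breeding +
    max(40, .round_half(stats::rnorm(1, breeding_days, 7)))
  add_site("breeding", breeding[["lat"]], breeding[["lon"]],
           arrive_breeding, depart_breeding)

  # --- autumn migration ----------------------------------------------------
  n_au <- sample(seq(n_stopovers[1], n_stopovers[2]), 1)
  au_stops <- place_stopovers(breeding, main, n_au, lon_shift = loop_shift_lon)
  t <- depart_breeding; prev <- breeding
  if (!is.null(au_stops)) for (k in seq_len(nrow(au_stops))) {
    s <- c(lat = au_stops$lat[k], lon = au_stops$lon[k])
    dur <- leg_duration(haversine(prev["lat"], prev["lon"], s["lat"], s["lon"]))
    arrive <- t + dur
    depart <- arrive + stopover_duration()
    add_site("stopover", s[["lat"]], s[["lon"]], arrive, depart)
    t <- depart; prev <- s
  }
  dur <- leg_duration(haversine(prev["lat"], prev["lon"],
                                main["lat"], main["lon"]))
  arrive_home <- t + dur
  add_site("main_nonbreeding", main[["lat"]], main[["lon"]],
           arrive_home, arrive_home + 60)

  sites <- do.call(rbind, sites)
  stopifnot(all(diff(sites$arrive) > 0), all(sites$depart >= sites$arrive))

  i <- seq_len(nrow(sites) - 1)
  legs <- data.frame(
    from = sites$label[i], to = sites$label[i + 1],
    start = sites$depart[i], end = sites$arrive[i + 1],
    distance_km = haversine(sites$lat[i], sites$lon[i],
                            sites$lat[i + 1], sites$lon[i + 1]),
    duration_days = sites$arrive[i + 1] - sites$depart[i])
  stopifnot(all(legs$duration_days >= 0.5))

  fail_day <- if (is.null(fail_date)) NA_real_
  else as.numeric(as.Date(fail_date) - origin)

  structure(list(bird_id = bird_id, country = country, origin = origin,
                 sites = sites, legs = legs, fail_day = fail_day),
            class = "sim_track")
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("Simulated track %s (%s): %d sites, %d legs, %s to %s\n",
              x$bird_id, x$country, nrow(x$sites), nrow(x$legs),
              format(x$origin),
              format(x$origin + max(x$sites$depart))))
  invisible(x)
}

# true position of the track at fractional day t (days since origin)
.track_position <- function(track, t) {
  s <- track$sites
  for (k in seq_len(nrow(s))) {
    if (t >= s$arrive[k] && t <= s$depart[k])
      return(c(lat = s$lat[k], lon = s$lon[k], state = 1, id = k))
    if (k < nrow(s) && t > s$depart[k] && t < s$arrive[k + 1]) {
      f <- (t - s$depart[k]) / (s$arrive[k + 1] - s$depart[k])
      p <- .gc_interpolate(s$lat[k], s$lon[k], s$lat[k + 1], s$lon[k + 1], f)
      return(c(lat = p[["lat"]], lon = p[["lon"]], state = 0, id = k))
    }
  }
  c(lat = s$lat[nrow(s)], lon = s$lon[nrow(s)], state = 1, id = nrow(s))
}

#' Simulate the twilight series a tag would record along a track
#'
#' For each deployment day the true position (site, or great-circle
#' interpolation within a leg) is evaluated at local noon and the forward
#' solar model gives the twilight pair at the tag's effective sun elevation
#' angle.  Shading noise then delays sunrise and advances sunset (never the
#' reverse), symmetric jitter is added, linear clock drift is applied, and
#' days are dropped at the missing-day probability.  Polar-day days are
#' emitted with their flag and NA times.
#'
#' @param track a `sim_track`.
#' @param sun_elevation effective twilight sun elevation angle of the tag,
#'   degrees (default -3.5).
#' @param noise a [noise_model()]; `noise_model(0, 0, 0)` gives the exact
#'   forward model.
#' @param seed integer seed for the noise draws.
#' @return list: `twilights` (date, sunrise_utc, sunset_utc, polar_flag),
#'   `truth` (date, state, site_id, label), both truncated at the track's
#'   `fail_day` if set.
#' @export
simulate_twilights <- function(track, sun_elevation = -3.5,
                               noise = noise_model(), seed = 1) {
  stopifnot(inherits(track, "sim_track"))
  set.seed(seed)
  last <- max(track$sites$depart)
  if (!is.na(track$fail_day)) last <- min(last, track$fail_day)
  days <- seq(0, floor(last))
  n <- length(days)

  tw <- vector("list", n); truth <- vector("list", n)
  for (k in seq_len(n)) {
    t <- days[k]
    pos <- .track_position(track, t + 0.5)
    date <- track$origin + t
    pair <- twilight_times(pos[["lat"]], pos[["lon"]], date, sun_elevation)
    tw[[k]] <- pair
    truth[[k]] <- data.frame(
      date = date,
      state = if (pos[["state"]] == 1) "stationary" else "migrating",
      site_id = as.integer(pos[["id"]]),
      label = if (pos[["state"]] == 1)
        track$sites$label[pos[["id"]]] else "migrating",
      lat = pos[["lat"]], lon = pos[["lon"]])
  }
  tw <- do.call(rbind, tw)
  truth <- do.call(rbind, truth)

  ok <- tw$polar_flag == "none"
  shade_sr <- stats::rexp(n, rate = 1 / max(noise$shade_mean, 1e-9)) *
    (noise$shade_mean > 0)
  shade_ss <- stats::rexp(n, rate = 1 / max(noise$shade_mean, 1e-9)) *
    (noise$shade_mean > 0)
  jit_sr <- stats::rnorm(n, 0, noise$jitter_sd)
  jit_ss <- stats::rnorm(n, 0, noise$jitter_sd)
  drift <- noise$clock_drift * (days / max(days[n], 1))
  tw$sunrise_utc[ok] <- tw$sunrise_utc[ok] +
    (shade_sr[ok] + jit_sr[ok] + drift[ok]) / 60
  tw$sunset_utc[ok] <- tw$sunset_utc[ok] +
    (-shade_ss[ok] + jit_ss[ok] + drift[ok]) / 60

  if (noise$missing_day_prob > 0) {
    drop <- stats::runif(n) < noise$missing_day_prob
    tw$sunrise_utc[drop] <- NA_real_
    tw$sunset_utc[drop] <- NA_real_
  }
  list(twilights = tw, truth = truth)
}

#' Render a twilight series as a raw light log
#'
#' Inverse of twilight extraction: emits a regularly sampled light record
#' (0 at night, 64 in daylight) whose first and last lit samples each day
#' bracket the given twilight pair to sampling resolution.
#'
#' @param twilights data.frame `date`, `sunrise_utc`, `sunset_utc`.
#' @param interval_min sampling interval, minutes (default 10, a common
#'   logger setting).
#' @return data.frame `timestamp` (POSIXct UTC), `light` (0 or 64).
#' @export
render_light_log <- function(twilights, interval_min = 10) {
  rows <- lapply(seq_len(nrow(twilights)), function(k) {
    h <- seq(0, 24 - interval_min / 60, by = interval_min / 60)
    sr <- twilights$sunrise_utc[k]; ss <- twilights$sunset_utc[k]
    lit <- if (is.na(sr) || is.na(ss)) rep(FALSE, length(h))
    else h >= sr & h <= ss
    data.frame(
      timestamp = as.POSIXct(paste(twilights$date[k], "00:00:00"),
                             tz = "UTC") + h * 3600,
      light = ifelse(lit, 64L, 0L))
  })
  do.call(rbind, rows)
}

#' Simulate a cohort of tracks
#'
#' Convenience wrapper drawing per-bird seeds from one master seed; used for
#' parameter-recovery studies and the completeness-mix pipeline runs.
#'
#' @param n number of birds.
#' @param seed master seed.
#' @param countries vector to sample countries from (default 3:1
#'   Nigeria:Liberia, the study's ratio).
#' @param ... further arguments passed to [simulate_track()].
#' @return list of `sim_track`.
#' @export
simulate_cohort <- function(n, seed = 1,
                            countries = c("Nigeria", "Nigeria", "Nigeria",
                                          "Liberia"), ...) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  ctry <- sample(countries, n, replace = TRUE)
  lapply(seq_len(n), function(i)
    simulate_track(bird_id = sprintf("bird%02d", i), country = ctry[i],
                   seed = seeds[i], ...))
}
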