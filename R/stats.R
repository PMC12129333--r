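# Population-level movement statistics: migratory spread with a
# randomization confidence interval, minimum convex polygon breeding ranges
# and their overlap, the loop-migration longitude contrast, and the
# closed-form flight-time and fuel arithmetic used to interpret leg speeds.

#' Migratory spread with randomization confidence interval
#'
#' Spread is the mean great-circle distance between all unordered pairs of
#' locations (typically one breeding location per bird); low spread means
#' high migratory connectivity.  The confidence interval is obtained by
#' drawing `n_resamples` random pairs (with replacement from the distinct
#' unordered pairs) and taking the 2.5th and 97.5th percentile order
#' statistics -- with the default 10,000 resamples, the 250th and 9,750th
#' sorted values.
#'
#' @param lat,lon coordinates of the locations (>= 2 points).
#' @param n_resamples random pairs for the CI; default 10000.
#' @param seed integer seed for reproducibility (optional).
#' @return list: `mean_pairwise_km`, `ci_low_km`, `ci_high_km`, `n_points`,
#'   `n_resamples`.
#' @export
migratory_spread <- function(lat, lon, n_resamples = 10000, seed = NULL) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (n < 2) stop("migratory spread needs at least 2 points")
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(n, 2)
  d <- haversine(lat[pairs[1, ]], lon[pairs[1, ]],
                 lat[pairs[2, ]], lon[pairs[2, ]])
  idx <- sample.int(length(d), n_resamples, replace = TRUE)
  sorted <- sort(d[idx])
  k_lo <- max(1L, round(0.025 * n_resamples))
  k_hi <- min(n_resamples, round(0.975 * n_resamples))
  list(mean_pairwise_km = mean(d),
       ci_low_km = sorted[k_lo], ci_high_km = sorted[k_hi],
       n_points = n, n_resamples = n_resamples)
}

# Lambert azimuthal equal-area projection centred at (lat0, lon0);
# returns x/y in km on a sphere of radius 6371 km.  Equal-area by
# construction, so planar polygon areas equal spherical areas.
.laea_project <- function(lat, lon, lat0, lon0, R = 6371) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  cbind(x = R * k * cos(phi) * sin(lam - lam0),
        y = R * k * (cos(phi0) * sin(phi) -
                       sin(phi0) * cos(phi) * cos(lam - lam0)))
}

# shoelace area of a planar polygon (vertices in order, km) -> km^2
.shoelace <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Minimum convex polygon range
#'
#' Convex hull of a set of locations, computed on a Lambert azimuthal
#' equal-area projection centred on the points' centroid so the planar area
#' equals the spherical area in km^2.
#'
#' @param lat,lon locations (>= 3, not all collinear).
#' @return object of class `range_polygon`: list with `lat`, `lon` (hull
#'   vertices, counter-clockwise), `area_km2`, `n_points` and the
#'   projection centre.
#' @export
convex_range <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  pts <- unique(cbind(lat, lon))
  if (nrow(pts) < 3)
    stop("convex range needs >= 3 distinct points, got ", nrow(pts))
  lat0 <- mean(pts[, 1]); lon0 <- mean(pts[, 2])
  xy <- .laea_project(pts[, 1], pts[, 2], lat0, lon0)
  h <- rev(grDevices::chull(xy))          # chull is clockwise; reverse to CCW
  if (length(h) < 3 || .shoelace(xy[h, , drop = FALSE]) < 1e-9)
    stop("degenerate geometry: the ", nrow(pts),
         " distinct points are collinear")
  structure(list(lat = pts[h, 1], lon = pts[h, 2],
                 area_km2 = .shoelace(xy[h, , drop = FALSE]),
                 n_points = length(lat), lat0 = lat0, lon0 = lon0),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("Minimum convex polygon: %d vertices (%d points), %.0f km^2\n",
              length(x$lat), x$n_points, x$area_km2))
  invisible(x)
}

# Sutherland-Hodgman clipping of convex polygon `subj` (n x 2 planar) by
# convex polygon `clip`; both counter-clockwise.  Exact for convex inputs.
.clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-9
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2]); d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
      p + t * d1
    }
    inp <- out; out <- matrix(numeric(0), ncol = 2)
    ni <- nrow(inp)
    for (i in seq_len(ni)) {
      cur <- inp[i, ]; prev <- inp[if (i == 1) ni else i - 1, ]
      if (inside(cur)) {
        if (!inside(prev)) out <- rbind(out, inter(prev, cur))
        out <- rbind(out, cur)
      } else if (inside(prev)) {
        out <- rbind(out, inter(prev, cur))
      }
    }
  }
  out
}

#' Overlap between two convex ranges
#'
#' Projects both polygons onto a common equal-area plane centred on their
#' joint centroid, intersects them (Sutherland-Hodgman clipping, exact for
#' convex polygons) and reports the intersection area as a fraction of each
#' polygon and of their union.
#'
#' @param polyA,polyB `range_polygon` objects from [convex_range()].
#' @return list: `overlap_km2`, `frac_A`, `frac_B`, `frac_union` (all in
#'   [0, 1]; zeros when disjoint).
#' @export
range_overlap <- function(polyA, polyB) {
  stopifnot(inherits(polyA, "range_polygon"), inherits(polyB, "range_polygon"))
  lat0 <- mean(c(polyA$lat, polyB$lat))
  lon0 <- mean(c(polyA$lon, polyB$lon))
  a <- .laea_project(polyA$lat, polyA$lon, lat0, lon0)
  b <- .laea_project(polyB$lat, polyB$lon, lat0, lon0)
  # re-orient CCW in the common plane
  orient <- function(xy) {
    s <- sum(xy[, 1] * xy[c(2:nrow(xy), 1), 2] -
               xy[c(2:nrow(xy), 1), 1] * xy[, 2])
    if (s < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
  }
  a <- orient(a); b <- orient(b)
  areaA <- .shoelace(a); areaB <- .shoelace(b)
  inter <- .clip_convex(a, b)
  ov <- if (nrow(inter) >= 3) .shoelace(inter) else 0
  list(overlap_km2 = ov,
       frac_A = ov / areaA,
       frac_B = ov / areaB,
       frac_union = ov / (areaA + areaB - ov))
}

#' Loop-migration longitude contrast
#'
#' For each bird, the mean stopover longitude in autumn minus the mean in
#' spring; positive values mean a more easterly autumn route.  The group
#' statistic is the mean of the per-bird differences.  Significance comes
#' from a within-bird permutation test: season labels are shuffled within
#' each bird's own stopovers, preserving per-bird sample sizes, and the
#' two-sided p-value is the (add-one corrected) fraction of permuted group
#' means at least as extreme as the observed one.
#'
#' @param stopovers data.frame with columns `bird_id`, `season` ("spring" /
#'   "autumn") and `lon`.
#' @param n_permutations default 2000.
#' @param seed integer seed (optional).
#' @return list: `per_bird` (data.frame bird_id, delta_lon, n_spring,
#'   n_autumn), `mean_delta_lon`, `p_value`, `n_birds`, `excluded` (bird ids
#'   lacking a season).
#' @export
loop_contrast <- function(stopovers, n_permutations = 2000, seed = NULL) {
  stopifnot(all(c("bird_id", "season", "lon") %in% names(stopovers)))
  if (!is.null(seed)) set.seed(seed)
  by_bird <- split(stopovers, stopovers$bird_id)
  usable <- vapply(by_bird, function(d)
    any(d$season == "spring") && any(d$season == "autumn"), logical(1))
  excluded <- names(by_bird)[!usable]
  if (length(excluded))
    message("loop_contrast: excluding ", length(excluded),
            " bird(s) lacking stopovers in one season: ",
            paste(excluded, collapse = ", "))
  by_bird <- by_bird[usable]
  if (!length(by_bird)) stop("no bird has stopovers in both seasons")

  delta <- function(d, season)
    mean(d$lon[season == "autumn"]) - mean(d$lon[season == "spring"])
  per_bird <- data.frame(
    bird_id = names(by_bird),
    delta_lon = vapply(by_bird, function(d) delta(d, d$season), numeric(1)),
    n_spring = vapply(by_bird, function(d) sum(d$season == "spring"),
                      integer(1)),
    n_autumn = vapply(by_bird, function(d) sum(d$season == "autumn"),
                      integer(1)),
    row.names = NULL)
  obs <- mean(per_bird$delta_lon)

  perm_stats <- vapply(seq_len(n_permutations), function(k) {
    mean(vapply(by_bird, function(d)
      delta(d, sample(d$season)), numeric(1)))
  }, numeric(1))
  p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (1 + n_permutations)
  list(per_bird = per_bird, mean_delta_lon = obs, p_value = p,
       n_birds = nrow(per_bird), excluded = excluded)
}

#' Leg travel speed
#'
#' Ground speed over a migration leg, including any rests shorter than the
#' two-day detection limit of light-level segmentation:
#' distance / (24 x duration).
#'
#' @param distance_km leg distance.
#' @param duration_days leg duration in days (half-day resolution upstream).
#' @return km/h.
#' @examples
#' leg_speed(2043, 3.1)  # ~27.5 km/h
#' @export
leg_speed <- function(distance_km, duration_days) {
  stopifnot(all(duration_days > 0))
  distance_km / (24 * duration_days)
}

#' Stationary hours per day during a migration leg
#'
#' If a bird flies at `flight_speed` when airborne, a leg of the given
#' distance requires distance / flight_speed hours aloft; the rest of the
#' observed leg duration is time on the ground.  Expressed per 24-h day:
#' 24 x (observed hours - flight hours) / observed hours.
#'
#' @param distance_km leg distance.
#' @param duration_days observed leg duration.
#' @param flight_speed airborne speed in km/h; 43 is a typical measured
#'   migratory flight speed for small chats.
#' @return hours per day stationary; negative values (observed duration
#'   shorter than the flight itself) are clipped to 0 with a warning.
#' @examples
#' stationary_hours_per_day(2008, 3.1)  # ~8.9 h/day
#' @export
stationary_hours_per_day <- function(distance_km, duration_days,
                                     flight_speed = 43) {
  stopifnot(all(duration_days > 0), flight_speed > 0)
  obs_h <- duration_days * 24
  h <- 24 * (obs_h - distance_km / flight_speed) / obs_h
  if (any(h < 0)) {
    warning("observed duration shorter than flight time; clipping to 0")
    h <- pmax(h, 0)
  }
  h
}

#' Fuel required for a journey
#'
#' Linear fuel-distance scaling: a passerine of this size needs about 25 g
#' of extra body reserves per 5000 km flown.
#'
#' @param distance_km journey distance.
#' @param fuel_per_5000km grams of reserves consumed per 5000 km; default 25.
#' @return grams.
#' @export
fuel_requirement <- function(distance_km, fuel_per_5000km = 25) {
  stopifnot(all(distance_km >= 0), fuel_per_5000km > 0)
  fuel_per_5000km * distance_km / 5000
}

#' Daily fuel gain and deposition rate over a journey
#'
#' The extra mass a bird must gain en route is the journey's fuel
#' requirement minus what it carried at departure; spread over the journey
#' this gives a mean daily gain, and relative to lean mass a daily
#' deposition rate.
#'
#' @param distance_km journey distance.
#' @param journey_days journey duration.
#' @param fuel_per_5000km grams per 5000 km; default 25.
#' @param departure_load grams of reserves aboard at departure.
#' @param lean_mass grams; optional, enables the deposition-rate fraction.
#' @param extra_mass override: grams to be gained en route, bypassing the
#'   requirement-minus-load computation (useful when the shortfall itself is
#'   the known quantity).
#' @return list: `required_g`, `extra_mass_g`, `daily_gain_g`,
#'   `deposition_rate` (fraction of lean mass per day; NA without
#'   `lean_mass`).
#' @examples
#' fuel_budget(5054, 7, extra_mass = 12)  # ~1.7 g/day
#' @export
fuel_budget <- function(distance_km, journey_days, fuel_per_5000km = 25,
                        departure_load = 0, lean_mass = NA,
                        extra_mass = NULL) {
  stopifnot(journey_days > 0)
  required <- fuel_requirement(distance_km, fuel_per_5000km)
  extra <- if (is.null(extra_mass)) max(required - departure_load, 0)
  else extra_mass
  gain <- extra / journey_days
  list(required_g = required, extra_mass_g = extra, daily_gain_g = gain,
       deposition_rate = if (is.na(lean_mass)) NA_real_ else gain / lean_mass)
}

#' Pool resighting proportions across studies
#'
#' Descriptive pooling of resighting counts for two groups (e.g. tagged
#' birds vs colour-ring-only controls) over several studies: per-study
#' percentages, the pooled percentage (sum of resighted over sum of totals)
#' per group and their difference.
#'
#' @param resighted,total integer vectors, one entry per study.
#' @param group factor/character of the same length naming the group of
#'   each entry.
#' @return list: `per_study` data.frame, `pooled` data.frame (group, resighted,
#'   total, percent), `difference_pct` (first group minus second).
#' @export
pool_resighting <- function(resighted, total, group) {
  stopifnot(length(resighted) == length(total),
            length(group) == length(total), all(total > 0),
            all(resighted >= 0), all(resighted <= total))
  per_study <- data.frame(group = group, resighted = resighted,
                          total = total,
                          percent = 100 * resighted / total)
  g <- unique(group)
  pooled <- do.call(rbind, lapply(g, function(gg) {
    r <- sum(resighted[group == gg]); t <- sum(total[group == gg])
    data.frame(group = gg, resighted = r, total = t,
               percent = 100 * r / t)
  }))
  diff <- if (length(g) == 2)
    pooled$percent[1] - pooled$percent[2] else NA_real_
  list(per_study = per_study, pooled = pooled, difference_pct = diff)
}
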