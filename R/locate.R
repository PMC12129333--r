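# Threshold geolocation of stationary periods.
#
# The sun elevation angle at which the logger registers twilight is unknown
# (it depends on sensor threshold, habitat shading and weather) and cannot
# be separated from location.  The standard resolution is to calibrate: find
# the angle that best relocates the bird at the tagging/recapture site --
# the only place its position is certain -- and apply that single angle to
# every stationary period of the deployment, so that errors are imprecision
# rather than systematic bias.

#' Daily threshold positions from a twilight series
#'
#' Longitude from the twilight midpoint, latitude from day length at the
#' given sun elevation angle.  Equinox-degenerate and polar days yield NA
#' latitude; polar days yield NA longitude too.
#'
#' @param twilights data.frame with `date`, `sunrise_utc`, `sunset_utc`,
#'   optionally `polar_flag`.
#' @param sun_elevation calibrated sun elevation angle, degrees.
#' @param lat_range latitude search band passed to
#'   [latitude_from_daylength()].
#' @return data.frame `date`, `lon`, `lat`, `lat_flag`.
#' @export
daily_positions <- function(twilights, sun_elevation,
                            lat_range = c(-40, 80)) {
  lon <- longitude_from_twilights(twilights)
  dl <- twilights$sunset_utc - twilights$sunrise_utc
  lat <- rep(NA_real_, nrow(twilights))
  flag <- rep("no_twilight", nrow(twilights))
  use <- !is.na(dl) & dl > 0 & dl < 24
  if (any(use)) {
    r <- latitude_from_daylength(dl[use], twilights$date[use], sun_elevation,
                                 lat_range = lat_range)
    lat[use] <- r$lat
    flag[use] <- r$flag
  }
  data.frame(date = twilights$date, lon = lon, lat = lat, lat_flag = flag)
}

#' Calibrate the sun elevation angle at a known site
#'
#' Grid search (default -9 to +3 degrees in 0.1-degree steps) for the angle
#' whose daily threshold positions have the smallest median great-circle
#' distance to the known site.  Longitude does not depend on the angle; the
#' calibration is driven by how the angle maps day length to latitude.
#' Equinox-degenerate days are excluded.
#'
#' Because shading shortens the apparent day one-sidedly, the calibrated
#' angle is typically lower (more negative) than the true geometric twilight
#' angle; that is the point -- it absorbs the average shading of the
#' deployment into the angle instead of into a latitude bias.
#'
#' @param twilights twilight series recorded while the bird was at the known
#'   site.
#' @param known_lat,known_lon the site, decimal degrees.
#' @param grid candidate angles, degrees.
#' @param min_days minimum usable (non-equinox, non-polar) days; default 10.
#' @return list with `sun_elevation` (the argmin), `median_error_km` and
#'   `rms_position_error` (km, at the chosen angle) and `n_days`.
#' @export
calibrate_sun_elevation <- function(twilights, known_lat, known_lon,
                                    grid = seq(-9, 3, by = 0.1),
                                    min_days = 10) {
  scores <- vapply(grid, function(a) {
    pos <- daily_positions(twilights, a)
    keep <- pos$lat_flag == "ok" & !is.na(pos$lon)
    if (sum(keep) < min_days) return(NA_real_)
    stats::median(haversine(pos$lat[keep], pos$lon[keep],
                            known_lat, known_lon))
  }, numeric(1))
  if (all(is.na(scores)))
    stop("fewer than ", min_days,
         " usable calibration days at every candidate angle")
  best <- grid[which.min(scores)]
  pos <- daily_positions(twilights, best)
  keep <- pos$lat_flag == "ok" & !is.na(pos$lon)
  d <- haversine(pos$lat[keep], pos$lon[keep], known_lat, known_lon)
  list(sun_elevation = best,
       median_error_km = stats::median(d),
       rms_position_error = sqrt(mean(d^2)),
       n_days = sum(keep))
}

#' Locate one stationary period
#'
#' Aggregates the daily threshold positions within a period: the location is
#' the median daily longitude and median daily latitude, with standard
#' errors sd/sqrt(n) per axis.  Days flagged polar are excluded from all
#' location arithmetic; equinox-degenerate days are excluded from latitude
#' only, so longitude keeps its full sample.  If no day yields a latitude
#' (e.g. an Arctic midsummer period with usable shoulder days only for
#' longitude), latitude is reported missing and longitude is still returned.
#'
#' @param twilights twilight rows belonging to the period (>= 2 valid days).
#' @param sun_elevation calibrated angle, degrees.
#' @param lat_range latitude search band.
#' @return one-row data.frame: `lon`, `lat`, `lon_se`, `lat_se`,
#'   `n_days_lon`, `n_days_lat`, `equinox_flag`, `polar_excluded_days`.
#' @export
locate_stationary_period <- function(twilights, sun_elevation,
                                     lat_range = c(-40, 80)) {
  pos <- daily_positions(twilights, sun_elevation, lat_range = lat_range)
  lon_ok <- !is.na(pos$lon)
  if (sum(lon_ok) < 1)
    stop("no valid longitude days in period (all polar or missing)")
  lat_ok <- pos$lat_flag == "ok" & !is.na(pos$lat)
  n_lon <- sum(lon_ok); n_lat <- sum(lat_ok)
  data.frame(
    lon = stats::median(pos$lon[lon_ok]),
    lat = if (n_lat) stats::median(pos$lat[lat_ok]) else NA_real_,
    lon_se = if (n_lon > 1) stats::sd(pos$lon[lon_ok]) / sqrt(n_lon) else 0,
    lat_se = if (n_lat > 1) stats::sd(pos$lat[lat_ok]) / sqrt(n_lat) else NA_real_,
    n_days_lon = n_lon,
    n_days_lat = n_lat,
    equinox_flag = any(pos$lat_flag == "equinox_degenerate"),
    polar_excluded_days = if (is.null(twilights$polar_flag)) 0L
                          else sum(twilights$polar_flag != "none")
  )
}

#' Locate every stationary period of a segmented track
#'
#' @param twilights full twilight series.
#' @param segments output of [detect_stationary_periods()].
#' @param sun_elevation calibrated angle.
#' @param lat_range latitude search band.
#' @return data.frame, one row per stationary period, joining
#'   [period_boundaries()] with the location fields.
#' @export
locate_periods <- function(twilights, segments, sun_elevation,
                           lat_range = c(-40, 80)) {
  bounds <- period_boundaries(segments)
  locs <- lapply(bounds$period_id, function(pid) {
    days <- segments$date[!is.na(segments$period_id) &
                            segments$period_id == pid]
    tw <- twilights[twilights$date %in% days, ]
    loc <- locate_stationary_period(tw, sun_elevation, lat_range = lat_range)
    loc$equinox_flag <- loc$equinox_flag ||
      flag_equinox(min(days), max(days))
    loc
  })
  cbind(bounds, do.call(rbind, locs))
}
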