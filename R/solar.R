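# Low-precision solar geometry for the threshold method.
#
# Declination and the equation of time come from the standard low-precision
# almanac series (mean longitude / mean anomaly polynomial in days since
# J2000, ecliptic longitude with two periodic terms, obliquity-rotated right
# ascension).  Stated accuracy is better than 0.01 deg in declination and a
# few seconds in the equation of time over the decades any tag deployment
# spans -- far finer than the 100-500 km accuracy of threshold geolocation.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Solar declination and equation of time
#'
#' Computes the apparent declination of the sun and the equation of time for
#' a calendar date, using a low-precision almanac series (days since J2000
#' epoch; mean longitude and mean anomaly linear in time, two periodic terms
#' in ecliptic longitude).
#'
#' @param date a `Date` (or something coercible to one).
#' @return a data.frame with columns `date`, `declination` (degrees,
#'   positive north), and `equation_of_time` (minutes; positive when the
#'   sundial is ahead of the mean clock, i.e. solar noon occurs before
#'   12:00 mean time).
#' @examples
#' solar_position(as.Date("2019-06-21"))  # declination near +23.44
#' @export
solar_position <- function(date) {
  date <- as.Date(date)
  # days since J2000.0, evaluated at 12:00 UT
  n <- as.numeric(date - as.Date("2000-01-01"))
  L <- (280.460 + 0.9856474 * n) %% 360          # mean longitude
  g <- .deg2rad((357.528 + 0.9856003 * n) %% 360) # mean anomaly
  lambda <- .deg2rad(L + 1.915 * sin(g) + 0.020 * sin(2 * g))
  eps <- .deg2rad(23.439 - 0.0000004 * n)         # obliquity
  decl <- asin(sin(eps) * sin(lambda))
  alpha <- atan2(cos(eps) * sin(lambda), cos(lambda)) # right ascension
  # equation of time = mean longitude - right ascension, in minutes
  eot <- ((L - .rad2deg(alpha) + 180) %% 360 - 180) * 4
  data.frame(date = date,
             declination = .rad2deg(decl),
             equation_of_time = eot)
}

#' Solar declination
#'
#' @inheritParams solar_position
#' @return declination in degrees.
#' @export
solar_declination <- function(date) solar_position(date)$declination

#' Equation of time
#'
#' @inheritParams solar_position
#' @return equation of time in minutes (sundial minus mean clock).
#' @export
equation_of_time <- function(date) solar_position(date)$equation_of_time

#' Sunrise and sunset times for a sun elevation angle
#'
#' Forward model of what a light logger sees: the UTC times at which the sun
#' crosses a given elevation angle at a location.  The hour angle H solves
#' \code{cos H = (sin a - sin(lat) sin(decl)) / (cos(lat) cos(decl))}; when
#' the right-hand side falls outside [-1, 1] the sun never crosses the
#' elevation that day and the pair is flagged polar day or polar night.
#'
#' Times are decimal hours UTC.  Sunset may exceed 24 h (and sunrise may be
#' negative) at far-east/far-west longitudes so that every pair satisfies
#' sunset > sunrise; callers that need clock-of-day values can take
#' \code{\%\% 24}.
#'
#' @param lat,lon location in decimal degrees (WGS84 convention, north/east
#'   positive); `abs(lat) <= 90`, `-180 < lon <= 180`.
#' @param date calendar date (the solar terms are evaluated once per day).
#' @param sun_elevation elevation angle in degrees defining twilight
#'   (negative below the horizon; 0 is the geometric horizon).
#' @return data.frame with columns `date`, `sunrise_utc`, `sunset_utc`
#'   (decimal hours, NA when degenerate) and `polar_flag`
#'   (`"none"`, `"polar_day"`, `"polar_night"`).
#' @examples
#' twilight_times(50, 10, as.Date("2019-10-01"), -3.5)
#' @export
twilight_times <- function(lat, lon, date, sun_elevation = 0) {
  stopifnot(all(abs(lat) <= 90), all(lon > -180 & lon <= 180))
  sp <- solar_position(date)
  phi <- .deg2rad(lat)
  delta <- .deg2rad(sp$declination)
  cosH <- (sin(.deg2rad(sun_elevation)) - sin(phi) * sin(delta)) /
    (cos(phi) * cos(delta))
  polar_flag <- ifelse(cosH < -1, "polar_day",
                       ifelse(cosH > 1, "polar_night", "none"))
  H <- .rad2deg(acos(pmin(1, pmax(-1, cosH))))       # degrees, 0..180
  noon <- 12 - sp$equation_of_time / 60 - lon / 15   # solar noon, UTC hours
  sunrise <- ifelse(polar_flag == "none", noon - H / 15, NA_real_)
  sunset <- ifelse(polar_flag == "none", noon + H / 15, NA_real_)
  data.frame(date = as.Date(date), sunrise_utc = sunrise,
             sunset_utc = sunset, polar_flag = polar_flag)
}

#' Longitude from a twilight pair
#'
#' The midpoint of sunrise and sunset is local solar noon; its offset from
#' 12:00 UTC, corrected for the equation of time, converts to longitude at
#' 15 degrees per hour.  Equivalently, one degree of longitude shifts both
#' twilights by 4 minutes, which is why longitude stays reliable through the
#' equinox while latitude does not.
#'
#' @param twilights data.frame with columns `date`, `sunrise_utc`,
#'   `sunset_utc` and optionally `polar_flag` (as from [twilight_times()]).
#' @return numeric vector of longitudes in degrees (east positive), NA for
#'   degenerate days.
#' @export
longitude_from_twilights <- function(twilights) {
  if (!is.null(twilights$polar_flag) && all(twilights$polar_flag != "none"))
    stop("all twilight pairs are polar day/night; longitude is undefined")
  mid <- (twilights$sunrise_utc + twilights$sunset_utc) / 2
  eot_h <- equation_of_time(twilights$date) / 60
  lon <- 15 * (12 - eot_h - mid)
  if (!is.null(twilights$polar_flag))
    lon[twilights$polar_flag != "none"] <- NA_real_
  # wrap into (-180, 180]
  ((lon + 180) %% 360) - 180 + 360 * (((lon + 180) %% 360) == 0)
}

#' Latitude from day length
#'
#' Inverts the day-length equation: given the observed interval between
#' sunrise and sunset (for a known sun elevation angle) the hour angle is
#' H = 7.5 deg/h x day length, and latitude solves
#' \code{sin a = sin(lat) sin(decl) + cos(lat) cos(decl) cos H}.  Away from
#' the equinoxes day length is strictly monotone in latitude, so the root is
#' unique within a hemisphere band and is found by bisection
#' (`stats::uniroot`, tolerance 1e-6 degrees).
#'
#' Near the equinoxes (`abs(declination) < equinox_decl`) day length is
#' nearly 12 h at every latitude and the inversion is unidentifiable; those
#' days return NA with `flag = "equinox_degenerate"` rather than an
#' arbitrarily amplified estimate.  Day lengths outside what the search band
#' can produce (polar conditions) return NA with `flag = "no_solution"`.
#'
#' @param day_length hours, in (0, 24).
#' @param date calendar date (sets the declination).
#' @param sun_elevation twilight sun elevation angle in degrees.
#' @param lat_range numeric(2), search band in degrees; default
#'   `c(-40, 80)` brackets the Afro-Palearctic system.
#' @param equinox_decl degenerate-declination threshold in degrees
#'   (default 3.5, about nine days either side of each equinox).
#' @param hemisphere_hint `"north"`, `"south"` or NULL.  For sun elevations
#'   below the horizon two latitudes can share the same day length on the
#'   same date; when both fall inside `lat_range` the hint picks the one in
#'   the expected hemisphere, and without a hint (or with both candidates
#'   in the same hemisphere) the day is flagged `"ambiguous"` rather than
#'   guessed.
#' @return data.frame with columns `lat` (degrees or NA) and `flag`
#'   (`"ok"`, `"equinox_degenerate"`, `"no_solution"`, `"ambiguous"`); one
#'   row per element of `day_length` (recycled against `date`).
#' @export
latitude_from_daylength <- function(day_length, date, sun_elevation = 0,
                                    lat_range = c(-40, 80),
                                    equinox_decl = 3.5,
                                    hemisphere_hint = NULL) {
  stopifnot(all(day_length > 0), all(day_length < 24),
            length(lat_range) == 2, lat_range[1] < lat_range[2])
  sp <- solar_position(date)
  m <- max(length(day_length), nrow(sp))
  day_length <- rep_len(day_length, m)
  delta <- .deg2rad(rep_len(sp$declination, m))
  # A sin(phi) + B cos(phi) = C  =>  phi = asin(C/R) - psi (closed form)
  H <- .deg2rad(7.5 * day_length)
  A <- sin(delta)
  B <- cos(delta) * cos(H)
  C <- rep_len(sin(.deg2rad(sun_elevation)), m)
  R <- sqrt(A^2 + B^2)
  psi <- atan2(B, A)
  arg <- C / R
  lat <- rep(NA_real_, m)
  flag <- rep("ok", m)
  ok <- abs(arg) <= 1
  flag[!ok] <- "no_solution"
  if (any(ok)) {
    # the sine form has two branches, and for sun elevations below the
    # horizon both can be genuine solutions (two latitudes share the same
    # interval between threshold crossings on the same date); keep roots
    # that solve the equation and fall in the search band, and when both
    # survive use the hemisphere hint -- or flag the day ambiguous
    p1 <- .rad2deg(asin(arg[ok]) - psi[ok])
    p2 <- .rad2deg(pi - asin(arg[ok]) - psi[ok])
    p2 <- ifelse(p2 > 180, p2 - 360, p2)
    resid <- function(p) {
      phi <- .deg2rad(p)
      abs(sin(phi) * A[ok] + cos(phi) * B[ok] - C[ok])
    }
    good1 <- resid(p1) < 1e-8 & p1 >= lat_range[1] & p1 <= lat_range[2]
    good2 <- resid(p2) < 1e-8 & p2 >= lat_range[1] & p2 <= lat_range[2] &
      abs(p2 - p1) > 1e-6
    chosen <- ifelse(good1 & !good2, p1,
                     ifelse(good2 & !good1, p2, NA_real_))
    both <- good1 & good2
    if (any(both)) {
      if (identical(hemisphere_hint, "north")) {
        pick <- ifelse(p1 >= 0 & p2 < 0, p1,
                       ifelse(p2 >= 0 & p1 < 0, p2, NA_real_))
        chosen[both] <- pick[both]
      } else if (identical(hemisphere_hint, "south")) {
        pick <- ifelse(p1 < 0 & p2 >= 0, p1,
                       ifelse(p2 < 0 & p1 >= 0, p2, NA_real_))
        chosen[both] <- pick[both]
      }
      flag[ok][both & is.na(chosen)] <- "ambiguous"
    }
    lat[ok] <- chosen
    flag[ok][is.na(chosen) & flag[ok] == "ok"] <- "no_solution"
  }
  eq <- abs(.rad2deg(delta)) < equinox_decl
  lat[eq] <- NA_real_
  flag[eq] <- "equinox_degenerate"
  data.frame(lat = lat, flag = flag)
}
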