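# Per-leg migration event table and per-bird annual summaries: site
# classification (main/secondary non-breeding, stopover, breeding), season
# assignment, great-circle leg distances, half-day durations and phenology.

#' Great-circle distance (haversine)
#'
#' Spherical great-circle distance on an Earth of radius 6371.0 km, via
#' `geosphere::distHaversine`.  Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km.
#' @examples
#' haversine(0, 0, 0, 1)  # one equatorial degree, ~111.19 km
#' @export
haversine <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Day-of-year (Julian date)
#'
#' @param date a Date. January 1 is day 1; leap years are honoured.
#' @return integer day of year.
#' @export
julian_date <- function(date) {
  as.POSIXlt(as.Date(date))$yday + 1L
}

#' Classify located stationary periods
#'
#' Applies the study-design rules for an Afro-Palearctic migrant tagged at
#' its non-breeding site:
#' \itemize{
#'   \item `main_nonbreeding`: the period occupied at the tagging site
#'     (the first period of the deployment).
#'   \item `secondary_nonbreeding`: any other sub-Saharan stationary period
#'     (latitude below `sahara_lat`) occurring before the spring Sahara
#'     crossing, displaced at least `min_displacement` km from the tagging
#'     site and lasting at least `min_secondary_days` days.
#'   \item `breeding`: the longest stationary period north of
#'     `breeding_lat_min`.
#'   \item `stopover`: everything else.
#' }
#'
#' @param periods data.frame from [locate_periods()] (needs `period_id`,
#'   `start_date`, `end_date`, `lat`, `lon`, `n_days`).
#' @param tagging_lat,tagging_lon the tagging site.
#' @param sahara_lat latitude (degrees N) separating sub-Saharan Africa from
#'   the Sahara and beyond; default 18.
#' @param min_displacement km from the tagging site below which a
#'   sub-Saharan period is still "the" main non-breeding site; default 250.
#' @param min_secondary_days minimum duration for a secondary non-breeding
#'   site; default 2.
#' @param breeding_lat_min latitude floor for breeding candidates;
#'   default 35 (European breeding range).
#' @return `periods` with a `classification` column added.
#' @export
classify_periods <- function(periods, tagging_lat, tagging_lon,
                             sahara_lat = 18, min_displacement = 250,
                             min_secondary_days = 2,
                             breeding_lat_min = 35) {
  p <- periods[order(periods$start), ]
  cls <- rep("stopover", nrow(p))
  disp <- haversine(p$lat, p$lon, tagging_lat, tagging_lon)

  # the main non-breeding site: at (or within min_displacement of) the
  # tagging site, sub-Saharan -- covers both the deployment period and the
  # return after autumn migration
  cls[!is.na(disp) & disp < min_displacement &
        !is.na(p$lat) & p$lat < sahara_lat] <- "main_nonbreeding"
  cls[1] <- "main_nonbreeding"

  # first crossing out of sub-Saharan Africa bounds the non-breeding season
  north <- which(!is.na(p$lat) & p$lat >= sahara_lat)
  first_crossing <- if (length(north)) min(north) else nrow(p) + 1L

  sec <- which(seq_len(nrow(p)) > 1 & seq_len(nrow(p)) < first_crossing &
                 !is.na(p$lat) & p$lat < sahara_lat &
                 !is.na(disp) & disp >= min_displacement &
                 p$n_days >= min_secondary_days)
  cls[sec] <- "secondary_nonbreeding"

  # breeding = the longest boreal-summer residence north of the floor;
  # the summer condition stops a long spring stopover on a truncated track
  # from being mistaken for the breeding site
  m1 <- as.integer(format(p$start_date, "%m"))
  m2 <- as.integer(format(p$end_date, "%m"))
  in_summer <- m1 <= 7 & m2 >= 6
  cand <- which(!is.na(p$lat) & p$lat > breeding_lat_min & in_summer)
  if (length(cand)) {
    dur <- p$end[cand] - p$start[cand]
    cls[cand[which.max(dur)]] <- "breeding"
  }
  p$classification <- cls
  p[match(periods$period_id, p$period_id), ]
}

#' Build the per-leg migration event table
#'
#' One row per movement between consecutive located stationary periods: the
#' start location is the prior period, the end location the following one.
#' Distance is the great-circle distance between the two period locations;
#' duration runs from the departure (end of the prior period, half-day
#' resolution) to the arrival (start of the next); speed is
#' distance / (24 x duration).
#'
#' @param periods classified, located periods (ordered in time).
#' @param bird_id,country identifiers copied into every row.
#' @return data.frame, one row per leg: ids, start/end dates and half-day
#'   offsets, from/to period ids and classifications, `distance_km`,
#'   `duration_days`, `speed_kmh`, `season`, `equinox_flag`.
#' @export
build_leg_table <- function(periods, bird_id = NA, country = NA) {
  p <- periods[order(periods$start), ]
  if (nrow(p) < 2) return(NULL)
  i <- seq_len(nrow(p) - 1)
  legs <- data.frame(
    bird_id = bird_id, country = country, leg_id = i,
    from_period_id = p$period_id[i], to_period_id = p$period_id[i + 1],
    from_class = p$classification[i], to_class = p$classification[i + 1],
    start = p$end[i], end = p$start[i + 1],
    start_date = p$end_date[i], end_date = p$start_date[i + 1],
    from_lat = p$lat[i], from_lon = p$lon[i],
    to_lat = p$lat[i + 1], to_lon = p$lon[i + 1],
    distance_km = haversine(p$lat[i], p$lon[i], p$lat[i + 1], p$lon[i + 1]),
    duration_days = p$start[i + 1] - p$end[i]
  )
  legs$speed_kmh <- legs$distance_km / (24 * legs$duration_days)
  legs$equinox_flag <- flag_equinox(legs$start_date, legs$end_date)
  legs$season <- assign_season(legs)
  legs
}

#' Assign a season to each migration leg
#'
#' Spring covers the movements from the last sub-Saharan site up to arrival
#' at the breeding site; autumn covers breeding departure back to the main
#' non-breeding arrival.  Movements between sub-Saharan non-breeding sites
#' before the spring Sahara crossing are `intra_african`; with
#' `include_subsaharan = TRUE` they are folded into spring, mirroring the
#' with/without-sub-Saharan-sites analysis toggle.
#'
#' @param legs leg table (needs `from_class`, `to_class`, ordered rows).
#' @param include_subsaharan fold intra-African moves into spring?
#' @return character vector of seasons.
#' @export
assign_season <- function(legs, include_subsaharan = FALSE) {
  n <- nrow(legs)
  season <- rep("spring", n)
  breed_arrival <- which(legs$to_class == "breeding")
  breed_departure <- which(legs$from_class == "breeding")
  if (length(breed_arrival) && length(breed_departure) &&
      min(breed_departure) < max(breed_arrival))
    stop("unordered phenology: breeding departure precedes arrival")
  if (length(breed_departure))
    season[seq_len(n) >= min(breed_departure)] <- "autumn"
  intra <- legs$to_class %in% c("secondary_nonbreeding", "main_nonbreeding") &
    season == "spring"
  season[intra] <- "intra_african"
  if (include_subsaharan) season[season == "intra_african"] <- "spring"
  season
}

#' Summarise one bird's annual cycle
#'
#' Seasonal totals (distance, leg-duration, stopover counts), end-to-end
#' durations and the four phenology dates.  Spring runs from departure from
#' the last sub-Saharan site (or the main non-breeding site when
#' `exclude_subsaharan = FALSE` folds intra-African moves in) to breeding
#' arrival; autumn from breeding departure to arrival at the final
#' non-breeding site.  Stopovers are stationary periods strictly between a
#' season's endpoints; the breeding period is never a stopover.
#'
#' @param periods classified located periods of the bird.
#' @param legs leg table from [build_leg_table()].
#' @param exclude_subsaharan drop intra-African legs/stopovers from the
#'   spring totals (TRUE, the default) or fold them in (FALSE).
#' @param origin date at numeric offset 0 (series start), used to convert
#'   half-day offsets to dates.
#' @return one-row data.frame with totals, counts, phenology (Julian days)
#'   and a `completeness` category (`full`, `to_breeding`, `failed_spring`,
#'   `failed_autumn`).
#' @export
summarise_bird <- function(periods, legs, exclude_subsaharan = TRUE,
                           origin = NULL) {
  p <- periods[order(periods$start), ]
  season <- assign_season(legs, include_subsaharan = !exclude_subsaharan)
  spring <- legs[season == "spring", , drop = FALSE]
  autumn <- legs[season == "autumn", , drop = FALSE]

  breeding <- p[p$classification == "breeding", , drop = FALSE]
  has_breeding <- nrow(breeding) == 1
  # completeness from which endpoints exist
  reached_home <- has_breeding && nrow(autumn) > 0 &&
    (utils::tail(autumn$to_class, 1) == "main_nonbreeding" ||
       utils::tail(autumn$to_lat, 1) < 18)
  completeness <- if (has_breeding && reached_home) "full"
  else if (has_breeding && nrow(autumn) == 0) "to_breeding"
  else if (!has_breeding) "failed_spring"
  else "failed_autumn"

  stopovers_in <- function(lg) {
    if (nrow(lg) < 2) return(0L)
    sum(p$period_id %in% lg$from_period_id[-1] &
          p$classification == "stopover")
  }
  phen <- function(x) if (length(x)) julian_date(x[[1]]) else NA_integer_

  data.frame(
    bird_id = legs$bird_id[1], country = legs$country[1],
    completeness = completeness,
    total_distance_spring = sum(spring$distance_km),
    total_distance_autumn = sum(autumn$distance_km),
    n_stopovers_spring = stopovers_in(spring),
    n_stopovers_autumn = stopovers_in(autumn),
    total_duration_spring = if (nrow(spring))
      max(spring$end) - min(spring$start) else NA_real_,
    total_duration_autumn = if (nrow(autumn))
      max(autumn$end) - min(autumn$start) else NA_real_,
    depart_nonbreeding = phen(spring$start_date[1]),
    arrive_breeding = phen(utils::tail(spring$end_date, 1)),
    depart_breeding = phen(autumn$start_date[1]),
    arrive_nonbreeding = phen(utils::tail(autumn$end_date, 1)),
    breeding_duration = if (has_breeding)
      breeding$end - breeding$start else NA_real_,
    breeding_lat = if (has_breeding) breeding$lat else NA_real_,
    breeding_lon = if (has_breeding) breeding$lon else NA_real_
  )
}
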