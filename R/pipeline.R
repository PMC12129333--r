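# End-to-end pipeline: simulate or load twilight series, segment, calibrate
# and locate, build event tables and summaries, compute cohort statistics,
# and write every artifact as plain CSV/JSON.  All randomness flows from
# the seeds in the config, so a rerun with the same config is
# bit-identical.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list.
#'
#' @param sun_elevation_grid calibration search grid, degrees.
#' @param shift_threshold,cum_threshold,min_stationary segmentation
#'   parameters (minutes, minutes, days).
#' @param sahara_lat,min_displacement,breeding_lat_min classification
#'   parameters (degrees, km, degrees).
#' @param exclude_subsaharan drop intra-African movements from spring
#'   totals (default TRUE).
#' @param lat_range latitude search band for geolocation.
#' @param flight_speed airborne speed for flight-time partitioning, km/h.
#' @param n_resamples spread-CI resamples.
#' @param n_permutations loop-contrast permutations.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sun_elevation_grid = seq(-9, 3, by = 0.1),
                            shift_threshold = 15, cum_threshold = 30,
                            min_stationary = 2, sahara_lat = 18,
                            min_displacement = 250, breeding_lat_min = 35,
                            exclude_subsaharan = TRUE,
                            lat_range = c(-40, 80), flight_speed = 43,
                            n_resamples = 10000, n_permutations = 2000,
                            seed = 1) {
  stopifnot(shift_threshold > 0, cum_threshold > 0, min_stationary >= 1,
            min_displacement > 0, n_resamples > 0, n_permutations > 0,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Process one bird from twilight series to located periods and legs
#'
#' Chains segmentation, calibration at the tagging site (the first detected
#' stationary period, where location is certain), threshold geolocation of
#' every stationary period, classification and the per-leg event table.
#'
#' @param twilights twilight series for the bird.
#' @param tagging_lat,tagging_lon the known tagging site.
#' @param bird_id,country identifiers.
#' @param config a [pipeline_config()].
#' @return list: `calibration`, `segments`, `periods` (located and
#'   classified), `legs`, `summary`, `exclusions` (named counts of days
#'   excluded and why).
#' @export
process_bird <- function(twilights, tagging_lat, tagging_lon,
                         bird_id = "bird01", country = NA,
                         config = pipeline_config()) {
  segments <- detect_stationary_periods(
    twilights, shift_threshold = config$shift_threshold,
    cum_threshold = config$cum_threshold,
    min_stationary = config$min_stationary)

  # calibration uses the deployment period at the tagging site
  first_id <- segments$period_id[!is.na(segments$period_id)][1]
  calib_days <- segments$date[!is.na(segments$period_id) &
                                segments$period_id == first_id]
  calib <- calibrate_sun_elevation(
    twilights[twilights$date %in% calib_days, ],
    tagging_lat, tagging_lon, grid = config$sun_elevation_grid)

  periods <- locate_periods(twilights, segments, calib$sun_elevation,
                            lat_range = config$lat_range)
  periods <- classify_periods(periods, tagging_lat, tagging_lon,
                              sahara_lat = config$sahara_lat,
                              min_displacement = config$min_displacement,
                              breeding_lat_min = config$breeding_lat_min)
  legs <- build_leg_table(periods, bird_id = bird_id, country = country)
  summary <- if (!is.null(legs))
    summarise_bird(periods, legs,
                   exclude_subsaharan = config$exclude_subsaharan) else NULL

  n_eq <- sum(vapply(split(twilights, format(twilights$date)), function(d)
    any(flag_equinox(d$date)), logical(1)))
  exclusions <- c(
    missing_days = sum(is.na(twilights$sunrise_utc)),
    polar_days = if (is.null(twilights$polar_flag)) 0L
    else sum(twilights$polar_flag != "none"),
    equinox_days = n_eq)

  list(calibration = calib, segments = segments, periods = periods,
       legs = legs, summary = summary, exclusions = exclusions)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates `n_birds` tracks, renders their twilight series, processes each
#' bird, stacks the event tables and annual summaries, and computes the
#' cohort statistics (per-country migratory spread with randomization CI,
#' breeding-range polygons and overlap, loop contrast).  If `out_dir` is
#' given, writes segmentation, located periods, the event table, summaries
#' (CSV), statistics (JSON) and the range polygons (GeoJSON).
#'
#' @param n_birds cohort size.
#' @param config a [pipeline_config()].
#' @param noise a [noise_model()].
#' @param out_dir optional output directory.
#' @param ... passed to [simulate_track()] via [simulate_cohort()].
#' @return list: `birds` (per-bird results), `legs`, `summaries`,
#'   `stats`, `log`.
#' @export
run_pipeline <- function(n_birds = 8, config = pipeline_config(),
                         noise = noise_model(), out_dir = NULL, ...) {
  tracks <- simulate_cohort(n_birds, seed = config$seed, ...)
  birds <- vector("list", n_birds)
  for (i in seq_len(n_birds)) {
    tr <- tracks[[i]]
    sim <- simulate_twilights(tr, noise = noise, seed = config$seed + i)
    main <- tr$sites[tr$sites$label == "main_nonbreeding", ][1, ]
    birds[[i]] <- tryCatch(
      process_bird(sim$twilights, main$lat, main$lon,
                   bird_id = tr$bird_id, country = tr$country,
                   config = config),
      error = function(e) list(error = conditionMessage(e)))
    birds[[i]]$track <- tr
  }
  ok <- !vapply(birds, function(b) !is.null(b$error), logical(1))
  legs <- do.call(rbind, lapply(birds[ok], `[[`, "legs"))
  summaries <- do.call(rbind, lapply(birds[ok], `[[`, "summary"))

  stats_out <- cohort_stats(birds[ok], summaries, config)
  log <- list(
    n_birds = n_birds, n_processed = sum(ok),
    failures = vapply(birds[!ok], `[[`, character(1), "error"),
    exclusions = Reduce(`+`, lapply(birds[ok], `[[`, "exclusions")))

  res <- list(birds = birds, legs = legs, summaries = summaries,
              stats = stats_out, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Cohort statistics from processed birds
#'
#' @param birds list of [process_bird()] results.
#' @param summaries stacked annual summaries.
#' @param config a [pipeline_config()].
#' @return list with per-country spread, range polygons, overlap fractions
#'   and the loop contrast (NULL entries where a country has too few birds).
#' @export
cohort_stats <- function(birds, summaries, config = pipeline_config()) {
  br <- summaries[!is.na(summaries$breeding_lat), , drop = FALSE]
  per_country <- lapply(split(br, br$country), function(d) {
    spread <- if (nrow(d) >= 2)
      migratory_spread(d$breeding_lat, d$breeding_lon,
                       n_resamples = config$n_resamples,
                       seed = config$seed) else NULL
    poly <- if (nrow(d) >= 3)
      tryCatch(convex_range(d$breeding_lat, d$breeding_lon),
               error = function(e) NULL) else NULL
    list(n = nrow(d), spread = spread, range = poly)
  })
  polys <- Filter(Negate(is.null), lapply(per_country, `[[`, "range"))
  overlap <- if (length(polys) >= 2)
    range_overlap(polys[[1]], polys[[2]]) else NULL

  stop_rows <- do.call(rbind, lapply(birds, function(b) {
    if (is.null(b$legs)) return(NULL)
    p <- b$periods
    st <- p[p$classification == "stopover", , drop = FALSE]
    if (!nrow(st)) return(NULL)
    season <- vapply(st$period_id, function(pid) {
      lg <- b$legs[b$legs$to_period_id == pid, , drop = FALSE]
      if (nrow(lg)) lg$season[1] else NA_character_
    }, character(1))
    data.frame(bird_id = b$legs$bird_id[1], season = season, lon = st$lon)
  }))
  loop <- if (!is.null(stop_rows)) tryCatch(
    loop_contrast(stop_rows[stop_rows$season %in% c("spring", "autumn"), ],
                  n_permutations = config$n_permutations,
                  seed = config$seed),
    error = function(e) NULL) else NULL

  list(per_country = per_country, overlap = overlap, loop = loop)
}

#' Write pipeline artifacts to disk
#'
#' CSV for tabular artifacts, JSON for the statistics report, GeoJSON for
#' range polygons and period locations.
#'
#' @param res result of [run_pipeline()].
#' @param out_dir directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  seg <- do.call(rbind, lapply(res$birds, function(b) {
    if (is.null(b$segments)) return(NULL)
    cbind(bird_id = b$track$bird_id, b$segments)
  }))
  per <- do.call(rbind, lapply(res$birds, function(b) {
    if (is.null(b$periods)) return(NULL)
    cbind(bird_id = b$track$bird_id, b$periods)
  }))
  w(seg, "segmentation.csv")
  w(per, "periods.csv")
  w(res$legs, "event_table.csv")
  w(res$summaries, "summaries.csv")

  stats <- res$stats
  report <- list(
    per_country = lapply(stats$per_country, function(pc) list(
      n = pc$n,
      spread = pc$spread[c("mean_pairwise_km", "ci_low_km", "ci_high_km")],
      range_km2 = if (!is.null(pc$range)) pc$range$area_km2 else NULL)),
    overlap = stats$overlap,
    loop = if (!is.null(stats$loop))
      stats$loop[c("mean_delta_lon", "p_value", "n_birds")] else NULL,
    log = res$log[c("n_birds", "n_processed", "exclusions")])
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  polys <- Filter(Negate(is.null),
                  lapply(stats$per_country, `[[`, "range"))
  if (length(polys))
    write_geojson_polygons(polys, file.path(out_dir, "ranges.geojson"))
  invisible(out_dir)
}

#' Write range polygons as GeoJSON
#'
#' @param polys named list of `range_polygon` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polys, path) {
  features <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ring <- cbind(p$lon, p$lat)
    ring <- rbind(ring, ring[1, ])   # closed ring
    list(type = "Feature",
         properties = list(name = names(polys)[i] %||% paste0("range", i),
                           area_km2 = p$area_km2),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(
                           seq_len(nrow(ring)),
                           function(k) c(ring[k, 1], ring[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a twilight series as CSV
#'
#' Dialect: columns `date` (ISO-8601), `sunrise_utc`, `sunset_utc`
#' (decimal hours UTC).
#'
#' @param twilights data.frame.
#' @param path output file.
#' @export
write_twilight_csv <- function(twilights, path) {
  utils::write.csv(twilights[, c("date", "sunrise_utc", "sunset_utc")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a twilight CSV
#'
#' @param path file written by [write_twilight_csv()] (or any CSV with
#'   `date`, `sunrise_utc`, `sunset_utc` columns).
#' @return data.frame with `date` parsed as `Date`.
#' @export
read_twilight_csv <- function(path) {
  if (!file.exists(path)) stop("twilight file not found: ", path)
  d <- utils::read.csv(path)
  stopifnot(all(c("date", "sunrise_utc", "sunset_utc") %in% names(d)))
  d$date <- as.Date(d$date)
  d
}
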