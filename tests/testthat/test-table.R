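test_that("haversine matches closed-form anchors", {
  expect_identical(haversine(10, 20, 10, 20), 0)
  # half the circumference of a 6371-km sphere
  expect_equal(haversine(0, 0, 0, 180), pi * 6371, tolerance = 0.1)
  # one equatorial degree
  expect_equal(haversine(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 0.01)
})

test_that("day-of-year handles leap years", {
  expect_identical(julian_date(as.Date("2019-01-01")), 1L)
  expect_identical(julian_date(as.Date("2019-04-09")), 99L)
  expect_identical(julian_date(as.Date("2020-12-31")), 366L)
  expect_identical(julian_date(as.Date("2019-12-31")), 365L)
})

# helper: periods table straight from a simulated track's truth (isolates
# the classification rules from the segmentation stage)
truth_periods <- function(tr) {
  s <- tr$sites
  data.frame(period_id = seq_len(nrow(s)), start = s$arrive, end = s$depart,
             start_date = tr$origin + floor(s$arrive),
             end_date = tr$origin + floor(s$depart),
             n_days = s$depart - s$arrive,
             lat = s$lat, lon = s$lon)
}

test_that("a planted 500-km secondary site is classified secondary_nonbreeding", {
  tr <- simulate_track(seed = 2)   # this seed draws a secondary site
  expect_true("secondary_nonbreeding" %in% tr$sites$label)
  p <- classify_periods(truth_periods(tr), tr$sites$lat[1], tr$sites$lon[1])
  expect_identical(p$classification[tr$sites$label == "secondary_nonbreeding"],
                   "secondary_nonbreeding")
  expect_identical(p$classification[1], "main_nonbreeding")
  expect_identical(p$classification[tr$sites$label == "breeding"], "breeding")
})

test_that("a 100-km shift stays part of the main non-breeding site", {
  tr <- simulate_track(seed = 2, p_secondary = 0)
  p <- truth_periods(tr)
  # insert a nearby period before spring departure
  near <- p[1, ]
  near$period_id <- 99
  near$start <- p$end[1] - 20; near$end <- p$end[1] - 10
  near$lat <- p$lat[1] + 0.9   # ~100 km north
  p$end[1] <- near$start - 1
  p2 <- rbind(p[1, ], near, p[-1, ])
  p2 <- classify_periods(p2, tr$sites$lat[1], tr$sites$lon[1])
  expect_identical(p2$classification[p2$period_id == 99], "main_nonbreeding")
})

test_that("season assignment splits at breeding and the sub-Saharan toggle
          moves exactly the intra-African component", {
  tr <- simulate_track(seed = 2)
  p <- classify_periods(truth_periods(tr), tr$sites$lat[1], tr$sites$lon[1])
  legs <- build_leg_table(p, bird_id = "b", country = "Nigeria")
  expect_identical(legs$season[legs$to_class == "breeding"], "spring")
  expect_true(all(legs$season[legs$from_class == "breeding"] == "autumn"))
  s_excl <- assign_season(legs, include_subsaharan = FALSE)
  s_incl <- assign_season(legs, include_subsaharan = TRUE)
  moved <- which(s_excl != s_incl)
  expect_true(all(s_excl[moved] == "intra_african"))
  expect_true(all(s_incl[moved] == "spring"))
  # accounting identity on spring totals
  d_excl <- sum(legs$distance_km[s_excl == "spring"])
  d_incl <- sum(legs$distance_km[s_incl == "spring"])
  expect_equal(d_incl - d_excl,
               sum(legs$distance_km[s_excl == "intra_african"]))
})

test_that("annual summary totals equal the truth-table sums", {
  for (s in c(2, 6)) {
    tr <- simulate_track(seed = s)
    p <- classify_periods(truth_periods(tr), tr$sites$lat[1],
                          tr$sites$lon[1])
    legs <- build_leg_table(p, bird_id = "b", country = tr$country)
    sm <- summarise_bird(p, legs, exclude_subsaharan = TRUE)
    expect_identical(sm$completeness, "full")
    season <- assign_season(legs)
    expect_equal(sm$total_distance_spring,
                 sum(legs$distance_km[season == "spring"]))
    expect_equal(sm$total_distance_autumn,
                 sum(legs$distance_km[season == "autumn"]))
    # triangle inequality: going through stopovers is never shorter than
    # the direct great circle
    br <- p[p$classification == "breeding", ]
    direct <- haversine(p$lat[1], p$lon[1], br$lat, br$lon)
    expect_gte(sm$total_distance_spring + 1e-6, direct)
    # ordered phenology
    expect_true(sm$depart_nonbreeding < sm$arrive_breeding)
    expect_true(sm$arrive_breeding < sm$depart_breeding)
    expect_true(sm$depart_breeding < sm$arrive_nonbreeding)
  }
})

test_that("leg durations plus stopover durations add to the season span", {
  tr <- simulate_track(seed = 6, p_secondary = 0)
  p <- classify_periods(truth_periods(tr), tr$sites$lat[1], tr$sites$lon[1])
  legs <- build_leg_table(p, bird_id = "b")
  season <- assign_season(legs)
  spring <- legs[season == "spring", ]
  stop_dur <- sum(p$end[p$period_id %in% spring$from_period_id[-1]] -
                    p$start[p$period_id %in% spring$from_period_id[-1]])
  expect_equal(sum(spring$duration_days) + stop_dur,
               max(spring$end) - min(spring$start))
})

test_that("a single-leg migration has the direct distance and no stopovers", {
  p <- data.frame(period_id = 1:2, start = c(0, 105), end = c(100, 200),
                  start_date = as.Date("2018-12-01") + c(0, 105),
                  end_date = as.Date("2018-12-01") + c(100, 200),
                  n_days = c(100, 95), lat = c(10, 50), lon = c(9, 25))
  p <- classify_periods(p, 10, 9)
  legs <- build_leg_table(p, bird_id = "b")
  expect_identical(nrow(legs), 1L)
  expect_equal(legs$distance_km, haversine(10, 9, 50, 25))
  sm <- summarise_bird(p, legs)
  expect_identical(sm$n_stopovers_spring, 0L)
})
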