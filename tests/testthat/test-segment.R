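test_that("twilight extraction takes first and last lit record per day", {
  days <- seq(as.Date("2019-01-01"), by = "day", length.out = 3)
  log <- render_light_log(data.frame(date = days, sunrise_utc = 6,
                                     sunset_utc = 18), interval_min = 10)
  tw <- extract_twilights_from_light(log, threshold = 0)
  expect_equal(tw$sunrise_utc, rep(6, 3), tolerance = 1e-9)
  expect_equal(tw$sunset_utc, rep(18, 3), tolerance = 1e-9)
  expect_false(any(tw$missing))
})

test_that("an all-dark day is flagged missing, not a zero-length day", {
  days <- seq(as.Date("2019-01-01"), by = "day", length.out = 3)
  tw0 <- data.frame(date = days, sunrise_utc = c(6, NA, 6),
                    sunset_utc = c(18, NA, 18))
  log <- render_light_log(tw0, interval_min = 10)
  tw <- extract_twilights_from_light(log, threshold = 0)
  expect_true(tw$missing[2])
  expect_true(is.na(tw$sunrise_utc[2]))
  expect_identical(nrow(tw), 3L)
})

test_that("empty or unsorted light logs are rejected", {
  expect_error(extract_twilights_from_light(
    data.frame(timestamp = as.POSIXct(character()), light = numeric())),
    "empty")
  bad <- data.frame(
    timestamp = as.POSIXct(c("2019-01-01 12:00", "2019-01-01 06:00"),
                           tz = "UTC"),
    light = c(64, 64))
  expect_error(extract_twilights_from_light(bad), "ordered")
})

test_that("clock drift correction is linear and invertible", {
  tw <- site_twilights(10, 0, "2019-01-01", 101)
  expect_identical(correct_clock_drift(tw, 0), tw)
  shifted <- correct_clock_drift(tw, 10)
  # halfway through a 100-day span the shift is 5 minutes
  expect_equal((tw$sunrise_utc[51] - shifted$sunrise_utc[51]) * 60, 5,
               tolerance = 1e-9)
  # simulated drift, then correction, recovers the clean series
  tr <- simulate_track(seed = 6)
  clean <- simulate_twilights(tr, noise = noise_model(0, 0, 0), seed = 1)
  drifted <- simulate_twilights(tr, noise = noise_model(0, 0, 0,
                                                        clock_drift = 12),
                                seed = 1)
  fixed <- correct_clock_drift(drifted$twilights, 12)
  ok <- clean$twilights$polar_flag == "none"
  expect_lt(max(abs(fixed$sunrise_utc[ok] -
                      clean$twilights$sunrise_utc[ok])) * 60, 0.1)
})

test_that("equinox windows are flagged correctly", {
  expect_true(flag_equinox(as.Date("2019-03-18"), as.Date("2019-03-21")))
  expect_true(flag_equinox(as.Date("2019-09-20")))
  expect_false(flag_equinox(as.Date("2019-06-01"), as.Date("2019-06-04")))
  expect_false(flag_equinox(as.Date("2019-03-28")))
  # interval spanning a year boundary still sees the spring window
  expect_true(flag_equinox(as.Date("2018-12-01"), as.Date("2019-03-15")))
})

test_that("a constant twilight series is one stationary period", {
  tw <- site_twilights(10, 0, "2019-01-01", 30)
  seg <- detect_stationary_periods(tw)
  expect_true(all(seg$state == "stationary"))
  expect_identical(unique(seg$period_id), 1L)
})

test_that("a 10-degree longitude jump splits two stationary periods
          within a day of the true boundary", {
  d1 <- site_twilights(10, 0, "2019-01-01", 20)
  d2 <- site_twilights(10, 10, "2019-01-21", 20)
  seg <- detect_stationary_periods(rbind(d1, d2))
  pb <- period_boundaries(seg)
  # one period per site, with boundaries within a day of the jump
  expect_true(any(pb$start <= 1 & abs(pb$end - 19.5) <= 1))
  expect_true(any(abs(pb$start - 20) <= 1 & pb$end >= 38.5))
})

test_that("a 4.2-degree relocation (~17-minute twilight shift) is
          detected at default thresholds", {
  d1 <- site_twilights(15, 0, "2019-05-01", 15)
  d2 <- site_twilights(15, 4.4, "2019-05-16", 15)
  seg <- detect_stationary_periods(rbind(d1, d2))
  expect_identical(max(seg$period_id, na.rm = TRUE), 2L)
})

test_that("detection is invariant to a constant clock offset", {
  tr <- simulate_track(seed = 8)
  sim <- simulate_twilights(tr, noise = noise_model(0, 0, 0), seed = 1)
  seg1 <- detect_stationary_periods(sim$twilights)
  shifted <- sim$twilights
  shifted$sunrise_utc <- shifted$sunrise_utc + 0.5
  shifted$sunset_utc <- shifted$sunset_utc + 0.5
  seg2 <- detect_stationary_periods(shifted)
  expect_identical(seg1$state, seg2$state)
  expect_identical(seg1$period_id, seg2$period_id)
})

test_that("segment labels partition all days and respect the 2-day minimum", {
  for (s in c(3, 9, 14)) {
    tr <- simulate_track(seed = s)
    sim <- simulate_twilights(tr, seed = s)
    seg <- detect_stationary_periods(sim$twilights)
    expect_identical(nrow(seg), nrow(sim$twilights))
    expect_false(any(is.na(seg$state)))
    expect_true(all(xor(is.na(seg$period_id), is.na(seg$leg_id))))
    runs <- rle(paste(seg$state, seg$period_id))
    st <- grepl("stationary", runs$values)
    expect_true(all(runs$lengths[st] >= 2))
  }
})

test_that("noise-free sites are recovered to sub-degree longitude
          through segmentation plus geolocation", {
  tr <- simulate_track(seed = 10)
  sim <- simulate_twilights(tr, noise = noise_model(0, 0, 0), seed = 1)
  seg <- detect_stationary_periods(sim$twilights)
  main <- tr$sites[1, ]
  cal <- calibrate_sun_elevation(
    sim$twilights[sim$twilights$date %in%
                    seg$date[!is.na(seg$period_id) & seg$period_id == 1], ],
    main$lat, main$lon)
  per <- locate_periods(sim$twilights, seg, cal$sun_elevation)
  # match each located period to the nearest true site by time
  err <- vapply(seq_len(nrow(per)), function(i) {
    truth <- tr$sites[which.min(abs(tr$sites$arrive - per$start[i])), ]
    abs(per$lon[i] - truth$lon)
  }, numeric(1))
  expect_lt(stats::median(err), 0.1)
})
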