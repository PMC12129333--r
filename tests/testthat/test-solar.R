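test_that("declination matches equinox and solstice anchors", {
  expect_lt(abs(solar_declination(as.Date("2019-03-20"))), 1)
  expect_equal(solar_declination(as.Date("2019-06-21")), 23.44,
               tolerance = 0.02)
  expect_equal(solar_declination(as.Date("2019-12-22")), -23.44,
               tolerance = 0.02)
})

test_that("declination and equation of time agree with the Spencer series", {
  dates <- seq(as.Date("2019-01-05"), as.Date("2019-12-20"), by = "11 days")
  mine <- solar_position(dates)
  oracle <- spencer_solar(dates)
  # each series is itself only good to ~0.3 deg; allow the sum
  expect_lt(max(abs(mine$declination - oracle$declination)), 0.4)
  expect_lt(max(abs(mine$equation_of_time - oracle$equation_of_time)), 1)
  # physical bounds
  expect_true(all(abs(mine$declination) <= 23.45))
  expect_true(all(abs(mine$equation_of_time) <= 17))
})

test_that("equatorial equinox twilights sit near 06:00/18:00 UTC", {
  tt <- twilight_times(0, 0, as.Date("2019-03-20"), 0)
  expect_equal(tt$sunrise_utc, 6, tolerance = 0.3)   # within EoT
  expect_equal(tt$sunset_utc, 18, tolerance = 0.3)
  expect_identical(tt$polar_flag, "none")
})

test_that("Arctic midsummer is flagged polar day", {
  tt <- twilight_times(70, 0, as.Date("2019-06-21"), 0)
  expect_identical(tt$polar_flag, "polar_day")
  expect_true(is.na(tt$sunrise_utc))
  tn <- twilight_times(70, 0, as.Date("2019-12-21"), 0)
  expect_identical(tn$polar_flag, "polar_night")
})

test_that("twilight pair matches the independent oracle within 2 minutes", {
  tt <- twilight_times(50, 10, as.Date("2019-10-01"), -3.5)
  or <- spencer_twilight(50, 10, as.Date("2019-10-01"), -3.5)
  expect_lt(abs(tt$sunrise_utc - or["sunrise"]) * 60, 2)
  expect_lt(abs(tt$sunset_utc - or["sunset"]) * 60, 2)
})

test_that("longitude from twilights: midpoint at 12:00 with zero EoT is 0", {
  # construct a pair whose midpoint equals solar noon at Greenwich
  d <- as.Date("2019-04-15")
  eot_h <- equation_of_time(d) / 60
  tw <- data.frame(date = d, sunrise_utc = 12 - eot_h - 5,
                   sunset_utc = 12 - eot_h + 5)
  expect_equal(longitude_from_twilights(tw), 0, tolerance = 1e-9)
})

test_that("one degree of longitude shifts both twilights by 4 minutes", {
  d <- as.Date("2019-05-10")
  a <- twilight_times(40, 10, d, -3.5)
  b <- twilight_times(40, 11, d, -3.5)
  # the easterly site sees the sun 4 minutes earlier
  expect_equal((a$sunrise_utc - b$sunrise_utc) * 60, 4, tolerance = 1e-9)
  expect_equal((a$sunset_utc - b$sunset_utc) * 60, 4, tolerance = 1e-9)
  # equinox detectability logic: a 4.2-degree relocation moves both
  # twilights by ~17 minutes
  shift <- 4.2 * 4
  expect_equal(round(shift), 17)
})

test_that("latitude is undefined at the equinox (any latitude fits)", {
  r <- latitude_from_daylength(12, as.Date("2019-03-20"), 0)
  expect_true(is.na(r$lat))
  expect_identical(r$flag, "equinox_degenerate")
})

test_that("latitude inversion recovers the generating latitude", {
  tt <- twilight_times(50, 0, as.Date("2019-05-20"), 0)
  r <- latitude_from_daylength(tt$sunset_utc - tt$sunrise_utc,
                               as.Date("2019-05-20"), 0)
  expect_equal(r$lat, 50, tolerance = 0.1)
})

test_that("polar day lengths are flagged, not extrapolated", {
  # 23.9 h of daylight in mid-northern winter fits no latitude in band
  r <- latitude_from_daylength(23.9, as.Date("2019-12-21"), 0,
                               lat_range = c(-40, 80))
  expect_true(is.na(r$lat))
  expect_identical(r$flag, "no_solution")
})

test_that("forward-inverse consistency holds away from degeneracy", {
  set.seed(42)
  n <- 0
  for (k in 1:300) {
    lat <- runif(1, -35, 60)
    lon <- runif(1, -179, 179)
    a <- runif(1, -6, 0)
    d <- as.Date("2019-01-01") + sample(0:364, 1)
    if (abs(solar_declination(d)) < 4) next  # off-equinox only
    tt <- twilight_times(lat, lon, d, a)
    if (tt$polar_flag != "none") next
    lon_hat <- longitude_from_twilights(tt)
    r <- latitude_from_daylength(tt$sunset_utc - tt$sunrise_utc,
                                 d, a, lat_range = c(-89, 89))
    if (r$flag == "ambiguous") next  # two-root days are flagged, not guessed
    expect_lt(abs(lon_hat - lon), 0.05)
    expect_lt(abs(r$lat - lat), 0.5)
    n <- n + 1
  }
  expect_gt(n, 100)  # the sweep actually exercised many cases
})

test_that("day length is monotone in latitude away from the equinoxes", {
  lats <- seq(0, 60, by = 5)
  dl <- function(d) {
    tt <- twilight_times(lats, 0, d, 0)
    tt$sunset_utc - tt$sunrise_utc
  }
  expect_true(all(diff(dl(as.Date("2019-06-21"))) > 0))  # boreal summer
  expect_true(all(diff(dl(as.Date("2019-12-21"))) < 0))  # boreal winter
})
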