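test_that("migratory spread equals the exhaustive pairwise mean and its
          randomization CI matches exhaustive quantiles", {
  set.seed(12)
  lat <- runif(8, 50, 65); lon <- runif(8, 5, 35)
  sp <- migratory_spread(lat, lon, n_resamples = 20000, seed = 99)
  # brute-force oracle: double loop over unordered pairs
  d <- c()
  for (i in 1:7) for (j in (i + 1):8)
    d <- c(d, haversine(lat[i], lon[i], lat[j], lon[j]))
  expect_equal(sp$mean_pairwise_km, mean(d), tolerance = 1e-9)
  expect_equal(sp$ci_low_km, unname(quantile(d, 0.025, type = 1)),
               tolerance = 0.1 * diff(range(d)))
  expect_equal(sp$ci_high_km, unname(quantile(d, 0.975, type = 1)),
               tolerance = 0.1 * diff(range(d)))
  expect_lte(sp$ci_low_km, sp$ci_high_km)
})

test_that("degenerate spreads behave: two points and identical points", {
  two <- migratory_spread(c(50, 51), c(10, 10), n_resamples = 100, seed = 1)
  expect_equal(two$ci_low_km, two$mean_pairwise_km)
  expect_equal(two$ci_high_km, two$mean_pairwise_km)
  same <- migratory_spread(rep(50, 4), rep(10, 4), n_resamples = 100,
                           seed = 1)
  expect_equal(same$mean_pairwise_km, 0)
  expect_error(migratory_spread(50, 10), "at least 2")
})

test_that("spread CI is stable in the number of resamples", {
  set.seed(4)
  lat <- runif(10, 45, 65); lon <- runif(10, 0, 40)
  a <- migratory_spread(lat, lon, n_resamples = 1000, seed = 5)
  b <- migratory_spread(lat, lon, n_resamples = 100000, seed = 5)
  expect_lt(abs(a$ci_low_km - b$ci_low_km) / b$ci_high_km, 0.05)
  expect_lt(abs(a$ci_high_km - b$ci_high_km) / b$ci_high_km, 0.05)
})

test_that("convex range of a one-degree equatorial box has the closed-form
          area and ignores interior points", {
  lat <- c(-0.5, -0.5, 0.5, 0.5)
  lon <- c(-0.5, 0.5, -0.5, 0.5)
  r <- convex_range(lat, lon)
  side <- 2 * pi * 6371 / 360
  expect_equal(r$area_km2, side^2, tolerance = side^2 * 0.005)
  r2 <- convex_range(c(lat, 0), c(lon, 0))    # add interior point
  expect_equal(r2$area_km2, r$area_km2, tolerance = 1e-6)
  expect_identical(length(r2$lat), 4L)
})

test_that("collinear points are rejected with a count", {
  expect_error(convex_range(c(0, 1, 2), c(0, 0, 0)), "collinear")
  expect_error(convex_range(c(0, 0, 0), c(5, 5, 5)), "3 distinct")
})

test_that("range overlap fractions are exact on constructed geometry", {
  sq <- function(lon0, lon1) convex_range(
    lat = c(49.5, 49.5, 50.5, 50.5), lon = c(lon0, lon1, lon0, lon1))
  A <- sq(0, 2)
  ident <- range_overlap(A, A)
  expect_equal(ident$frac_A, 1, tolerance = 1e-6)
  expect_equal(ident$frac_union, 1, tolerance = 1e-6)
  B <- sq(0, 1)   # left half of A
  half <- range_overlap(A, B)
  expect_equal(half$frac_A, 0.5, tolerance = 0.01)
  expect_equal(half$frac_B, 1, tolerance = 0.01)
  expect_equal(half$frac_union, 0.5, tolerance = 0.01)
  C <- sq(10, 12)  # disjoint
  none <- range_overlap(A, C)
  expect_identical(none$overlap_km2, 0)
  expect_equal(none$frac_union, 0)
  # general bound: overlap/union never exceeds either single fraction
  expect_lte(half$frac_union, min(half$frac_A, half$frac_B) + 1e-12)
})

test_that("loop contrast is null for identical seasonal longitudes and
          recovers a planted shift", {
  stops <- data.frame(
    bird_id = rep(sprintf("b%d", 1:6), each = 4),
    season = rep(c("spring", "spring", "autumn", "autumn"), 6),
    lon = rep(c(10, 14, 10, 14), 6))
  null_res <- loop_contrast(stops, n_permutations = 500, seed = 1)
  expect_equal(null_res$mean_delta_lon, 0)
  expect_gt(null_res$p_value, 0.5)
  set.seed(8)
  stops$lon <- stops$lon + rnorm(nrow(stops), 0, 1.5) +
    ifelse(stops$season == "autumn", 7.8, 0)
  shifted <- loop_contrast(stops, n_permutations = 500, seed = 1)
  se <- stats::sd(shifted$per_bird$delta_lon) / sqrt(shifted$n_birds)
  expect_lt(abs(shifted$mean_delta_lon - 7.8), 2.5 * se + 1e-9)
  expect_lt(shifted$p_value, 0.05)
})

test_that("birds lacking a season are excluded with a message", {
  stops <- data.frame(bird_id = c("a", "a", "b"),
                      season = c("spring", "autumn", "spring"),
                      lon = c(1, 2, 3))
  expect_message(res <- loop_contrast(stops, n_permutations = 50, seed = 1),
                 "excluding")
  expect_identical(res$excluded, "b")
  expect_identical(res$n_birds, 1L)
})

test_that("stationary hours per day reproduce the printed partitioning", {
  # leg distances at the two populations' spring means, 3.1-day legs,
  # 43 km/h flying
  expect_equal(round(stationary_hours_per_day(2008, 3.1), 1), 8.9)
  expect_equal(round(stationary_hours_per_day(2411, 3.1), 1), 5.9)
  # a leg flown non-stop leaves no stationary time
  expect_equal(stationary_hours_per_day(43 * 24 * 2, 2), 0)
  expect_warning(stationary_hours_per_day(5000, 1), "clipping")
})

test_that("leg speed identities match the printed values", {
  expect_equal(round(leg_speed(2043, 3.1), 1), 27.5)
  expect_equal(round(leg_speed(5054, 7), 1), 30.1)
  expect_equal(leg_speed(0, 3), 0)
})

test_that("fuel arithmetic follows the 25 g per 5000 km rule", {
  expect_equal(fuel_requirement(5000), 25)
  expect_equal(fuel_requirement(2500), 12.5)
  full <- fuel_budget(5000, 7, departure_load = 25)
  expect_equal(full$extra_mass_g, 0)
  b <- fuel_budget(5054, 7, extra_mass = 12, lean_mass = 13)
  expect_equal(round(b$daily_gain_g, 1), 1.7)
  expect_equal(round(b$deposition_rate, 2), 0.13)
})

test_that("resighting pooling reproduces the printed 27.8%", {
  tagged <- pool_resighting(c(10, 39, 10, 19), c(36, 130, 49, 66),
                            rep("tagged", 4))
  expect_equal(round(tagged$pooled$percent, 1), 27.8)
  one <- pool_resighting(5, 10, "x")
  expect_equal(one$pooled$percent, 50)
  both <- pool_resighting(c(5, 5), c(10, 10), c("a", "b"))
  expect_equal(both$difference_pct, 0)
})
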