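test_that("solar position matches geometry at landmark instants", {
  # equator, longitude 0, near solar noon at the March equinox: sun near zenith
  eq <- solar_position(0, 0, as.POSIXct("2020-03-20 12:07:00", tz = "UTC"))
  expect_gt(eq$altitude, 89)

  # 72 N at winter-solstice noon: polar night, sun below the horizon
  polar <- solar_position(72, 0, as.POSIXct("2020-12-21 12:00:00", tz = "UTC"))
  expect_lt(polar$altitude, 0)
  expect_equal(polar$altitude, 90 - 72 - 23.44, tolerance = 0.5)

  expect_error(solar_position(0, 0, as.POSIXct("2020-03-20 12:00:00", tz = "")),
               "UTC")
  expect_error(solar_position(0, 0, "2020-03-20"), "POSIXct")
})

test_that("solar position agrees with an independent ephemeris on random cases", {
  set.seed(10)
  n <- 100
  lat <- runif(n, -70, 70)
  lon <- runif(n, -180, 180)
  t0 <- as.POSIXct("2000-01-01", tz = "UTC")
  times <- t0 + runif(n, 0, 30 * 365.25 * 86400)
  pos <- solar_position(lat, lon, times)
  ora <- michalsky_solar(lat, lon, times)
  sep <- angular_separation(pos$altitude, pos$azimuth, ora$altitude, ora$azimuth)
  expect_lt(max(sep), 0.5)
})

test_that("clearness index handles limits and the night convention", {
  expect_equal(clearness_index(2, 2), 1)
  expect_equal(clearness_index(0, 3), 0)
  expect_equal(clearness_index(0.01, 0), 0) # sun below horizon
  expect_equal(clearness_index(5, 2), 1)    # clipped
  expect_error(clearness_index(-1, 2), "non-negative")
})

test_that("diffuse fraction follows the published piecewise model", {
  expect_equal(diffuse_fraction(0), 1)            # overcast limit
  expect_equal(diffuse_fraction(0.2), 1 - 0.249 * 0.2)
  expect_equal(diffuse_fraction(0.5), 1.557 - 1.84 * 0.5)
  expect_equal(diffuse_fraction(0.9), 0.177)
  # near-continuity at the published piece boundaries
  expect_equal(diffuse_fraction(0.35 - 1e-9), diffuse_fraction(0.35), tolerance = 1e-3)
  expect_equal(diffuse_fraction(0.75 - 1e-9), diffuse_fraction(0.75), tolerance = 1e-3)
  # monotone non-increasing within each polynomial piece, bounded overall
  for (piece in list(c(0, 0.3499), c(0.35, 0.7499), c(0.75, 1))) {
    kt <- seq(piece[1], piece[2], length.out = 500)
    expect_true(all(diff(diffuse_fraction(kt)) <= 1e-12))
  }
  kd <- diffuse_fraction(seq(0, 1, by = 1e-3))
  expect_true(all(kd >= 0 & kd <= 1))
  expect_error(diffuse_fraction(1.2), "\\[0, 1\\]")
})

test_that("net partition conserves energy exactly", {
  p <- partition_net(2.0, 0.25)
  expect_equal(p$direct, 1.5)
  expect_equal(p$diffuse, 0.5)
  expect_equal(partition_net(3, 1)$direct, 0)
  set.seed(11)
  net <- runif(200, 0, 4); kd <- runif(200)
  p <- partition_net(net, kd)
  expect_lt(max(abs(p$direct + p$diffuse - net)), 1e-12)
  expect_error(partition_net(-1, 0.5), ">= 0")
})

test_that("horizon angles and sky view factor behave on canonical terrain", {
  flat <- slope_aspect(fc_grid(matrix(100, 21, 21), 10))
  f <- horizon_svf(flat, n_sectors = 8, max_search = 100)
  expect_lt(max(abs(f$horizon)), 1e-10)
  expect_equal(as.vector(f$svf$values), rep(1, 441), tolerance = 1e-12)
  expect_error(horizon_svf(flat, n_sectors = 3), "n_sectors")

  # symmetric pit with 45 degree walls: cone z = distance from center
  n <- 21; cs <- 10
  center <- (n + 1) / 2
  cone <- outer(seq_len(n), seq_len(n), function(i, j) {
    cs * sqrt((i - center)^2 + (j - center)^2)
  })
  pit <- slope_aspect(fc_grid(cone, cs))
  fp <- horizon_svf(pit, n_sectors = 8, max_search = 80)
  centre_idx <- (center - 1) * n + center # column-major linear index
  expect_equal(unname(fp$horizon[centre_idx, ]), rep(45, 8), tolerance = 2)
})

test_that("the sky view factor closed form gives cos^2(slope/2) when unobstructed", {
  # 45 degree uniform slope with zero horizon screening
  flat <- slope_aspect(fc_grid(matrix(0, 5, 5), 1))
  flat$slope$values[] <- 45
  f <- horizon_svf(flat, n_sectors = 8, max_search = 2)
  expect_equal(as.vector(f$svf$values), rep(cos(pi / 8)^2, 25), tolerance = 1e-10)
  expect_equal(cos(pi / 8)^2, 0.8535534, tolerance = 1e-6)
})

test_that("absorbed radiation reduces to net for a flat unshaded zenith case", {
  # sun at zenith, flat cell, svf 1, no adjacent albedo
  abs1 <- absorbed_hourly(
    direct = 1.5, diffuse = 0.5, extraterrestrial = 4,
    sun_altitude = 90, sun_azimuth = 0, slope = 0, aspect = 180,
    svf = 1, shaded = FALSE, albedo_adjacent = 0
  )
  expect_equal(abs1, 2.0, tolerance = 1e-12)

  # sun below horizon: no direct contribution
  abs2 <- absorbed_hourly(1.5, 0.5, 0, -5, 120, 0, 180, 1, FALSE, 0)
  expect_equal(abs2, 0.5)

  # slope 60 facing the sun at altitude 30: beam amplified to 2x direct
  abs3 <- absorbed_hourly(1.0, 0, 4, 30, 90, 60, 90, 1, FALSE, 0)
  expect_equal(abs3, 2.0, tolerance = 1e-12)

  # shading kills the beam
  abs4 <- absorbed_hourly(1.0, 0, 4, 30, 90, 60, 90, 1, TRUE, 0)
  expect_equal(abs4, 0)
})

test_that("absorbed radiation never exceeds the geometric energy bound", {
  set.seed(12)
  for (k in 1:200) {
    net <- runif(1, 0, 4)
    kd <- runif(1)
    p <- partition_net(net, kd)
    alt <- runif(1, 1, 90)
    a <- absorbed_hourly(p$direct, p$diffuse, 4.5, alt, runif(1, 0, 360),
                         runif(1, 0, 70), runif(1, 0, 360), runif(1, 0.3, 1),
                         FALSE, runif(1, 0, 0.5))
    bound <- p$direct / max(1e-3, sin(alt * pi / 180)) + net
    expect_lte(a, bound + 1e-9)
    expect_gte(a, 0)
  }
})

test_that("daily cumulative radiation validates its input and sums exactly", {
  expect_equal(daily_cumulative(rep(0, 24)), 0)
  expect_equal(daily_cumulative(rep(0.5, 24)), 12)
  set.seed(13)
  x <- runif(24)
  expect_equal(daily_cumulative(x), sum(x))
  expect_error(daily_cumulative(runif(23)), "24")
})

test_that("flat unshaded worlds absorb exactly the net input over the day", {
  flat <- slope_aspect(fc_grid(matrix(0, 5, 5), 30))
  f <- horizon_svf(flat, n_sectors = 8, max_search = 60)
  set.seed(14)
  hours <- 0:23
  daylight <- hours >= 6 & hours <= 18
  downward <- ifelse(daylight, runif(24, 0.5, 3), 0)
  net <- downward * 0.85
  out <- radiation_monthly(flat, f, lat = 46, lon = 0, month = 6,
                           downward = downward, net = net, albedo_adjacent = 0.2)
  # svf = 1 and slope = 0: absorbed equals net hour by hour, so the daily
  # cumulative equals the summed net series
  expect_equal(as.vector(out$values), rep(sum(net), 25), tolerance = 1e-9)
})
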