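# Independent oracles used across test files. These stay deliberately
# independent of the package implementation paths they check.

# Michalsky (1988) / Astronomical Almanac low-precision solar ephemeris:
# mean anomaly and mean longitude polynomials in days since J2000, ecliptic
# longitude, right ascension/declination, and the hour angle via sidereal
# time. Independent of the geometric-mean-longitude/equation-of-time
# formulation used by the package; documented accuracy ~0.01 degrees.
michalsky_solar <- function(lat, lon, datetime) {
  jd <- as.numeric(datetime) / 86400 + 2440587.5
  d <- jd - 2451545
  g <- (357.528 + 0.9856003 * d) %% 360 * pi / 180
  q <- (280.460 + 0.9856474 * d) %% 360
  L <- (q + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360 * pi / 180
  ep <- (23.439 - 4e-7 * d) * pi / 180
  ra <- atan2(cos(ep) * sin(L), cos(L)) %% (2 * pi)
  decl <- asin(sin(ep) * sin(L))
  hours_ut <- ((jd + 0.5) %% 1) * 24
  gmst <- (6.697375 + 0.0657098242 * (jd - 2451545 - hours_ut / 24) +
             1.00273790935 * hours_ut) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  ha <- (ha + pi) %% (2 * pi) - pi
  latr <- lat * pi / 180
  sin_alt <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  alt <- asin(pmin(1, pmax(-1, sin_alt)))
  cos_az <- (sin(decl) - sin(latr) * sin_alt) / (cos(latr) * cos(alt))
  az0 <- acos(pmin(1, pmax(-1, cos_az))) * 180 / pi
  az <- ifelse(ha > 0, 360 - az0, az0) %% 360
  list(altitude = alt * 180 / pi, azimuth = az)
}

# great-circle separation (degrees) between two (altitude, azimuth) positions
angular_separation <- function(alt1, az1, alt2, az2) {
  a1 <- alt1 * pi / 180; a2 <- alt2 * pi / 180
  z1 <- az1 * pi / 180; z2 <- az2 * pi / 180
  cosd <- sin(a1) * sin(a2) + cos(a1) * cos(a2) * cos(z1 - z2)
  acos(pmin(1, pmax(-1, cosd))) * 180 / pi
}

# brute-force Dijkstra over the 8-connected lattice (distance-from-sources)
dijkstra_grid_distance <- function(mask, cell_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  dist[mask] <- 0
  visited <- matrix(FALSE, nr, nc)
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    un <- which(!visited & is.finite(dist))
    if (length(un) == 0) break
    u <- un[which.min(dist[un])]
    visited[u] <- TRUE
    ui <- (u - 1) %% nr + 1
    uj <- (u - 1) %/% nr + 1
    for (k in seq_len(nrow(moves))) {
      vi <- ui + moves$dr[k]; vj <- uj + moves$dc[k]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      step <- cell_size * sqrt(moves$dr[k]^2 + moves$dc[k]^2)
      if (dist[ui, uj] + step < dist[vi, vj]) dist[vi, vj] <- dist[ui, uj] + step
    }
  }
  dist
}

# hourly sinusoidal day of temperatures around a mean, amplitude A
sinusoid_day <- function(date, mean_t, amplitude, n = 24) {
  hours <- seq(0, 24 - 24 / n, length.out = n)
  tibble::tibble(
    timestamp = as.POSIXct(date, tz = "UTC") + hours * 3600,
    temperature = mean_t + amplitude * sin(2 * pi * (hours - 9) / 24)
  )
}
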