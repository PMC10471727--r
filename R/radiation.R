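#' Solar position (altitude and azimuth)
#'
#' Low-precision astronomical ephemeris after the NOAA/Meeus formulation:
#' geometric mean longitude and anomaly, equation of center, obliquity of
#' the ecliptic, declination and equation of time, then the hour angle for
#' the requested instant. Accuracy is a few hundredths of a degree over
#' 1950--2050, well inside the 0.5 degree tolerance this pipeline needs.
#' Atmospheric refraction is not applied.
#'
#' @param lat,lon Latitude and longitude, decimal degrees (EPSG:4326).
#' @param datetime `POSIXct` in UTC (timezone attribute must be set to
#'   `"UTC"` or `"GMT"`; a naive timestamp is an error).
#' @return Tibble with `altitude`, `azimuth` (degrees, azimuth clockwise
#'   from north), `declination`, `eq_time_min`, `hour_angle`.
#' @export
solar_position <- function(lat, lon, datetime) {
  if (!inherits(datetime, "POSIXct")) {
    stop("datetime must be POSIXct in UTC", call. = FALSE)
  }
  tz <- attr(datetime, "tzone")
  if (is.null(tz) || !nzchar(tz) || !(tz %in% c("UTC", "GMT"))) {
    stop("datetime must be timezone-aware UTC (tz = \"UTC\")", call. = FALSE)
  }
  n <- max(length(lat), length(lon), length(datetime))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  datetime <- rep(datetime, length.out = n)

  # Julian day from Unix epoch; T in Julian centuries from J2000.0
  jd <- as.numeric(datetime) / 86400 + 2440587.5
  tc <- (jd - 2451545) / 36525

  l0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  m <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  mr <- m * pi / 180
  ec <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)
  ceq <- sin(mr) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(2 * mr) * (0.019993 - 0.000101 * tc) + sin(3 * mr) * 0.000289
  true_long <- l0 + ceq
  omega <- 125.04 - 1934.136 * tc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * pi / 180)
  e0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- e0 + 0.00256 * cos(omega * pi / 180)
  epsr <- eps * pi / 180

  decl <- asin(sin(epsr) * sin(app_long * pi / 180))

  y <- tan(epsr / 2)^2
  l0r <- l0 * pi / 180
  eqtime <- 4 * (180 / pi) * (
    y * sin(2 * l0r) - 2 * ec * sin(mr) + 4 * ec * y * sin(mr) * cos(2 * l0r) -
      0.5 * y^2 * sin(4 * l0r) - 1.25 * ec^2 * sin(2 * mr)
  )

  frac_day <- (jd + 0.5) %% 1              # fraction of UTC day from midnight
  tst <- (frac_day * 1440 + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180                       # degrees, solar noon = 0
  har <- ha * pi / 180
  latr <- lat * pi / 180

  sin_alt <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(har)
  sin_alt <- pmin(1, pmax(-1, sin_alt))
  alt <- asin(sin_alt)
  cos_az <- (sin(decl) - sin(latr) * sin_alt) / (cos(latr) * cos(alt))
  cos_az[!is.finite(cos_az)] <- 1
  az0 <- acos(pmin(1, pmax(-1, cos_az))) * 180 / pi
  # hour angle > 0 is afternoon: sun in the western half (azimuth > 180)
  az <- ifelse(ha > 0, 360 - az0, az0) %% 360

  tibble::tibble(
    altitude = alt * 180 / pi,
    azimuth = az,
    declination = decl * 180 / pi,
    eq_time_min = eqtime,
    hour_angle = ha
  )
}

#' Hourly clearness index
#'
#' `Kt = downward / extraterrestrial`, clipped to `[0, 1]`; defined as 0
#' whenever extraterrestrial irradiance is 0 (sun below the horizon), which
#' avoids 0/0 at night.
#'
#' @param downward Downward total shortwave on a horizontal plane,
#'   MJ m-2 h-1.
#' @param extraterrestrial Extraterrestrial irradiance on a horizontal
#'   plane, MJ m-2 h-1.
#' @return Numeric vector of Kt in `[0, 1]`.
#' @export
clearness_index <- function(downward, extraterrestrial) {
  if (any(downward < 0, na.rm = TRUE) || any(extraterrestrial < 0, na.rm = TRUE)) {
    stop("radiation inputs must be non-negative", call. = FALSE)
  }
  kt <- ifelse(extraterrestrial <= 0, 0, downward / extraterrestrial)
  pmin(1, pmax(0, kt))
}

# piecewise clearness-index separation coefficients (Orgill & Hollands 1977):
# each row is one Kt piece, Kd = a + b * Kt on [lo, hi)
kd_separation_pieces <- function() {
  tibble::tibble(
    lo = c(0, 0.35, 0.75),
    hi = c(0.35, 0.75, 1.0000001),
    a = c(1.0, 1.557, 0.177),
    b = c(-0.249, -1.84, 0.0)
  )
}

#' Diffuse fraction from the clearness index
#'
#' Piecewise-polynomial separation of global shortwave into its diffuse
#' share as a function of the hourly clearness index (Orgill--Hollands
#' form): `Kd = 1 - 0.249 Kt` below `Kt = 0.35`, `1.557 - 1.84 Kt` up to
#' `0.75`, and the clear-sky floor `0.177` above. Fully overcast skies
#' (`Kt = 0`) give `Kd = 1`; the result is clipped to `[0, 1]`.
#'
#' @param kt Clearness index in `[0, 1]`.
#' @return Diffuse fraction `Kd` in `[0, 1]`.
#' @export
diffuse_fraction <- function(kt) {
  if (any(kt < 0 | kt > 1, na.rm = TRUE)) {
    stop("Kt must lie in [0, 1]", call. = FALSE)
  }
  pieces <- kd_separation_pieces()
  kd <- rep(NA_real_, length(kt))
  for (i in seq_len(nrow(pieces))) {
    sel <- !is.na(kt) & kt >= pieces$lo[i] & kt < pieces$hi[i]
    kd[sel] <- pieces$a[i] + pieces$b[i] * kt[sel]
  }
  pmin(1, pmax(0, kd))
}

#' Partition net shortwave into direct and diffuse components
#'
#' `diffuse = net * Kd`, `direct = net * (1 - Kd)`; the sum is conserved
#' exactly.
#'
#' @param net Net (albedo-free) shortwave, MJ m-2 h-1, non-negative.
#' @param kd Diffuse fraction in `[0, 1]`.
#' @return Tibble with `direct` and `diffuse`.
#' @export
partition_net <- function(net, kd) {
  if (any(net < 0, na.rm = TRUE)) stop("net radiation must be >= 0", call. = FALSE)
  if (any(kd < 0 | kd > 1, na.rm = TRUE)) stop("Kd must lie in [0, 1]", call. = FALSE)
  tibble::tibble(direct = net * (1 - kd), diffuse = net * kd)
}

#' Horizon angles and sky view factor
#'
#' For every cell, ray-marches `n_sectors` azimuth directions in steps of
#' one cell size out to `max_search`, recording the maximum elevation angle
#' of the surrounding terrain (the horizon) per sector. The sky view factor
#' combines slope self-obstruction with the horizon screening:
#' `svf = cos^2(slope / 2) * mean_sectors(cos^2(horizon))`, in `[0, 1]`.
#'
#' @param terrain An `fc_terrain` from [slope_aspect()].
#' @param n_sectors Number of azimuth sectors (>= 4), default 24.
#' @param max_search Maximum horizon search radius in meters, default 5000.
#' @return List with `horizon` (matrix cells x sectors, degrees),
#'   `sector_azimuth` (sector centers, degrees), and `svf` grid.
#' @export
horizon_svf <- function(terrain, n_sectors = 24, max_search = 5000) {
  stopifnot(inherits(terrain, "fc_terrain"))
  if (n_sectors < 4) stop("n_sectors must be at least 4", call. = FALSE)
  z <- terrain$elevation$values
  cs <- terrain$elevation$cell_size
  nr <- nrow(z); nc <- ncol(z)
  co <- grid_coordinates(terrain$elevation)
  az <- (seq_len(n_sectors) - 1) * 360 / n_sectors
  steps <- seq(cs, max_search, by = cs)
  horizon <- matrix(0, nrow(co), n_sectors)
  for (s in seq_len(n_sectors)) {
    a <- az[s] * pi / 180
    dx <- sin(a); dy <- cos(a)
    hmax <- rep(0, nrow(co))
    for (d in steps) {
      xs <- co$x + d * dx
      ys <- co$y + d * dy
      zs <- bilinear_elevation(terrain$elevation, xs, ys)
      ang <- atan((zs - co$value) / d)
      hmax <- pmax(hmax, ifelse(is.na(ang), -Inf, ang))
    }
    hmax[!is.finite(hmax)] <- 0
    horizon[, s] <- pmax(0, hmax) * 180 / pi
  }
  slope <- as.vector(terrain$slope$values)
  svf <- cos(slope * pi / 360)^2 *
    rowMeans(cos(horizon * pi / 180)^2)
  out <- terrain$elevation
  out$values <- matrix(svf, nr, nc)
  list(horizon = horizon, sector_azimuth = az, svf = out)
}

# bilinear interpolation of grid values at arbitrary points; NA outside
bilinear_elevation <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  # continuous cell-center coordinates
  cx <- (x - grid$xll) / cs + 0.5
  cy <- (y - grid$yll) / cs + 0.5
  col0 <- floor(cx); row_from_s <- floor(cy)
  fx <- cx - col0; fy <- cy - row_from_s
  ok <- col0 >= 1 & col0 + 1 <= nc & row_from_s >= 1 & row_from_s + 1 <= nr
  val <- rep(NA_real_, length(x))
  if (any(ok)) {
    r1 <- nr - row_from_s[ok] + 1        # southern row (row index from north)
    r0 <- r1 - 1                          # northern row
    c0 <- col0[ok]; c1 <- c0 + 1
    v00 <- grid$values[cbind(r1, c0)]     # SW
    v10 <- grid$values[cbind(r1, c1)]     # SE
    v01 <- grid$values[cbind(r0, c0)]     # NW
    v11 <- grid$values[cbind(r0, c1)]     # NE
    fxo <- fx[ok]; fyo <- fy[ok]
    val[ok] <- v00 * (1 - fxo) * (1 - fyo) + v10 * fxo * (1 - fyo) +
      v01 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  val
}

#' Is the sun behind the local horizon?
#'
#' @param horizon Matrix of per-sector horizon angles (cells x sectors).
#' @param sector_azimuth Sector center azimuths, degrees.
#' @param sun_altitude,sun_azimuth Solar position, degrees.
#' @return Logical vector per cell.
#' @export
is_shaded <- function(horizon, sector_azimuth, sun_altitude, sun_azimuth) {
  n_sectors <- length(sector_azimuth)
  width <- 360 / n_sectors
  sector <- (floor(((sun_azimuth + width / 2) %% 360) / width)) + 1
  sun_altitude < horizon[, sector]
}

#' Absorbed shortwave on a tilted surface for one hour
#'
#' Direct beam is routed through the incidence angle on the tilted surface,
#' `direct * max(0, cos(incidence)) / max(eps, sin(altitude))`, zeroed when
#' the cell is shaded or the sun is down. Diffuse is split into an isotropic
#' part weighted by the sky view factor, a circumsolar part weighted by a
#' Hay-type anisotropy index (`direct / extraterrestrial`) and routed like
#' the beam, and a terrain-reflected part
#' `albedo_adjacent * (1 - svf) * global`.
#'
#' @param direct,diffuse Direct and diffuse net shortwave, MJ m-2 h-1.
#' @param extraterrestrial Extraterrestrial horizontal irradiance,
#'   MJ m-2 h-1 (0 at night).
#' @param sun_altitude,sun_azimuth Solar position, degrees.
#' @param slope,aspect Surface slope and aspect, degrees.
#' @param svf Sky view factor in `[0, 1]`.
#' @param shaded Logical: cell behind the local horizon this hour.
#' @param albedo_adjacent Albedo of the adjacent terrain, `[0, 1]`.
#' @param eps Guard for the `1 / sin(altitude)` amplification (default 1e-3).
#' @return Absorbed shortwave, MJ m-2 h-1 (non-negative).
#' @export
absorbed_hourly <- function(direct, diffuse, extraterrestrial,
                            sun_altitude, sun_azimuth,
                            slope, aspect, svf, shaded = FALSE,
                            albedo_adjacent = 0, eps = 1e-3) {
  sr <- slope * pi / 180
  altr <- sun_altitude * pi / 180
  cos_inc <- cos(sr) * sin(altr) +
    sin(sr) * cos(altr) * cos((sun_azimuth - aspect) * pi / 180)
  beam_factor <- pmax(0, cos_inc) / pmax(eps, sin(altr))
  sun_up <- sun_altitude > 0 & !shaded
  beam_factor <- ifelse(sun_up, beam_factor, 0)

  anis <- ifelse(extraterrestrial > 0, pmin(1, direct / extraterrestrial), 0)
  global <- direct + diffuse
  dir_term <- direct * beam_factor
  diff_iso <- diffuse * (1 - anis) * svf
  diff_circ <- diffuse * anis * beam_factor
  refl <- albedo_adjacent * (1 - svf) * global
  out <- dir_term + diff_iso + diff_circ + refl
  if (any(out < -1e-12, na.rm = TRUE)) {
    warning("negative absorbed radiation clamped to 0")
  }
  pmax(0, out)
}

#' Daily cumulative shortwave from 24 hourly values
#'
#' @param hourly Numeric vector of exactly 24 hourly absorbed values,
#'   MJ m-2 h-1.
#' @return Daily cumulative radiation, MJ m-2 d-1.
#' @export
daily_cumulative <- function(hourly) {
  if (length(hourly) != 24) {
    stop("exactly 24 hourly values are required, got ", length(hourly), call. = FALSE)
  }
  sum(hourly)
}

#' Extraterrestrial irradiance on a horizontal plane
#'
#' Solar-constant irradiance projected on the horizontal, with the usual
#' eccentricity correction; 0 when the sun is below the horizon.
#'
#' @param sun_altitude Solar altitude, degrees.
#' @param doy Day of year (1--366).
#' @return MJ m-2 h-1.
#' @export
extraterrestrial_hourly <- function(sun_altitude, doy) {
  gsc <- 1.367e-3 * 3600 # solar constant, MJ m-2 h-1
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  pmax(0, gsc * e0 * sin(pmax(0, sun_altitude) * pi / 180))
}

#' Monthly-averaged daily cumulative absorbed shortwave for a grid
#'
#' Evaluates the full hourly chain for the 15th day of `month`: solar
#' position at each of the 24 local solar hours (00:00--23:00, offset from
#' UTC by longitude at 15 degrees/hour), clearness index from the hourly
#' downward series, diffuse fraction, net partition, topographic routing,
#' and the daily sum.
#'
#' @param terrain `fc_terrain` from [slope_aspect()].
#' @param factors Output of [horizon_svf()].
#' @param lat,lon Representative latitude/longitude of the grid, degrees.
#' @param month Month number 1--12.
#' @param year Calendar year used for the ephemeris (default 2018).
#' @param downward,net Hourly downward and net shortwave series, length 24,
#'   MJ m-2 h-1 (UTC-indexed like the evaluation hours).
#' @param albedo_adjacent Adjacent-terrain albedo, scalar or length 24.
#' @return [fc_grid()] of daily cumulative absorbed shortwave, MJ m-2 d-1.
#' @export
radiation_monthly <- function(terrain, factors, lat, lon, month, year = 2018,
                              downward, net, albedo_adjacent = 0.2) {
  stopifnot(length(downward) == 24, length(net) == 24)
  albedo_adjacent <- rep_len(albedo_adjacent, 24)
  slope <- as.vector(terrain$slope$values)
  aspect <- as.vector(terrain$aspect$values)
  svf <- as.vector(factors$svf$values)
  total <- numeric(length(slope))
  doy <- as.integer(strftime(as.Date(sprintf("%d-%02d-15", year, month)), "%j"))
  for (h in 0:23) {
    # local solar hour h -> UTC instant via the 15 degrees/hour offset
    utc <- as.POSIXct(sprintf("%d-%02d-15 00:00:00", year, month), tz = "UTC") +
      h * 3600 - lon / 15 * 3600
    pos <- solar_position(lat, lon, utc)
    exth <- extraterrestrial_hourly(pos$altitude, doy)
    kt <- clearness_index(downward[h + 1], max(exth, 0))
    kt <- if (pos$altitude <= 0) 0 else kt
    kd <- if (pos$altitude <= 0) 1 else diffuse_fraction(kt)
    parts <- partition_net(net[h + 1], kd)
    shaded <- is_shaded(factors$horizon, factors$sector_azimuth,
                        pos$altitude, pos$azimuth)
    total <- total + absorbed_hourly(
      parts$direct, parts$diffuse, exth,
      pos$altitude, pos$azimuth, slope, aspect, svf, shaded,
      albedo_adjacent[h + 1]
    )
  }
  out <- terrain$elevation
  out$values <- matrix(total, nrow(out$values), ncol(out$values))
  out
}
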