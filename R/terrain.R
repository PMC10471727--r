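#' Slope and aspect from a DEM (Horn 3x3)
#'
#' Computes slope (degrees) and aspect (degrees clockwise from north, of the
#' downslope direction) with Horn's third-order finite differences on the
#' 3x3 neighbourhood. Border cells fall back to one-sided differences via
#' edge replication. Flat cells (zero gradient) are assigned slope 0 and the
#' sentinel aspect 180: at zero slope any aspect gives zero surface tilt, so
#' the choice has no downstream effect.
#'
#' @param elevation An [fc_grid()] of elevations in meters, projected CRS.
#' @return List with `slope` and `aspect` grids (degrees) plus the input
#'   `elevation`, classed `fc_terrain`.
#' @export
slope_aspect <- function(elevation) {
  stopifnot(inherits(elevation, "fc_grid"))
  z <- elevation$values
  if (nrow(z) < 3 || ncol(z) < 3) {
    stop("DEM must be at least 3x3", call. = FALSE)
  }
  bad <- !is.finite(z)
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf(
      "DEM has %d non-finite cells (first at linear index %d)",
      sum(bad), idx
    ), call. = FALSE)
  }
  cs <- elevation$cell_size
  nr <- nrow(z)
  nc <- ncol(z)

  # pad edges by linear extrapolation so Horn's window degrades to exact
  # one-sided differences at the border
  zp <- rbind(2 * z[1, , drop = FALSE] - z[2, , drop = FALSE], z,
              2 * z[nr, , drop = FALSE] - z[nr - 1, , drop = FALSE])
  zp <- cbind(2 * zp[, 1, drop = FALSE] - zp[, 2, drop = FALSE], zp,
              2 * zp[, nc, drop = FALSE] - zp[, nc - 1, drop = FALSE])
  sh <- function(dr, dc) zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # row index grows southward, column index grows eastward
  nwz <- sh(-1, -1); nz <- sh(-1, 0); nez <- sh(-1, 1)
  wz  <- sh(0, -1);                   ez  <- sh(0, 1)
  swz <- sh(1, -1);  sz <- sh(1, 0);  sez <- sh(1, 1)

  dzdx <- ((nez + 2 * ez + sez) - (nwz + 2 * wz + swz)) / (8 * cs)
  dzdy <- ((nwz + 2 * nz + nez) - (swz + 2 * sz + sez)) / (8 * cs) # northward

  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # azimuth of the downslope direction, clockwise from north
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[dzdx == 0 & dzdy == 0] <- 180

  g <- function(m) fc_grid(m, cs, elevation$xll, elevation$yll, elevation$crs)
  structure(
    list(elevation = elevation, slope = g(slope), aspect = g(aspect)),
    class = "fc_terrain"
  )
}

#' Monthly mean temperature as the min/max midpoint
#'
#' @param tmin,tmax Matching [fc_grid()]s (or plain matrices) of monthly
#'   minimum and maximum temperature, degrees C.
#' @return Grid (or matrix, matching the input) of `(tmin + tmax) / 2`.
#' @export
monthly_mean_from_minmax <- function(tmin, tmax) {
  if (inherits(tmin, "fc_grid") && inherits(tmax, "fc_grid")) {
    if (!identical(dim(tmin$values), dim(tmax$values)) ||
        tmin$cell_size != tmax$cell_size ||
        tmin$xll != tmax$xll || tmin$yll != tmax$yll) {
      stop("tmin and tmax grids do not share shape and georeference", call. = FALSE)
    }
    out <- tmin
    out$values <- (tmin$values + tmax$values) / 2
    return(out)
  }
  if (!identical(dim(tmin), dim(tmax))) {
    stop("tmin and tmax do not share shape", call. = FALSE)
  }
  (tmin + tmax) / 2
}

#' Lapse-rate downscaling of coarse temperature to a fine DEM
#'
#' Each fine cell inherits the temperature of the coarse cell containing its
#' center, corrected by `lapse_rate * (z_fine - z_ref)` where `z_ref` is the
#' coarse cell's reference elevation. With `z_ref` equal to the mean fine
#' elevation of the coarse cell (the default via [aggregate_elevation()]),
#' downscaling is mean-preserving over every coarse cell.
#'
#' @param coarse_mean [fc_grid()] of coarse monthly mean temperature, deg C.
#' @param coarse_ref_elev [fc_grid()] of coarse reference elevations, m,
#'   on the same layout as `coarse_mean`.
#' @param fine_elev [fc_grid()] fine DEM nested inside the coarse extent.
#' @param lapse_rate Environmental lapse rate in deg C per meter; must be
#'   negative. Default -0.0065; -0.005 and -0.008 are the usual sensitivity
#'   alternates.
#' @return [fc_grid()] of fine-scale temperature.
#' @export
downscale_temperature <- function(coarse_mean, coarse_ref_elev, fine_elev,
                                  lapse_rate = -0.0065) {
  stopifnot(inherits(coarse_mean, "fc_grid"), inherits(fine_elev, "fc_grid"))
  if (!is.numeric(lapse_rate) || lapse_rate >= 0) {
    stop("lapse_rate must be negative (deg C per meter)", call. = FALSE)
  }
  if (!identical(dim(coarse_mean$values), dim(coarse_ref_elev$values))) {
    stop("coarse_mean and coarse_ref_elev do not share shape", call. = FALSE)
  }
  fc <- grid_coordinates(fine_elev)
  idx <- locate_cells(coarse_mean, fc$x, fc$y)
  if (anyNA(idx$row)) {
    stop(sprintf(
      "%d fine cells fall outside the coarse extent", sum(is.na(idx$row))
    ), call. = FALSE)
  }
  tc <- coarse_mean$values[cbind(idx$row, idx$col)]
  zr <- coarse_ref_elev$values[cbind(idx$row, idx$col)]
  out <- fine_elev
  out$values <- matrix(
    tc + lapse_rate * (fc$value - zr),
    nrow(fine_elev$values), ncol(fine_elev$values)
  )
  out
}

#' Aggregate a fine DEM to coarse-cell mean elevations
#'
#' @param fine_elev Fine [fc_grid()].
#' @param coarse_template Coarse [fc_grid()] supplying the target layout.
#' @return Coarse grid of mean fine elevations (NA where no fine cell falls).
#' @export
aggregate_elevation <- function(fine_elev, coarse_template) {
  fcoords <- grid_coordinates(fine_elev)
  idx <- locate_cells(coarse_template, fcoords$x, fcoords$y)
  keep <- !is.na(idx$row)
  key <- paste(idx$row[keep], idx$col[keep])
  means <- tapply(fcoords$value[keep], key, mean)
  out <- coarse_template
  out$values[] <- NA_real_
  rc <- do.call(rbind, strsplit(names(means), " "))
  out$values[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <- as.numeric(means)
  out
}

# row/col of the cell containing each point; NA outside the extent
locate_cells <- function(grid, x, y) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  cs <- grid$cell_size
  col <- floor((x - grid$xll) / cs) + 1
  row <- nr - floor((y - grid$yll) / cs)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Grid distance to the glacier outline
#'
#' Rasterizes the outline polygons onto the grid (cells whose centers fall
#' inside any polygon are glacier, distance 0) and accumulates 8-connected
#' chamfer path distance outward: cardinal steps cost one cell size, diagonal
#' steps `sqrt(2)` cell sizes. Cells farther than `max_distance` are masked
#' to `NA`.
#'
#' @param outlines A list of polygons; each polygon is a two-column matrix or
#'   data frame of `x`, `y` vertices (closed implicitly).
#' @param template [fc_grid()] defining extent and resolution (projected CRS).
#' @param max_distance Mask distance in meters (default `Inf`).
#' @return [fc_grid()] of distances in meters.
#' @export
distance_to_glacier <- function(outlines, template, max_distance = Inf) {
  if (length(outlines) == 0) {
    stop("empty outline set: at least one glacier polygon is required", call. = FALSE)
  }
  mask <- rasterize_polygons(outlines, template)
  d <- chamfer_distance(mask, template$cell_size)
  d[d > max_distance] <- NA_real_
  out <- template
  out$values <- d
  out
}

#' Rasterize polygons by cell-center inclusion
#'
#' @inheritParams distance_to_glacier
#' @return Logical matrix: `TRUE` where the cell center is inside a polygon.
#' @export
rasterize_polygons <- function(outlines, template) {
  co <- grid_coordinates(template)
  inside <- rep(FALSE, nrow(co))
  for (p in outlines) {
    p <- as.matrix(as.data.frame(p)[, 1:2])
    inside <- inside | point_in_polygon(co$x, co$y, p[, 1], p[, 2])
  }
  matrix(inside, nrow(template$values), ncol(template$values))
}

# even-odd ray crossing test, vectorized over points
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# 8-connected chamfer distance from a logical source mask, by repeated
# forward/backward raster sweeps until convergence (exact on an open grid)
chamfer_distance <- function(mask, cell_size) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  a <- cell_size
  b <- cell_size * sqrt(2)
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        v <- d[i, j]
        if (i > 1) v <- min(v, d[i - 1, j] + a)
        if (j > 1) v <- min(v, d[i, j - 1] + a)
        if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + b)
        if (i > 1 && j < nc) v <- min(v, d[i - 1, j + 1] + b)
        if (v < d[i, j]) { d[i, j] <- v; changed <- TRUE }
      }
    }
    for (i in rev(seq_len(nr))) {
      for (j in rev(seq_len(nc))) {
        v <- d[i, j]
        if (i < nr) v <- min(v, d[i + 1, j] + a)
        if (j < nc) v <- min(v, d[i, j + 1] + a)
        if (i < nr && j < nc) v <- min(v, d[i + 1, j + 1] + b)
        if (i < nr && j > 1) v <- min(v, d[i + 1, j - 1] + b)
        if (v < d[i, j]) { d[i, j] <- v; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d
}
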