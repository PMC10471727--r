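#' Lightweight georeferenced grid
#'
#' A minimal raster container: a numeric matrix with cell size, lower-left
#' corner and CRS label attached. Row 1 is the northern edge (north-up) and
#' values are registered to cell centers. All metric operations (slope,
#' distance, horizon search) require a projected CRS with coordinates in
#' meters.
#'
#' @param values Numeric matrix (row 1 = northern edge).
#' @param cell_size Cell edge length in CRS units (meters for projected CRS).
#' @param xll,yll Coordinates of the lower-left *corner* of the grid.
#' @param crs Free-text CRS label (e.g. `"local-metric"`, `"ESRI:54009"`).
#' @return An `fc_grid` object.
#' @export
fc_grid <- function(values, cell_size, xll = 0, yll = 0, crs = "local-metric") {
  stopifnot(is.matrix(values), is.numeric(values), cell_size > 0)
  structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll, crs = crs),
    class = "fc_grid"
  )
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf(
    "<fc_grid> %d x %d cells, cell %g, origin (%g, %g), crs %s\n",
    nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll, x$crs
  ))
  cat(sprintf(
    "  range: [%g, %g]\n",
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE))
  ))
  invisible(x)
}

#' @export
dim.fc_grid <- function(x) dim(x$values)

#' Cell-center coordinates of a grid
#'
#' @param grid An [fc_grid()].
#' @return Tibble with `row`, `col`, `x`, `y`, `value` (row 1 = north).
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "fc_grid"))
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  cs <- grid$cell_size
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = grid$xll + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    # row 1 is the northern edge
    y = grid$yll + (nr - rep(seq_len(nr), times = nc) + 0.5) * cs,
    value = as.vector(grid$values)
  )
}

#' Convert a tibble of cell values back to a grid
#'
#' Inverse of [grid_coordinates()]: `df` must carry `row`, `col` and the
#' value column for every cell of the template.
#'
#' @param df Tibble with `row`, `col` and `value_col`.
#' @param template An [fc_grid()] supplying shape and georeference.
#' @param value_col Name of the column holding cell values.
#' @return An `fc_grid`.
#' @export
grid_from_table <- function(df, template, value_col = "value") {
  m <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  m[cbind(df$row, df$col)] <- df[[value_col]]
  fc_grid(m, template$cell_size, template$xll, template$yll, template$crs)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the northern edge southwards.
#'
#' @param path File path.
#' @param crs CRS label to attach on read (the format itself carries none).
#' @return [read_ascii_grid()] returns an `fc_grid`;
#'   [write_ascii_grid()] returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, crs = "local-metric") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  fc_grid(m, vals[["cellsize"]], vals[["xllcorner"]], vals[["yllcorner"]], crs)
}

#' @param grid An [fc_grid()] to write.
#' @param nodata Sentinel written for `NA` cells.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "fc_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
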