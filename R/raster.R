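# Minimal in-memory single-band raster. Values are stored as a matrix with
# rows = y (row 1 is the NORTH/top row, as in ESRI ASCII grids), columns = x.
# Coordinates are kilometres; `res` is the square pixel size in km.

#' Create a raster
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin lower-left corner of the raster extent (km).
#' @param res pixel size (km).
#' @return An object of class `fs_raster`.
#' @export
fs_raster <- function(values, xmin, ymin, res) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res),
            class = "fs_raster")
}

#' @export
print.fs_raster <- function(x, ...) {
  cat(sprintf("<fs_raster> %d x %d pixels, res %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin))
  invisible(x)
}

#' Pixel-centroid coordinates of a raster
#'
#' @param r an `fs_raster`.
#' @return List with vectors `x`, `y` aligned with `as.vector(r$values)`
#'   (column-major over the value matrix).
#' @keywords internal
raster_centroids <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cx <- r$xmin + (seq_len(nc) - 0.5) * r$res
  cy <- r$ymin + (nr - seq_len(nr) + 0.5) * r$res  # row 1 is the top row
  list(x = rep(cx, each = nr), y = rep(cy, times = nc))
}

#' Slope raster from an elevation raster
#'
#' Slope is computed from changes in elevation between adjacent pixels:
#' central finite differences in the interior, one-sided at the boundary,
#' reported in degrees. Elevation is metres, pixel size kilometres.
#'
#' @param elevation an `fs_raster` of elevation in metres.
#' @return An `fs_raster` of slope in degrees (NA where elevation is NA).
#' @export
slope_from_elevation <- function(elevation) {
  z <- elevation$values
  h <- elevation$res * 1000  # horizontal spacing in metres
  nr <- nrow(z); nc <- ncol(z)
  # d/dx along columns, span 2h in the interior, h at the boundary
  gx <- (z[, c(2:nc, nc)] - z[, c(1, 1:(nc - 1))])
  span_x <- matrix(rep(c(1, rep(2, max(nc - 2, 0)), 1), each = nr), nr, nc)
  gx <- gx / (span_x * h)
  gy <- (z[c(1, 1:(nr - 1)), ] - z[c(2:nr, nr), ])  # y increases northwards = decreasing row
  span_y <- matrix(rep(c(1, rep(2, max(nr - 2, 0)), 1), times = nc), nr, nc)
  gy <- gy / (span_y * h)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  fs_raster(slope, elevation$xmin, elevation$ymin, elevation$res)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster format readable by standard GIS software.
#'
#' @param r an `fs_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata value written for NA pixels.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$res),
    sprintf("NODATA_value %g", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return An `fs_raster`; NODATA pixels become NA.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == hdr[["nodata_value"]]] <- NA
  fs_raster(v, hdr[["xllcorner"]], hdr[["yllcorner"]], hdr[["cellsize"]])
}

# Smooth a matrix with a separable Gaussian kernel (truncated at 3 sigma),
# reflecting at the edges. sigma in pixels.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(x, h) c(x[h:1], x, x[length(x):(length(x) - h + 1)])
  conv1 <- function(x) {
    xp <- pad_reflect(x, half)
    stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}
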