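# Regular cell lattice over a land mask, the land-area filter, and the
# per-cell summaries (forest-cover overlay, raster averaging) that populate
# the cell table used by every downstream stage.

#' Build a regular grid over a land mask
#'
#' Lays a square lattice over the bounding box of `land`, computes for every
#' cell the fraction of its area covered by the land polygon, and flags cells
#' with at least half their area on land as retained. Cells covering less
#' land carry a low and biased forest-cover signal and are excluded from all
#' analyses. The grid origin is the land bounding box lower-left corner
#' snapped down to a multiple of the cell size, so reruns on the same mask
#' give an identical lattice.
#'
#' @param land two-column matrix: the land-mask polygon (km).
#' @param cell_size cell edge length in km (default 5).
#' @param min_land_fraction retention threshold on the land fraction
#'   (default 0.5; the closed bound: exactly half-land cells are kept).
#' @return A `data.frame` of class `fs_grid` with one row per lattice cell:
#'   `id`, `col`, `row`, `xmin`, `ymin`, `xmax`, `ymax`, `cx`, `cy`
#'   (centroid), `land_fraction`, `retained`. Attributes `cell_size` and
#'   `origin` record the lattice.
#' @export
build_grid <- function(land, cell_size = 5, min_land_fraction = 0.5) {
  stopifnot(cell_size > 0)
  if (polygon_area(land) == 0) stop("land mask has zero area: empty grid")
  x0 <- floor(min(land[, 1]) / cell_size) * cell_size
  y0 <- floor(min(land[, 2]) / cell_size) * cell_size
  ncx <- ceiling((max(land[, 1]) - x0) / cell_size)
  ncy <- ceiling((max(land[, 2]) - y0) / cell_size)
  cells <- expand.grid(col = seq_len(ncx), row = seq_len(ncy))
  cells$xmin <- x0 + (cells$col - 1) * cell_size
  cells$ymin <- y0 + (cells$row - 1) * cell_size
  cells$xmax <- cells$xmin + cell_size
  cells$ymax <- cells$ymin + cell_size
  cells$cx <- cells$xmin + cell_size / 2
  cells$cy <- cells$ymin + cell_size / 2
  area <- cell_size^2
  cells$land_fraction <- vapply(seq_len(nrow(cells)), function(i) {
    polygon_rect_area(land, cells$xmin[i], cells$ymin[i],
                      cells$xmax[i], cells$ymax[i]) / area
  }, numeric(1))
  cells$retained <- cells$land_fraction >= min_land_fraction
  cells <- cbind(id = seq_len(nrow(cells)), cells)
  if (!any(cells$retained)) stop("no cell reaches the land-fraction threshold")
  structure(cells, class = c("fs_grid", "data.frame"),
            cell_size = cell_size, origin = c(x0, y0))
}

#' Retained cells of a grid
#' @param grid an `fs_grid`.
#' @return The rows of `grid` with `retained == TRUE`.
#' @export
retained_cells <- function(grid) grid[grid$retained, , drop = FALSE]

#' Per-cell natural forest cover from forest maps
#'
#' NFC of a cell is the fraction of the cell area covered by natural forest.
#' With polygon input the intersection areas are computed exactly by polygon
#' clipping; with a binary forest raster the fraction is the forest pixel
#' area assigned to the cell by the half-open pixel-centroid rule (exact up
#' to one pixel-area quantum when pixels nest in cells).
#'
#' @param grid an `fs_grid`.
#' @param forest either a list of polygon vertex matrices (assumed disjoint)
#'   or an `fs_raster` whose values are 1 = forest, 0 = non-forest.
#' @return Numeric vector of NFC in `[0,1]`, one value per retained cell, in
#'   `retained_cells(grid)` order.
#' @export
overlay_nfc <- function(grid, forest) {
  rc <- retained_cells(grid)
  area <- attr(grid, "cell_size")^2
  if (inherits(forest, "fs_raster")) {
    agg <- aggregate_raster(grid, forest, fun = "sum")
    nfc <- ifelse(is.na(agg), 0, agg) * forest$res^2 / area
  } else {
    if (is.matrix(forest)) forest <- list(forest)
    bad <- vapply(forest, function(p) is.null(nrow(p)) || nrow(p) < 3, logical(1))
    if (any(bad)) stop("invalid forest polygon(s): ", paste(which(bad), collapse = ", "))
    nfc <- vapply(seq_len(nrow(rc)), function(i) {
      a <- sum(vapply(forest, polygon_rect_area, numeric(1),
                      rc$xmin[i], rc$ymin[i], rc$xmax[i], rc$ymax[i]))
      a / area
    }, numeric(1))
  }
  pmin(pmax(nfc, 0), 1)
}

#' Average (or sum) a raster over grid cells
#'
#' Each source pixel is assigned to the cell containing its centroid under
#' the half-open convention `[x0, x1) x [y0, y1)`, so every pixel contributes
#' to at most one cell; cell values are the mean (or sum) over assigned
#' non-NA pixels. Cells receiving no pixel centroid get NA.
#'
#' @param grid an `fs_grid`.
#' @param r an `fs_raster` in the same coordinate frame.
#' @param fun `"mean"` (default) or `"sum"`.
#' @return Numeric vector, one value per retained cell.
#' @export
aggregate_raster <- function(grid, r, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  rc <- retained_cells(grid)
  cs <- attr(grid, "cell_size")
  org <- attr(grid, "origin")
  cen <- raster_centroids(r)
  v <- as.vector(r$values)
  keep <- !is.na(v)
  col <- floor((cen$x[keep] - org[1]) / cs) + 1
  row <- floor((cen$y[keep] - org[2]) / cs) + 1
  ncx <- max(c(rc$col, col)) + 1L
  key <- (row - 1) * ncx + col
  cell_key <- (rc$row - 1) * ncx + rc$col
  idx <- match(key, cell_key)
  ok <- !is.na(idx) & col >= 1 & row >= 1
  sums <- rowsum(v[keep][ok], idx[ok])
  out <- rep(NA_real_, nrow(rc))
  out[as.integer(rownames(sums))] <- sums[, 1]
  if (fun == "mean") {
    counts <- rowsum(rep(1, sum(ok)), idx[ok])
    out[as.integer(rownames(counts))] <-
      out[as.integer(rownames(counts))] / counts[, 1]
  }
  out
}

#' Assemble the per-cell, per-period covariate table
#'
#' One row per (retained cell, period). Topography and climatic potential
#' productivity (ELE, SLO, CPP) are period-invariant — topography and climate
#' are assumed static over the study horizon — while road metrics and NFC
#' vary by period.
#'
#' @param grid an `fs_grid`.
#' @param ele,slo,cpp per-retained-cell vectors (from [aggregate_raster()]).
#' @param road_metrics wide per-cell/per-period road metric table from
#'   [road_metrics()].
#' @param nfc optional named list: period label -> per-retained-cell NFC.
#' @return A `data.frame` with columns `cell`, `period`, `ELE`, `SLO`, `CPP`,
#'   the eight road-metric columns, and `NFC` (NA where not supplied).
#' @export
build_cell_table <- function(grid, ele, slo, cpp, road_metrics, nfc = NULL) {
  rc <- retained_cells(grid)
  static <- data.frame(cell = rc$id, ELE = ele, SLO = slo, CPP = cpp)
  tab <- merge(road_metrics, static, by = "cell", sort = FALSE)
  tab$NFC <- NA_real_
  if (!is.null(nfc)) {
    for (p in names(nfc)) {
      tab$NFC[tab$period == p] <- nfc[[p]][match(tab$cell[tab$period == p], rc$id)]
    }
  }
  metric_cols <- setdiff(names(road_metrics), c("cell", "period"))
  tab <- tab[order(match(tab$period, unique(road_metrics$period)), tab$cell),
             c("cell", "period", "ELE", "SLO", "CPP", metric_cols, "NFC")]
  rownames(tab) <- NULL
  tab
}
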