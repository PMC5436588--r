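# GeoJSON and CSV serialisation of the pipeline's spatial objects. GeoJSON
# is written/read through jsonlite; coordinates are in the local planar km
# frame (recorded in the FeatureCollection's `crs_note` property).

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_geojson <- function(features, path, extra = list()) {
  fc <- c(list(type = "FeatureCollection",
               crs_note = "local planar frame, kilometres"),
          extra, list(features = features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
            c(xmin, ymin)))
}

#' Write a grid as GeoJSON
#'
#' One square Polygon feature per cell with `id`, `land_fraction` and
#' `retained` properties; lattice origin and cell size are recorded on the
#' collection for reproducibility.
#'
#' @param grid an `fs_grid`.
#' @param path output path.
#' @export
write_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    geojson_feature(
      list(type = "Polygon",
           coordinates = rect_ring(grid$xmin[i], grid$ymin[i],
                                   grid$xmax[i], grid$ymax[i])),
      list(id = grid$id[i], land_fraction = grid$land_fraction[i],
           retained = grid$retained[i]))
  })
  write_geojson(feats, path,
                extra = list(cell_size = attr(grid, "cell_size"),
                             origin = attr(grid, "origin")))
}

#' Write road segments as GeoJSON
#'
#' One LineString feature per segment with `class` and `period` (label of
#' the period in which it was built).
#'
#' @param roads an `fs_roads` table.
#' @param periods period labels indexed by `period_built`.
#' @param path output path.
#' @export
write_roads_geojson <- function(roads, periods, path) {
  feats <- lapply(seq_len(nrow(roads)), function(i) {
    geojson_feature(
      list(type = "LineString",
           coordinates = list(c(roads$x1[i], roads$y1[i]),
                              c(roads$x2[i], roads$y2[i]))),
      list(class = roads$class[i], period = periods[roads$period_built[i]]))
  })
  write_geojson(feats, path)
}

#' Read road segments from GeoJSON
#'
#' Accepts LineString features with `class` and `period` properties;
#' multi-vertex lines are decomposed into straight segments.
#'
#' @param path GeoJSON path.
#' @param periods period labels (to map the `period` property back to an
#'   index).
#' @return An `fs_roads` table.
#' @export
read_roads_geojson <- function(path, periods) {
  fc <- jsonlite::read_json(path)
  rows <- list()
  for (f in fc$features) {
    stopifnot(f$geometry$type == "LineString")
    cc <- f$geometry$coordinates
    for (k in seq_len(length(cc) - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        x1 = cc[[k]][[1]], y1 = cc[[k]][[2]],
        x2 = cc[[k + 1]][[1]], y2 = cc[[k + 1]][[2]],
        class = f$properties$class,
        period_built = match(f$properties$period, periods))
    }
  }
  out <- do.call(rbind, rows)
  fs_roads(out$x1, out$y1, out$x2, out$y2, out$class, out$period_built)
}

#' Write polygons (e.g. a land mask or forest patches) as GeoJSON
#'
#' @param polys list of two-column vertex matrices (open rings).
#' @param path output path.
#' @param properties optional list of per-polygon property lists.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  if (is.matrix(polys)) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ring <- lapply(seq_len(nrow(p)), function(k) c(p[k, 1], p[k, 2]))
    ring[[length(ring) + 1]] <- c(p[1, 1], p[1, 2])
    geojson_feature(list(type = "Polygon", coordinates = list(ring)),
                    if (is.null(properties)) list(id = i) else properties[[i]])
  })
  write_geojson(feats, path)
}

#' Read polygons from GeoJSON
#'
#' Outer rings of Polygon (and MultiPolygon part) features; holes are not
#' supported and raise an error.
#'
#' @param path GeoJSON path.
#' @return List of two-column vertex matrices (open rings).
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list()
  add_ring <- function(rings) {
    if (length(rings) > 1) stop("polygon holes are not supported")
    m <- do.call(rbind, lapply(rings[[1]], function(c2) c(c2[[1]], c2[[2]])))
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    out[[length(out) + 1]] <<- m
  }
  for (f in fc$features) {
    g <- f$geometry
    if (g$type == "Polygon") add_ring(g$coordinates)
    else if (g$type == "MultiPolygon") for (part in g$coordinates) add_ring(part)
    else stop("unsupported geometry type: ", g$type)
  }
  out
}

#' Write a hot-spot field as GeoJSON
#'
#' One square Polygon per retained cell with `z` and `class` properties;
#' the weighting scheme is recorded on the collection.
#'
#' @param grid an `fs_grid`.
#' @param gistar an `fs_gistar` table.
#' @param path output path.
#' @param scheme weights scheme descriptor recorded in the metadata.
#' @export
write_hotspots_geojson <- function(grid, gistar, path, scheme = "queen") {
  rc <- retained_cells(grid)
  idx <- match(gistar$cell, rc$id)
  feats <- lapply(seq_len(nrow(gistar)), function(i) {
    j <- idx[i]
    geojson_feature(
      list(type = "Polygon",
           coordinates = rect_ring(rc$xmin[j], rc$ymin[j], rc$xmax[j], rc$ymax[j])),
      list(id = gistar$cell[i], z = gistar$z[i],
           class = as.character(gistar$class[i])))
  })
  write_geojson(feats, path, extra = list(weights_scheme = scheme))
}

#' Write a data frame as CSV (stable format for reproducible bundles)
#' @param df data frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table CSV
#' @param path CSV path.
#' @return data.frame with `period` as character.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
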