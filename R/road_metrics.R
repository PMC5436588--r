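# Road-network indicators per grid cell, road class and period:
#   SRL - sum of road length per cell area (km km^-2)
#   DNR - Euclidean distance from the cell centroid to the nearest road (km)
#   NON - number of road-network nodes per cell area (km^-2)
#   MND - mean node degree; reported per cell area by default
# Nodes are defined on the planarized network: junctions (degree >= 3) and
# terminals (degree 1); pass-through vertices of degree 2 are dissolved.

#' Construct a road-segment table
#'
#' @param x1,y1,x2,y2 straight segment endpoints (km).
#' @param class road class, `"main"` or `"secondary"`.
#' @param period_built integer index of the first period in which the
#'   segment exists (networks only ever grow).
#' @return A `data.frame` of class `fs_roads`.
#' @export
fs_roads <- function(x1, y1, x2, y2, class, period_built = 1L) {
  class <- as.character(class)
  stopifnot(all(class %in% c("main", "secondary")))
  structure(data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                       class = class, period_built = as.integer(period_built)),
            class = c("fs_roads", "data.frame"))
}

#' Road segments present in a given period
#' @param roads an `fs_roads` table.
#' @param period integer period index.
#' @return The subset built in or before `period`.
#' @export
roads_in_period <- function(roads, period) {
  roads[roads$period_built <= period, , drop = FALSE]
}

# Drop zero-length segments (warning) and exact duplicate geometries
# (digitisation artifacts), direction-insensitive.
clean_segments <- function(seg) {
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  if (any(len == 0)) {
    warning(sum(len == 0), " zero-length segment(s) dropped")
    seg <- seg[len > 0, , drop = FALSE]
  }
  a <- pmin(paste(seg$x1, seg$y1), paste(seg$x2, seg$y2))
  b <- pmax(paste(seg$x1, seg$y1), paste(seg$x2, seg$y2))
  seg[!duplicated(paste(a, b)), , drop = FALSE]
}

#' Planarize a set of road segments
#'
#' Splits every pairwise crossing into shared vertices, merges coincident
#' endpoints, and classifies vertices by degree. Degree-2 pass-through
#' vertices (polyline shape points) are dissolved: the node set of the
#' returned graph is junctions (degree >= 3) plus terminals (degree 1).
#'
#' @param seg a `data.frame` with columns `x1`, `y1`, `x2`, `y2`.
#' @param snap coordinate snapping tolerance in km used to merge vertices
#'   (default 1e-6).
#' @return List of class `fs_graph`: `nodes` (data.frame `x`, `y`, `degree`
#'   for nodes of degree != 2) and `vertices` (all vertices incl. degree-2).
#' @export
planarize <- function(seg, snap = 1e-6) {
  seg <- clean_segments(seg)
  n <- nrow(seg)
  if (n == 0) {
    empty <- data.frame(x = numeric(0), y = numeric(0), degree = integer(0))
    return(structure(list(nodes = empty, vertices = empty), class = "fs_graph"))
  }
  # split parameters per segment: endpoints plus every crossing
  tsplits <- vector("list", n)
  for (i in seq_len(n)) tsplits[[i]] <- c(0, 1)
  if (n > 1) {
    bxmin <- pmin(seg$x1, seg$x2); bxmax <- pmax(seg$x1, seg$x2)
    bymin <- pmin(seg$y1, seg$y2); bymax <- pmax(seg$y1, seg$y2)
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      # bounding-box prefilter: only candidate pairs reach the exact test
      cand <- bxmin[js] <= bxmax[i] & bxmax[js] >= bxmin[i] &
        bymin[js] <= bymax[i] & bymax[js] >= bymin[i]
      js <- js[cand]
      if (!length(js)) next
      hits <- segment_intersections_one(
        seg$x1[i], seg$y1[i], seg$x2[i], seg$y2[i],
        seg$x1[js], seg$y1[js], seg$x2[js], seg$y2[js])
      if (nrow(hits)) {
        tsplits[[i]] <- c(tsplits[[i]], hits$t_i)
        for (k in seq_len(nrow(hits))) {
          j <- js[hits$j[k]]
          tsplits[[j]] <- c(tsplits[[j]], hits$t_j[k])
        }
      }
    }
  }
  # build edge list of sub-segments between consecutive split points
  ex1 <- ey1 <- ex2 <- ey2 <- vector("list", n)
  for (i in seq_len(n)) {
    t <- sort(unique(round(tsplits[[i]], 12)))
    px <- seg$x1[i] + t * (seg$x2[i] - seg$x1[i])
    py <- seg$y1[i] + t * (seg$y2[i] - seg$y1[i])
    m <- length(t) - 1
    ex1[[i]] <- px[1:m]; ey1[[i]] <- py[1:m]
    ex2[[i]] <- px[2:(m + 1)]; ey2[[i]] <- py[2:(m + 1)]
  }
  ex1 <- unlist(ex1); ey1 <- unlist(ey1); ex2 <- unlist(ex2); ey2 <- unlist(ey2)
  # drop degenerate sub-edges created by split-point rounding
  keep <- sqrt((ex2 - ex1)^2 + (ey2 - ey1)^2) > snap
  ex1 <- ex1[keep]; ey1 <- ey1[keep]; ex2 <- ex2[keep]; ey2 <- ey2[keep]
  # vertex degrees from snapped endpoint coordinates
  vx <- c(ex1, ex2); vy <- c(ey1, ey2)
  key <- paste(round(vx / snap), round(vy / snap))
  first <- !duplicated(key)
  deg <- as.integer(table(factor(key, levels = key[first])))
  vertices <- data.frame(x = vx[first], y = vy[first], degree = deg)
  nodes <- vertices[vertices$degree != 2, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, vertices = vertices), class = "fs_graph")
}

#' Sum of road length per unit cell area (SRL)
#'
#' @param cell one row of an `fs_grid` (needs `xmin`, `ymin`, `xmax`,
#'   `ymax`).
#' @param seg segment table (already filtered to one class/period).
#' @return SRL in km per km^2: total clipped segment length inside the cell
#'   divided by the full cell area.
#' @export
srl <- function(cell, seg) {
  area <- (cell$xmax - cell$xmin) * (cell$ymax - cell$ymin)
  if (nrow(seg) == 0) return(0)
  clip <- clip_segments_rect(seg$x1, seg$y1, seg$x2, seg$y2,
                             cell$xmin, cell$ymin, cell$xmax, cell$ymax)
  sum(clip$length) / area
}

#' Distance from the cell centroid to the nearest road (DNR)
#'
#' Network-wide: the nearest segment of the class anywhere, not only inside
#' the cell.
#'
#' @param cell one row of an `fs_grid` (needs `cx`, `cy`).
#' @param seg segment table for the class.
#' @return Distance in km; NA when the class network is empty (a missing
#'   flag, imputed at modelling time).
#' @export
dnr <- function(cell, seg) {
  if (nrow(seg) == 0) return(NA_real_)
  min(point_segment_distance(cell$cx, cell$cy, seg$x1, seg$y1, seg$x2, seg$y2))
}

#' Node density (NON) and mean node degree (MND) of a cell
#'
#' Nodes are assigned to cells by the half-open rule, so every node counts
#' in exactly one cell. NON is nodes per km^2. MND is the mean degree of the
#' cell's nodes, divided by the cell area when `per_area` (the reporting
#' convention used for the indicator); cells with no node get (0, 0).
#'
#' @param cell one row of an `fs_grid`.
#' @param graph an `fs_graph` from [planarize()].
#' @param per_area report MND per unit area (default TRUE).
#' @return Named numeric vector `c(NON = ..., MND = ...)`.
#' @export
non_mnd <- function(cell, graph, per_area = TRUE) {
  area <- (cell$xmax - cell$xmin) * (cell$ymax - cell$ymin)
  nd <- graph$nodes
  inside <- nd$x >= cell$xmin & nd$x < cell$xmax &
    nd$y >= cell$ymin & nd$y < cell$ymax
  if (!any(inside)) return(c(NON = 0, MND = 0))
  md <- mean(nd$degree[inside])
  c(NON = sum(inside) / area, MND = if (per_area) md / area else md)
}

#' All four road indicators for every retained cell, class and period
#'
#' @param grid an `fs_grid`.
#' @param roads an `fs_roads` table covering all periods.
#' @param periods character vector of period labels; period `i` uses the
#'   segments with `period_built <= i`.
#' @param mnd_per_area report MND per unit cell area (default TRUE).
#' @return Wide `data.frame`: `cell`, `period`, then
#'   `SRL_main`, `DNR_main`, `NON_main`, `MND_main` and the same for
#'   `_secondary`.
#' @export
road_metrics <- function(grid, roads, periods, mnd_per_area = TRUE) {
  rc <- retained_cells(grid)
  area <- attr(grid, "cell_size")^2
  out <- vector("list", length(periods))
  for (t in seq_along(periods)) {
    seg_t <- roads_in_period(roads, t)
    row <- data.frame(cell = rc$id, period = periods[t])
    for (cl in c("main", "secondary")) {
      seg <- seg_t[seg_t$class == cl, , drop = FALSE]
      graph <- planarize(seg)
      srl_v <- numeric(nrow(rc)); dnr_v <- numeric(nrow(rc))
      non_v <- numeric(nrow(rc)); mnd_v <- numeric(nrow(rc))
      if (nrow(seg) == 0) {
        srl_v[] <- 0; non_v[] <- 0; mnd_v[] <- 0; dnr_v[] <- NA_real_
      } else {
        bxmin <- pmin(seg$x1, seg$x2); bxmax <- pmax(seg$x1, seg$x2)
        bymin <- pmin(seg$y1, seg$y2); bymax <- pmax(seg$y1, seg$y2)
        for (i in seq_len(nrow(rc))) {
          cell <- rc[i, ]
          touch <- bxmin <= cell$xmax & bxmax >= cell$xmin &
            bymin <= cell$ymax & bymax >= cell$ymin
          srl_v[i] <- if (any(touch)) srl(cell, seg[touch, , drop = FALSE]) else 0
          dnr_v[i] <- dnr(cell, seg)
          nm <- non_mnd(cell, graph, per_area = mnd_per_area)
          non_v[i] <- nm[["NON"]]; mnd_v[i] <- nm[["MND"]]
        }
      }
      row[[paste0("SRL_", cl)]] <- srl_v
      row[[paste0("DNR_", cl)]] <- dnr_v
      row[[paste0("NON_", cl)]] <- non_v
      row[[paste0("MND_", cl)]] <- mnd_v
    }
    out[[t]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
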