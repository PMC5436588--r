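# Planar geometry kernel: everything downstream clips against axis-aligned
# grid cells, so the only primitives needed are polygon/segment clipping
# against rectangles, point-in-polygon, point-to-segment distance and
# pairwise segment intersection. All coordinates are kilometres in a local
# projected frame.

#' Signed polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertex coordinates (open ring; the
#'   closing edge back to the first vertex is implied).
#' @return Signed area; positive for counter-clockwise rings.
#' @keywords internal
polygon_area_signed <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_area_signed
#' @return Non-negative area.
#' @keywords internal
polygon_area <- function(poly) abs(polygon_area_signed(poly))

# Clip a (possibly non-convex) simple polygon against one axis-aligned
# half-plane. `axis` is 1 (x) or 2 (y); keep side where sgn*(coord - c) >= 0.
clip_halfplane <- function(poly, axis, c0, sgn) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(poly[0, , drop = FALSE])
  v <- poly[, axis]
  inside <- sgn * (v - c0) >= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  nxt <- c(2:n, 1)
  in1 <- inside; in2 <- inside[nxt]
  cross <- in1 != in2
  # Intersection of each crossing edge with the boundary line coord==c0
  t <- (c0 - v) / (poly[nxt, axis] - v)
  ix <- poly[, 1] + t * (poly[nxt, 1] - poly[, 1])
  iy <- poly[, 2] + t * (poly[nxt, 2] - poly[, 2])
  # Emit per edge i: intersection point (if crossing), then vertex i+1 (if inside)
  out_x <- c(rbind(ifelse(cross, ix, NA), ifelse(in2, poly[nxt, 1], NA)))
  out_y <- c(rbind(ifelse(cross, iy, NA), ifelse(in2, poly[nxt, 2], NA)))
  keep <- !is.na(out_x)
  cbind(out_x[keep], out_y[keep])
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param poly two-column coordinate matrix (simple polygon, open ring).
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return Clipped polygon vertex matrix (possibly 0 rows). For non-convex
#'   subjects the result may contain degenerate connecting edges; its area is
#'   still the exact intersection area.
#' @keywords internal
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  p <- clip_halfplane(poly, 1, xmin, +1)
  p <- clip_halfplane(p, 1, xmax, -1)
  p <- clip_halfplane(p, 2, ymin, +1)
  clip_halfplane(p, 2, ymax, -1)
}

#' Area of intersection between a polygon and a rectangle
#' @inheritParams clip_polygon_rect
#' @keywords internal
polygon_rect_area <- function(poly, xmin, ymin, xmax, ymax) {
  polygon_area(clip_polygon_rect(poly, xmin, ymin, xmax, ymax))
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param poly polygon vertex matrix.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yn[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Clip segments to a rectangle (Liang-Barsky), vectorised over segments
#'
#' @param x1,y1,x2,y2 segment endpoint vectors.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return List with `t0`, `t1` (clip parameters, NA when the segment misses
#'   the rectangle) and `length` (clipped length, 0 when it misses).
#' @keywords internal
clip_segments_rect <- function(x1, y1, x2, y2, xmin, ymin, xmax, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- rep(0, length(x1)); t1 <- rep(1, length(x1))
  ok <- rep(TRUE, length(x1))
  upd <- function(p, q) {
    # p: direction component against the boundary; q: slack
    zero <- p == 0
    ok <<- ok & !(zero & q < 0)
    r <- ifelse(zero, NA_real_, q / p)
    neg <- !zero & p < 0
    pos <- !zero & p > 0
    t0 <<- ifelse(neg, pmax(t0, r), t0)
    t1 <<- ifelse(pos, pmin(t1, r), t1)
    invisible(NULL)
  }
  upd(-dx, x1 - xmin)
  upd(dx, xmax - x1)
  upd(-dy, y1 - ymin)
  upd(dy, ymax - y1)
  ok <- ok & (t1 >= t0)
  len <- ifelse(ok, sqrt(dx^2 + dy^2) * pmax(t1 - t0, 0), 0)
  list(t0 = ifelse(ok, t0, NA_real_), t1 = ifelse(ok, t1, NA_real_), length = len)
}

#' Distance from one point to each of a set of segments
#'
#' @param px,py the point.
#' @param x1,y1,x2,y2 segment endpoint vectors.
#' @return Vector of Euclidean distances.
#' @keywords internal
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  t <- ifelse(l2 == 0, 0, ((px - x1) * dx + (py - y1) * dy) / l2)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Proper/touching intersection of segment i with segments js (vectorised over
# js). Returns data.frame of (j, t_i, t_j, x, y) for parameter values in
# [0,1] on both; parallel/collinear pairs are skipped (the road generator
# never produces overlapping collinear spans, and exact duplicates are
# deduplicated upstream).
segment_intersections_one <- function(xi1, yi1, xi2, yi2, x1, y1, x2, y2) {
  rx <- xi2 - xi1; ry <- yi2 - yi1
  sx <- x2 - x1; sy <- y2 - y1
  denom <- rx * sy - ry * sx
  qpx <- x1 - xi1; qpy <- y1 - yi1
  ti <- (qpx * sy - qpy * sx) / denom
  tj <- (qpx * ry - qpy * rx) / denom
  eps <- 1e-12
  hit <- abs(denom) > eps & ti >= -eps & ti <= 1 + eps & tj >= -eps & tj <= 1 + eps
  hit[is.na(hit)] <- FALSE
  data.frame(
    j = which(hit),
    t_i = pmin(pmax(ti[hit], 0), 1),
    t_j = pmin(pmax(tj[hit], 0), 1),
    x = xi1 + pmin(pmax(ti[hit], 0), 1) * rx,
    y = yi1 + pmin(pmax(ti[hit], 0), 1) * ry
  )
}
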