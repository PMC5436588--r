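# Getis-Ord Gi* hot/cold-spot detection over the retained cells of the
# grid. The statistic for cell i is
#   z_i = (sum_j w_ij x_j - Xbar * sum_j w_ij) /
#         ( S * sqrt( (n * sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1) ) )
# with Xbar the global mean, S = sqrt(mean(x^2) - Xbar^2), and w including
# the focal cell itself (w_ii = 1). It is already a z score; cells are
# classified against the two-sided normal quantiles 1.645 / 1.960 / 2.576.

#' Build a spatial weights matrix over retained cells
#'
#' Binary weights under queen contiguity (shared edge or corner), rook
#' contiguity (shared edge), or a centroid distance band; the self-weight 1
#' is always included, as the Gi* convention requires. Cells with no
#' neighbour under a distance band keep only their self-weight, with a
#' warning.
#'
#' @param grid an `fs_grid`.
#' @param scheme `"queen"` (default), `"rook"`, or `"distance_band"`.
#' @param band band radius in km (required for `"distance_band"`).
#' @return A sparse symmetric `Matrix` of class `fs_weights` with a
#'   `scheme` attribute, rows/columns in `retained_cells(grid)` order.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "distance_band"),
                          band = NULL) {
  scheme <- match.arg(scheme)
  rc <- retained_cells(grid)
  n <- nrow(rc)
  if (scheme == "distance_band") {
    if (is.null(band)) stop("distance_band scheme needs a band radius")
    if (band < attr(grid, "cell_size"))
      warning("band radius smaller than the cell size: isolated cells likely")
    d2 <- outer(rc$cx, rc$cx, `-`)^2 + outer(rc$cy, rc$cy, `-`)^2
    w <- (d2 <= band^2) * 1
  } else {
    dc <- abs(outer(rc$col, rc$col, `-`))
    dr <- abs(outer(rc$row, rc$row, `-`))
    w <- if (scheme == "queen") (dc <= 1 & dr <= 1) * 1
         else ((dc + dr) <= 1) * 1
  }
  diag(w) <- 1
  if (scheme == "distance_band" && any(Matrix::rowSums(w) == 1))
    warning(sum(Matrix::rowSums(w) == 1), " cell(s) have self-only weights")
  w <- Matrix::Matrix(w, sparse = TRUE)
  attr(w, "scheme") <- scheme
  attr(w, "band") <- band
  attr(w, "cell_ids") <- rc$id
  w
}

#' Getis-Ord Gi* z-scores
#'
#' @param values numeric vector over the weight matrix's index set (finite).
#' @param weights a weights matrix from [build_weights()].
#' @return `data.frame` of class `fs_gistar`: `cell`, `z`, `class` with
#'   levels `cold99 < cold95 < cold90 < ns < hot90 < hot95 < hot99`. For a
#'   constant field the statistic is undefined: all `z` are NA and the
#'   result carries attribute `undefined = TRUE`.
#' @export
gi_star <- function(values, weights) {
  n <- length(values)
  stopifnot(n >= 2, nrow(weights) == n)
  if (any(!is.finite(values))) stop("values must be finite")
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  ids <- attr(weights, "cell_ids")
  if (is.null(ids)) ids <- seq_len(n)
  if (s == 0) {
    out <- data.frame(cell = ids, z = NA_real_,
                      class = factor(rep(NA, n), levels = gi_levels()))
    attr(out, "undefined") <- TRUE
    class(out) <- c("fs_gistar", "data.frame")
    return(out)
  }
  wx <- as.numeric(weights %*% values)
  sw <- Matrix::rowSums(weights)
  sw2 <- Matrix::rowSums(weights^2)
  z <- (wx - xbar * sw) / (s * sqrt((n * sw2 - sw^2) / (n - 1)))
  out <- data.frame(cell = ids, z = z, class = classify_gi(z))
  attr(out, "undefined") <- FALSE
  class(out) <- c("fs_gistar", "data.frame")
  out
}

gi_levels <- function() c("cold99", "cold95", "cold90", "ns", "hot90", "hot95", "hot99")

#' Classify Gi* z-scores at the 90/95/99% confidence levels
#' @param z numeric vector of z-scores.
#' @return Factor with levels `cold99 ... hot99`.
#' @export
classify_gi <- function(z) {
  cls <- rep("ns", length(z))
  cls[z <= -1.645] <- "cold90"
  cls[z <= -1.960] <- "cold95"
  cls[z <= -2.576] <- "cold99"
  cls[z >= 1.645] <- "hot90"
  cls[z >= 1.960] <- "hot95"
  cls[z >= 2.576] <- "hot99"
  factor(cls, levels = gi_levels())
}

#' Hot/cold-spot report for a change field
#'
#' Runs Gi* on a per-cell change field. Negative-z clusters are hot spots of
#' NFC DECREASE (deforestation), positive-z clusters of increase.
#'
#' @param grid an `fs_grid`.
#' @param values per-retained-cell change field (e.g. `d_nfc` from
#'   [change_table()]).
#' @param weights optional weights (default queen contiguity on `grid`).
#' @return The `fs_gistar` table joined with cell centroids.
#' @export
hotspot_report <- function(grid, values, weights = NULL) {
  if (is.null(weights)) weights <- build_weights(grid, "queen")
  rc <- retained_cells(grid)
  g <- gi_star(values, weights)
  g$cx <- rc$cx[match(g$cell, rc$id)]
  g$cy <- rc$cy[match(g$cell, rc$id)]
  g
}
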