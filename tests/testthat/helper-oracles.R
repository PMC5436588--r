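# Independent oracles used to check the implementation by a different route.

# OLS via the textbook normal equations (X'X)^-1 X'y, with adjusted R^2, F
# and p computed from first principles.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X) - 1
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  list(slope = beta[2], intercept = beta[1], r_squared = 100 * r2,
       adj_r_squared = 100 * adj, f = f,
       p = stats::pf(f, p, n - p - 1, lower.tail = FALSE))
}

# Literal per-cell evaluation of the Getis-Ord Gi* formula, scalar loops,
# no matrix algebra.
gi_star_oracle <- function(values, w_dense) {
  n <- length(values)
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wi <- w_dense[i, ]
    num <- sum(wi * values) - xbar * sum(wi)
    den <- s * sqrt((n * sum(wi^2) - sum(wi)^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

# Segment clipped length inside a rectangle via explicit parameter-interval
# intersection (independent of the Liang-Barsky routine).
clip_length_oracle <- function(x1, y1, x2, y2, xmin, ymin, xmax, ymax) {
  axis_interval <- function(a, b, lo, hi) {
    if (a == b) {
      if (a < lo || a > hi) return(NULL)
      return(c(0, 1))
    }
    t <- sort(c((lo - a) / (b - a), (hi - a) / (b - a)))
    c(max(t[1], 0), min(t[2], 1))
  }
  ix <- axis_interval(x1, x2, xmin, xmax)
  iy <- axis_interval(y1, y2, ymin, ymax)
  if (is.null(ix) || is.null(iy)) return(0)
  lo <- max(ix[1], iy[1]); hi <- min(ix[2], iy[2])
  if (hi <= lo) return(0)
  (hi - lo) * sqrt((x2 - x1)^2 + (y2 - y1)^2)
}

# Distance to a segment set by dense point sampling along each segment.
dnr_oracle <- function(px, py, seg, step = 0.002) {
  best <- Inf
  for (i in seq_len(nrow(seg))) {
    len <- sqrt((seg$x2[i] - seg$x1[i])^2 + (seg$y2[i] - seg$y1[i])^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    qx <- seg$x1[i] + t * (seg$x2[i] - seg$x1[i])
    qy <- seg$y1[i] + t * (seg$y2[i] - seg$y1[i])
    best <- min(best, min(sqrt((qx - px)^2 + (qy - py)^2)))
  }
  best
}

# Planar node/degree multiset by brute force: split every segment at every
# pairwise intersection, snap endpoints on a coarse key, count incidences,
# drop pass-through (degree 2) vertices.
planarize_oracle <- function(seg, snap = 1e-6) {
  n <- nrow(seg)
  splits <- lapply(seq_len(n), function(i) c(0, 1))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      rx <- seg$x2[i] - seg$x1[i]; ry <- seg$y2[i] - seg$y1[i]
      sx <- seg$x2[j] - seg$x1[j]; sy <- seg$y2[j] - seg$y1[j]
      den <- rx * sy - ry * sx
      if (abs(den) < 1e-12) next
      qx <- seg$x1[j] - seg$x1[i]; qy <- seg$y1[j] - seg$y1[i]
      ti <- (qx * sy - qy * sx) / den
      tj <- (qx * ry - qy * rx) / den
      if (ti >= -1e-12 && ti <= 1 + 1e-12 && tj >= -1e-12 && tj <= 1 + 1e-12) {
        splits[[i]] <- c(splits[[i]], min(max(ti, 0), 1))
        splits[[j]] <- c(splits[[j]], min(max(tj, 0), 1))
      }
    }
  }
  ex <- ey <- numeric(0)
  for (i in seq_len(n)) {
    t <- sort(unique(round(splits[[i]], 12)))
    px <- seg$x1[i] + t * (seg$x2[i] - seg$x1[i])
    py <- seg$y1[i] + t * (seg$y2[i] - seg$y1[i])
    for (k in seq_len(length(t) - 1)) {
      if (sqrt((px[k + 1] - px[k])^2 + (py[k + 1] - py[k])^2) > snap) {
        ex <- c(ex, px[k], px[k + 1]); ey <- c(ey, py[k], py[k + 1])
      }
    }
  }
  key <- paste(round(ex / snap), round(ey / snap))
  tab <- table(key)
  first <- !duplicated(key)
  coord <- data.frame(key = key[first], x = ex[first], y = ey[first])
  coord$degree <- as.integer(tab[coord$key])
  coord <- coord[coord$degree != 2, c("x", "y", "degree")]
  coord[order(coord$x, coord$y), ]
}

random_segments <- function(n, extent = 10, min_len = 1, max_len = 4) {
  x1 <- runif(n, 0, extent); y1 <- runif(n, 0, extent)
  ang <- runif(n, 0, 2 * pi); len <- runif(n, min_len, max_len)
  data.frame(x1 = x1, y1 = y1, x2 = x1 + len * cos(ang), y2 = y1 + len * sin(ang))
}
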