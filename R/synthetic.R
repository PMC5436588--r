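# Synthetic island generator. Emulates the study system end-to-end: a
# roughly circular tropical island with a central mountain massif, a
# climatic-productivity surface, a two-class road network that densifies
# over four periods (main roads keep growing; the secondary network
# saturates after the second period), and per-cell natural forest cover
# (NFC) produced by a known monotone function of the covariates plus
# bounded noise, declining as the road network grows. Everything is
# deterministic under the scenario seed, so downstream stages can be tested
# against known ground truth.

#' Define a synthetic island scenario
#'
#' Defaults describe an island of Hainan-like extent (~31,000 km^2) whose
#' mean road-length densities per period track the magnitudes reported for
#' such landscapes (main-road SRL growing from ~0.11 to ~0.45 km km^-2, the
#' secondary network stable after the second period) and whose period-mean
#' NFC declines from ~0.41 to ~0.24.
#'
#' @param seed integer root seed; the same seed reproduces every output
#'   bit-identically.
#' @param island_radius_km nominal coastline radius (km).
#' @param cell_size_km analysis cell edge (km).
#' @param periods period labels, oldest first.
#' @param period_years representative calendar year per period (used only
#'   for per-decade change rates).
#' @param n_towns number of towns anchoring the main-road network (>= 2).
#' @param road_growth list with integer vectors `main` and `secondary`:
#'   number of road segments ADDED in each period. Secondary additions must
#'   be zero from period 3 onward (the saturating-network contract).
#' @param segment_length_km nominal road segment length.
#' @param nfc_coefficients named coefficients of the NFC link predictor over
#'   (intercept, ELE, SLO, CPP, SRL_main, SRL_secondary, DNR_main), applied
#'   to internally standardised covariates (see [generate_nfc()]).
#' @param nfc_interaction coefficient of the SRL_main x slope interaction
#'   (nonlinearity; set 0 for a purely additive truth).
#' @param noise_sd i.i.d. Gaussian noise added to true NFC, in [0, 0.2].
#' @param relief_max_m peak elevation of the central massif (m).
#' @param ele_res_km elevation/productivity raster resolution (km).
#' @param mask_res_km forest-mask raster resolution (km); 0.1 km gives 2,500
#'   pixels per 5-km cell, an NFC quantum of 4e-4.
#' @return A list of class `fs_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               island_radius_km = 100,
                               cell_size_km = 5,
                               periods = c("1950s", "1970s", "1990s", "2010s"),
                               period_years = c(1950, 1970, 1990, 2010),
                               n_towns = 24,
                               road_growth = list(main = c(595, 650, 230, 980),
                                                  secondary = c(1400, 1400, 0, 0)),
                               segment_length_km = 4,
                               nfc_coefficients = c(intercept = -1.11, ELE = 0.40,
                                                    SLO = 0.55, CPP = -0.25,
                                                    SRL_main = -2.30,
                                                    SRL_secondary = -1.50,
                                                    DNR_main = 0.05),
                               nfc_interaction = 1.80,
                               noise_sd = 0.05,
                               relief_max_m = 1800,
                               ele_res_km = 0.5,
                               mask_res_km = 0.1) {
  if (island_radius_km <= 0) stop("island_radius_km must be positive")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  if (n_towns < 2) stop("need at least 2 towns to anchor the road network")
  if (noise_sd < 0 || noise_sd > 0.2) stop("noise_sd must lie in [0, 0.2]")
  stopifnot(length(periods) == length(period_years),
            length(road_growth$main) == length(periods),
            length(road_growth$secondary) == length(periods))
  if (length(periods) > 2 && any(road_growth$secondary[-(1:2)] != 0))
    stop("secondary road additions must be zero after period 2 (saturating network)")
  need <- c("intercept", "ELE", "SLO", "CPP", "SRL_main", "SRL_secondary", "DNR_main")
  stopifnot(all(need %in% names(nfc_coefficients)))
  structure(list(seed = as.integer(seed), island_radius_km = island_radius_km,
                 cell_size_km = cell_size_km, periods = periods,
                 period_years = period_years, n_towns = n_towns,
                 road_growth = road_growth, segment_length_km = segment_length_km,
                 nfc_coefficients = nfc_coefficients,
                 nfc_interaction = nfc_interaction, noise_sd = noise_sd,
                 relief_max_m = relief_max_m, ele_res_km = ele_res_km,
                 mask_res_km = mask_res_km),
            class = "fs_scenario")
}

# Stage-specific seeds derived from the root seed (kept below 2^31).
stage_seed <- function(scenario, stage) {
  offsets <- c(island = 101L, terrain = 211L, cpp = 307L, towns = 401L,
               roads = 503L, nfc = 601L, mask = 701L)
  (scenario$seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Generate the island coastline
#'
#' The coast is a star-shaped radial perturbation of a circle: low-order
#' cosine harmonics on the radius, sampled as a 720-vertex polygon centred
#' at the origin.
#'
#' @param scenario an `fs_scenario`.
#' @return List: `polygon` (vertex matrix), `radius_fun(theta)`, `center`.
#' @export
generate_island <- function(scenario) {
  set.seed(stage_seed(scenario, "island"))
  R <- scenario$island_radius_km
  k <- 2:5
  amp <- stats::runif(length(k), 0.02, 0.06)
  phase <- stats::runif(length(k), 0, 2 * pi)
  radius_fun <- function(theta) {
    r <- rep(R, length(theta))
    for (i in seq_along(k)) r <- r + R * amp[i] * cos(k[i] * theta + phase[i])
    r
  }
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  poly <- cbind(radius_fun(theta) * cos(theta), radius_fun(theta) * sin(theta))
  list(polygon = poly, radius_fun = radius_fun, center = c(0, 0))
}

# Raster extent covering the island, aligned to the grid lattice.
island_extent <- function(scenario, island) {
  cs <- scenario$cell_size_km
  x0 <- floor(min(island$polygon[, 1]) / cs) * cs
  y0 <- floor(min(island$polygon[, 2]) / cs) * cs
  x1 <- x0 + ceiling((max(island$polygon[, 1]) - x0) / cs) * cs
  y1 <- y0 + ceiling((max(island$polygon[, 2]) - y0) / cs) * cs
  c(x0, y0, x1, y1)
}

# Land test on raster pixel centroids via the radial coastline function.
mask_to_land <- function(values, r, island) {
  cen <- raster_centroids(fs_raster(values, r$xmin, r$ymin, r$res))
  d <- sqrt(cen$x^2 + cen$y^2)
  theta <- atan2(cen$y, cen$x)
  land <- d <= island$radius_fun(theta)
  values[!land] <- NA
  values
}

#' Generate elevation and slope rasters
#'
#' Elevation is a central dome (the mountain massif) plus Gaussian-smoothed
#' white noise, clamped non-negative and masked to land; slope is derived by
#' finite differences on the elevation raster.
#'
#' @param scenario an `fs_scenario`.
#' @param island from [generate_island()].
#' @return List with `elevation` (m) and `slope` (degrees) rasters.
#' @export
generate_terrain <- function(scenario, island) {
  set.seed(stage_seed(scenario, "terrain"))
  ext <- island_extent(scenario, island)
  res <- scenario$ele_res_km
  nc <- round((ext[3] - ext[1]) / res)
  nr <- round((ext[4] - ext[2]) / res)
  cx <- ext[1] + (seq_len(nc) - 0.5) * res
  cy <- ext[2] + (nr - seq_len(nr) + 0.5) * res
  d <- sqrt(outer(cy^2, cx^2, `+`))
  dome <- scenario$relief_max_m *
    pmax(0, 1 - (d / (0.72 * scenario$island_radius_km))^2)^1.6
  noise <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 4)
  noise <- noise / stats::sd(noise) * 180
  z <- pmax(dome + noise, 0)
  z <- mask_to_land(z, fs_raster(z, ext[1], ext[2], res), island)
  elevation <- fs_raster(z, ext[1], ext[2], res)
  list(elevation = elevation, slope = slope_from_elevation(elevation))
}

#' Generate the climatic-potential-productivity raster
#'
#' Productivity (kg hm^-2 a^-1) declines with elevation (cooler uplands) and
#' carries a smooth regional gradient, emulating the island's uneven
#' rainfall.
#'
#' @param scenario an `fs_scenario`.
#' @param island from [generate_island()].
#' @param elevation elevation raster from [generate_terrain()].
#' @return An `fs_raster` of CPP.
#' @export
generate_cpp <- function(scenario, island, elevation) {
  set.seed(stage_seed(scenario, "cpp"))
  z <- elevation$values
  noise <- gaussian_smooth(matrix(stats::rnorm(length(z)), nrow(z), ncol(z)),
                           sigma = 8)
  noise <- noise / stats::sd(noise)
  cpp <- pmax(9000 - 2.0 * ifelse(is.na(z), 0, z) + 1200 * noise, 500)
  cpp[is.na(z)] <- NA
  fs_raster(cpp, elevation$xmin, elevation$ymin, elevation$res)
}

# Towns cluster on the coastal lowlands (the mountainous interior is barely
# settled), which concentrates road growth -- and hence forest loss -- in
# the cells that already have the least forest.
sample_towns <- function(n, island, coastal_fraction = 0.9) {
  theta <- stats::runif(n, 0, 2 * pi)
  coastal <- stats::runif(n) < coastal_fraction
  frac <- ifelse(coastal, stats::runif(n, 0.72, 0.95),
                 stats::runif(n, 0.40, 0.65))
  r <- island$radius_fun(theta) * frac
  cbind(r * cos(theta), r * sin(theta))
}

#' Generate the multi-period two-class road network
#'
#' Main roads connect towns: a minimum spanning tree first, then
#' near-neighbour and long-distance links, each rendered as a chain of
#' jittered straight segments; the pool is consumed in construction order,
#' so every period's network is a superset of the previous one. Secondary
#' roads are short branches sprouting from the network existing at the time,
#' which concentrates secondary growth where roads (and hence deforestation)
#' already are.
#'
#' @param scenario an `fs_scenario`.
#' @param island from [generate_island()].
#' @return An `fs_roads` segment table with `class` and `period_built`.
#' @export
generate_roads <- function(scenario, island) {
  if (scenario$n_towns < 2) stop("need at least 2 towns")
  set.seed(stage_seed(scenario, "towns"))
  towns <- sample_towns(scenario$n_towns, island)
  set.seed(stage_seed(scenario, "roads"))
  seglen <- scenario$segment_length_km
  n_main_total <- sum(scenario$road_growth$main)

  # --- link order: MST, then 2nd/3rd nearest neighbours, then random pairs
  D <- as.matrix(stats::dist(towns))
  n <- nrow(towns)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  links <- matrix(0L, 0, 2)
  dmin <- D[, 1]; from <- rep(1L, n)
  while (!all(in_tree)) {
    cand <- which(!in_tree)
    j <- cand[which.min(dmin[cand])]
    links <- rbind(links, c(from[j], j))
    in_tree[j] <- TRUE
    upd <- !in_tree & D[, j] < dmin
    dmin[upd] <- D[upd, j]; from[upd] <- j
  }
  for (k in 2:3) {
    nn <- apply(D + diag(Inf, n), 1, function(d) order(d)[k])
    links <- rbind(links, cbind(seq_len(n), nn))
  }
  a <- pmin(links[, 1], links[, 2]); b <- pmax(links[, 1], links[, 2])
  links <- links[!duplicated(paste(a, b)), , drop = FALSE]

  # --- render links as jittered chains until the main pool is large enough
  chain <- function(p, q) {
    d <- sqrt(sum((q - p)^2))
    m <- max(1L, ceiling(d / seglen))
    t <- seq(0, 1, length.out = m + 1)
    vx <- p[1] + t * (q[1] - p[1]); vy <- p[2] + t * (q[2] - p[2])
    if (m > 1) {
      j <- stats::rnorm(m - 1, 0, 0.035 * d)
      ux <- -(q[2] - p[2]) / d; uy <- (q[1] - p[1]) / d
      vx[2:m] <- vx[2:m] + j * ux
      vy[2:m] <- vy[2:m] + j * uy
    }
    cbind(vx[-(m + 1)], vy[-(m + 1)], vx[-1], vy[-1])
  }
  pool <- vector("list", 0)
  n_seg <- 0L
  li <- 1L
  while (n_seg < n_main_total) {
    if (li <= nrow(links)) {
      p <- towns[links[li, 1], ]; q <- towns[links[li, 2], ]
      li <- li + 1L
    } else {
      # densification links favour nearby towns (distance decay), so late
      # growth thickens the settled lowlands rather than crossing the range
      i0 <- sample.int(n, 1)
      wgt <- exp(-D[i0, ] / 30); wgt[i0] <- 0
      j0 <- sample.int(n, 1, prob = wgt)
      p <- towns[i0, ]; q <- towns[j0, ]
    }
    cs <- chain(p, q)
    pool[[length(pool) + 1]] <- cs
    n_seg <- n_seg + nrow(cs)
  }
  main <- do.call(rbind, pool)[seq_len(n_main_total), , drop = FALSE]
  main_period <- rep(seq_along(scenario$periods),
                     times = scenario$road_growth$main)

  # --- secondary branches off the contemporaneous network
  sx1 <- sy1 <- sx2 <- sy2 <- numeric(0)
  sec_period <- integer(0)
  for (t in seq_along(scenario$periods)) {
    n_add <- scenario$road_growth$secondary[t]
    if (n_add == 0) next
    bx1 <- c(main[main_period <= t, 1], sx1)
    by1 <- c(main[main_period <= t, 2], sy1)
    bx2 <- c(main[main_period <= t, 3], sx2)
    by2 <- c(main[main_period <= t, 4], sy2)
    for (s in seq_len(n_add)) {
      w <- sqrt((bx2 - bx1)^2 + (by2 - by1)^2)
      i <- sample.int(length(w), 1, prob = w)
      tt <- stats::runif(1)
      px <- bx1[i] + tt * (bx2[i] - bx1[i])
      py <- by1[i] + tt * (by2[i] - by1[i])
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.5, 1.4) * seglen
      qx <- px + len * cos(ang); qy <- py + len * sin(ang)
      sx1 <- c(sx1, px); sy1 <- c(sy1, py); sx2 <- c(sx2, qx); sy2 <- c(sy2, qy)
      sec_period <- c(sec_period, t)
      bx1 <- c(bx1, px); by1 <- c(by1, py); bx2 <- c(bx2, qx); by2 <- c(by2, qy)
    }
  }
  fs_roads(x1 = c(main[, 1], sx1), y1 = c(main[, 2], sy1),
           x2 = c(main[, 3], sx2), y2 = c(main[, 4], sy2),
           class = c(rep("main", nrow(main)), rep("secondary", length(sx1))),
           period_built = c(main_period, sec_period))
}

# Standardisation constants for the NFC link predictor: fixed reference
# scales (not data-dependent), so the truth function is fully specified by
# the coefficient vector.
nfc_design <- function(scenario, cell_table) {
  b <- scenario$nfc_coefficients
  z_slo <- cell_table$SLO / 4
  lp <- b[["intercept"]] +
    b[["ELE"]] * cell_table$ELE / 300 +
    b[["SLO"]] * z_slo +
    b[["CPP"]] * (cell_table$CPP - 8000) / 2000 +
    b[["SRL_main"]] * cell_table$SRL_main +
    b[["SRL_secondary"]] * cell_table$SRL_secondary +
    b[["DNR_main"]] * cell_table$DNR_main / 10 +
    scenario$nfc_interaction * cell_table$SRL_main * z_slo
  lp
}

#' Generate true per-cell NFC for every period
#'
#' True NFC is the inverse logit of a linear predictor over the standardised
#' covariates plus i.i.d. Gaussian noise, clipped to [0, 1]. The inverse
#' logit keeps the noiseless truth inside the unit interval by construction;
#' clipping only guards the noise tails, and a warning is raised if more
#' than 5% of values clip.
#'
#' @param scenario an `fs_scenario`.
#' @param cell_table covariate table from [build_cell_table()] (NFC column
#'   may be empty), complete for all cells and periods.
#' @return `cell_table` with columns `NFC_true` (realised, noisy) and
#'   `NFC_signal` (noiseless inverse-logit surface) filled in.
#' @export
generate_nfc <- function(scenario, cell_table) {
  need <- c("ELE", "SLO", "CPP", "SRL_main", "SRL_secondary", "DNR_main")
  miss <- need[!need %in% names(cell_table)]
  if (length(miss)) stop("cell table lacks covariates: ", paste(miss, collapse = ", "))
  if (anyNA(cell_table[need]))
    stop("cell table has missing covariates; the generator requires complete rows")
  set.seed(stage_seed(scenario, "nfc"))
  signal <- stats::plogis(nfc_design(scenario, cell_table))
  raw <- signal + stats::rnorm(length(signal), 0, scenario$noise_sd)
  clipped <- raw < 0 | raw > 1
  if (mean(clipped) > 0.05)
    warning(sprintf("%.1f%% of true NFC values clipped to [0,1]", 100 * mean(clipped)))
  cell_table$NFC_signal <- signal
  cell_table$NFC_true <- pmin(pmax(raw, 0), 1)
  cell_table
}

#' Rasterize per-cell NFC into a binary forest mask
#'
#' Within each retained cell the `round(NFC * npix)` most suitable pixels
#' are set to forest, so the polygon/pixel overlay recovers the cell NFC to
#' within half a pixel-area quantum. Suitability is elevation plus fine
#' noise, which clumps forest into upland patches.
#'
#' @param scenario an `fs_scenario`.
#' @param grid the analysis grid.
#' @param nfc per-retained-cell NFC vector (one period).
#' @param elevation elevation raster (suitability backbone).
#' @param frame optional precomputed pixel frame (internal; lets several
#'   periods share the pixel-to-cell assignment and suitability ranking).
#' @return Binary `fs_raster` at `mask_res_km` resolution (non-land and
#'   non-retained areas are 0).
#' @export
rasterize_forest <- function(scenario, grid, nfc, elevation, frame = NULL) {
  if (is.null(frame)) frame <- forest_mask_frame(scenario, grid, elevation)
  vals <- integer(frame$n_pix)
  for (ci in seq_along(frame$pix_ranked)) {
    k <- round(nfc[frame$cell_row[ci]] * length(frame$pix_ranked[[ci]]))
    if (k > 0) vals[frame$pix_ranked[[ci]][seq_len(k)]] <- 1L
  }
  out <- matrix(vals, frame$nr, frame$nc)
  fs_raster(out, frame$xmin, frame$ymin, frame$res)
}

# Pixel-to-cell assignment and per-cell suitability ranking, computed once
# and shared across periods (the suitability surface is static, so forest
# loss is spatially nested over time).
forest_mask_frame <- function(scenario, grid, elevation) {
  set.seed(stage_seed(scenario, "mask"))
  rc <- retained_cells(grid)
  cs <- attr(grid, "cell_size")
  org <- attr(grid, "origin")
  res <- scenario$mask_res_km
  gx1 <- min(grid$xmin); gy1 <- min(grid$ymin)
  nc <- round((max(grid$xmax) - gx1) / res)
  nr <- round((max(grid$ymax) - gy1) / res)
  cen <- raster_centroids(fs_raster(matrix(0L, nr, nc), gx1, gy1, res))
  col <- floor((cen$x - org[1]) / cs) + 1L
  row <- floor((cen$y - org[2]) / cs) + 1L
  ncx <- max(c(rc$col, col)) + 1L
  pix_cell <- match((row - 1) * ncx + col, (rc$row - 1) * ncx + rc$col)
  pix_cell[col < 1 | row < 1] <- NA
  # suitability: elevation (nearest-neighbour lookup) + fine tie-breaker noise
  ei <- pmin(pmax(floor((cen$x - elevation$xmin) / elevation$res) + 1, 1),
             ncol(elevation$values))
  ej <- pmin(pmax(nrow(elevation$values) -
                    floor((cen$y - elevation$ymin) / elevation$res), 1),
             nrow(elevation$values))
  suit <- elevation$values[cbind(ej, ei)]
  suit[is.na(suit)] <- -Inf
  suit <- suit + stats::rnorm(length(suit), 0, 40)
  idx_by_cell <- split(seq_along(pix_cell), pix_cell)
  pix_ranked <- lapply(idx_by_cell, function(pix) {
    pix[order(suit[pix], decreasing = TRUE)]
  })
  list(pix_ranked = pix_ranked,
       cell_row = as.integer(names(idx_by_cell)),
       n_pix = length(pix_cell), nr = nr, nc = nc,
       xmin = gx1, ymin = gy1, res = res)
}

#' Run the full synthetic generator
#'
#' Island, grid, terrain, productivity, roads, road metrics, covariate
#' table, true NFC and (optionally) per-period forest-mask rasters with the
#' overlay-recovered NFC written into the table's `NFC` column.
#'
#' @param scenario an `fs_scenario`.
#' @param masks rasterize forest masks and recover observed NFC by overlay
#'   (default TRUE); with FALSE, observed NFC is the true NFC directly.
#' @return List of class `fs_island_data` with elements `scenario`,
#'   `island`, `grid`, `elevation`, `slope`, `cpp`, `roads`, `metrics`,
#'   `cell_table`, `masks`.
#' @export
simulate_scenario <- function(scenario, masks = TRUE) {
  island <- generate_island(scenario)
  grid <- build_grid(island$polygon, scenario$cell_size_km)
  terrain <- generate_terrain(scenario, island)
  cpp <- generate_cpp(scenario, island, terrain$elevation)
  roads <- generate_roads(scenario, island)
  metrics <- road_metrics(grid, roads, scenario$periods)
  tab <- build_cell_table(grid,
                          ele = aggregate_raster(grid, terrain$elevation),
                          slo = aggregate_raster(grid, terrain$slope),
                          cpp = aggregate_raster(grid, cpp),
                          road_metrics = metrics)
  tab <- generate_nfc(scenario, tab)
  mask_list <- NULL
  if (masks) {
    rc <- retained_cells(grid)
    mask_list <- list()
    frame <- forest_mask_frame(scenario, grid, terrain$elevation)
    for (p in scenario$periods) {
      nfc_p <- tab$NFC_true[tab$period == p][match(rc$id, tab$cell[tab$period == p])]
      m <- rasterize_forest(scenario, grid, nfc_p, terrain$elevation, frame = frame)
      mask_list[[p]] <- m
      tab$NFC[tab$period == p] <- overlay_nfc(grid, m)[
        match(tab$cell[tab$period == p], rc$id)]
    }
  } else {
    tab$NFC <- tab$NFC_true
  }
  structure(list(scenario = scenario, island = island, grid = grid,
                 elevation = terrain$elevation, slope = terrain$slope,
                 cpp = cpp, roads = roads, metrics = metrics,
                 cell_table = tab, masks = mask_list),
            class = "fs_island_data")
}
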