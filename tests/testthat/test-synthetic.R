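test_that("scenario validation rejects impossible configurations", {
  expect_error(small_scenario(island_radius_km = -1), "positive")
  expect_error(small_scenario(n_towns = 1), "2 towns")
  expect_error(small_scenario(noise_sd = 0.5), "noise_sd")
  expect_error(small_scenario(
    road_growth = list(main = c(10, 10, 10, 10), secondary = c(10, 10, 5, 0))),
    "period 2")
})

test_that("slope of a flat field is zero and of a plane is its closed-form angle", {
  flat <- fs_raster(matrix(250, 12, 12), 0, 0, 1)
  expect_equal(slope_from_elevation(flat)$values, matrix(0, 12, 12))
  # elevation plane rising 0.1 m per m along x: slope atan(0.1) = 5.71 deg
  z <- outer(rep(1, 10), (seq_len(10) - 0.5) * 1000 * 0.1)
  plane <- fs_raster(z, 0, 0, 1)
  s <- slope_from_elevation(plane)$values
  expect_equal(s[2:9, 2:9], matrix(atan(0.1) * 180 / pi, 8, 8), tolerance = 1e-10)
})

test_that("the generator is bit-identical under a fixed seed", {
  scn <- small_scenario()
  isl1 <- generate_island(scn); isl2 <- generate_island(scn)
  expect_identical(isl1$polygon, isl2$polygon)
  t1 <- generate_terrain(scn, isl1); t2 <- generate_terrain(scn, isl2)
  expect_identical(t1$elevation$values, t2$elevation$values)
  r1 <- generate_roads(scn, isl1); r2 <- generate_roads(scn, isl2)
  expect_identical(r1, r2)
})

test_that("road networks are nested and class growth follows the scenario", {
  sim <- small_sim()
  roads <- sim$roads
  seg_key <- function(s) paste(s$x1, s$y1, s$x2, s$y2, s$class)
  for (t in 2:4) {
    prev <- roads_in_period(roads, t - 1)
    cur <- roads_in_period(roads, t)
    expect_true(nrow(cur) >= nrow(prev))
    expect_true(all(seg_key(prev) %in% seg_key(cur)))
  }
  growth <- small_scenario()$road_growth
  for (t in 1:4) {
    cur <- roads_in_period(roads, t)
    expect_equal(sum(cur$class == "main"), cumsum(growth$main)[t])
    expect_equal(sum(cur$class == "secondary"), cumsum(growth$secondary)[t])
  }
  # no growth after period 1: all period networks identical
  frozen <- small_scenario(road_growth = list(main = c(50, 0, 0, 0),
                                              secondary = c(40, 0, 0, 0)))
  fr <- generate_roads(frozen, generate_island(frozen))
  expect_identical(roads_in_period(fr, 1), roads_in_period(fr, 4))
})

test_that("true NFC responds to covariates as the link function dictates", {
  sim <- small_sim()
  tab <- sim$cell_table
  scn <- sim$scenario
  # static covariates are period-invariant per cell
  for (v in c("ELE", "SLO", "CPP")) {
    spread <- tapply(tab[[v]], tab$cell, function(x) diff(range(x)))
    expect_equal(max(spread), 0)
  }
  expect_true(all(tab$NFC_true >= 0 & tab$NFC_true <= 1))
  # period means of the noiseless signal decline strictly
  m <- tapply(tab$NFC_signal, tab$period, mean)[scn$periods]
  expect_true(all(diff(m) < 0))
  # zero noise and zero road coefficients freeze NFC across periods
  b <- scn$nfc_coefficients
  b[c("SRL_main", "SRL_secondary", "DNR_main")] <- 0
  frozen <- small_scenario(nfc_coefficients = b, nfc_interaction = 0, noise_sd = 0)
  tab0 <- generate_nfc(frozen, sim$cell_table)
  per_cell <- tapply(tab0$NFC_true, tab0$cell, function(x) diff(range(x)))
  expect_equal(max(per_cell), 0)
})

test_that("extreme coefficients trigger the clipping warning", {
  sim <- small_sim()
  b <- sim$scenario$nfc_coefficients
  b["intercept"] <- 6  # nearly everything saturates at 1, noise clips
  loud <- small_scenario(nfc_coefficients = b, noise_sd = 0.2)
  expect_warning(generate_nfc(loud, sim$cell_table), "clipped")
})

test_that("forest masks reproduce cell NFC to within one pixel-area quantum", {
  sim <- small_sim()
  tab <- sim$cell_table
  quantum <- sim$scenario$mask_res_km^2 / attr(sim$grid, "cell_size")^2
  expect_true(all(abs(tab$NFC - tab$NFC_true) <= quantum))
  # and the masks are binary rasters aligned with the grid
  m <- sim$masks[[1]]
  expect_true(all(m$values %in% c(0L, 1L)))
})

test_that("simulation is deterministic end to end", {
  scn <- small_scenario(seed = 9)
  s1 <- simulate_scenario(scn, masks = FALSE)
  s2 <- simulate_scenario(scn, masks = FALSE)
  expect_identical(s1$cell_table, s2$cell_table)
})
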