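# Shared fixtures: a small island scenario (fast enough for unit tests) and
# a cache so several test files reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

small_scenario <- function(...) {
  args <- list(
    seed = 42,
    island_radius_km = 30,
    n_towns = 8,
    road_growth = list(main = c(70, 80, 30, 120), secondary = c(150, 150, 0, 0)),
    relief_max_m = 550  # keep slopes comparable to the full-size island
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_scenario, args)
}

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    # the compressed island clips slightly more than 5% of noisy NFC values,
    # so the generator's clipping warning fires by design; not a defect
    .fixture_cache$sim <- suppressWarnings(
      simulate_scenario(small_scenario(), masks = TRUE))
  }
  .fixture_cache$sim
}

# a 4 x 4 fully-land grid (20 km square land mask, 5 km cells)
square_grid <- function(size_km = 20, cell = 5) {
  land <- cbind(c(0, size_km, size_km, 0), c(0, 0, size_km, size_km))
  build_grid(land, cell)
}

period_years_of <- function(scenario) {
  stats::setNames(scenario$period_years, scenario$periods)
}
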