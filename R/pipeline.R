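# End-to-end orchestration: simulate (or load) -> grid -> road metrics ->
# backend comparison -> fit -> hindcast -> change analysis -> hot spots,
# writing a reproducible output bundle. All randomness flows from the
# config seed, split per stage.

#' Build a pipeline configuration
#'
#' @param seed root seed for the run.
#' @param scenario an `fs_scenario`, or a list of arguments to
#'   [synthetic_scenario()] (its `seed` defaults to the pipeline seed).
#' @param backends backends entered in the NMSE comparison.
#' @param cv_folds cross-validation folds for the comparison.
#' @param observed_periods periods whose NFC is treated as observed
#'   (training data). Default: all but the first, so the earliest period is
#'   a genuine hindcast.
#' @param change_pairs list of `c(t1, t2)` period pairs for the change
#'   analysis; default: the full span plus all consecutive pairs.
#' @param weights_scheme spatial weights scheme for hot spots.
#' @param mnd_per_area report mean node degree per unit cell area.
#' @param masks rasterize forest masks and observe NFC by overlay.
#' @return List of class `fs_pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            scenario = list(),
                            backends = c("linear", "additive", "neural", "forest"),
                            cv_folds = 10,
                            observed_periods = NULL,
                            change_pairs = NULL,
                            weights_scheme = "queen",
                            mnd_per_area = TRUE,
                            masks = TRUE) {
  if (!inherits(scenario, "fs_scenario")) {
    if (is.null(scenario$seed)) scenario$seed <- seed
    scenario <- do.call(synthetic_scenario, scenario)
  }
  periods <- scenario$periods
  if (is.null(observed_periods)) observed_periods <- periods[-1]
  stopifnot(all(observed_periods %in% periods))
  if (is.null(change_pairs)) {
    change_pairs <- c(list(c(periods[1], periods[length(periods)])),
                      lapply(seq_len(length(periods) - 1),
                             function(i) c(periods[i], periods[i + 1])))
  }
  for (pr in change_pairs) stopifnot(all(pr %in% periods))
  structure(list(seed = as.integer(seed), scenario = scenario,
                 backends = backends, cv_folds = cv_folds,
                 observed_periods = observed_periods,
                 change_pairs = change_pairs,
                 weights_scheme = weights_scheme,
                 mnd_per_area = mnd_per_area, masks = masks),
            class = "fs_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; the `scenario`
#' block holds [synthetic_scenario()] fields.
#'
#' @param path YAML file.
#' @return An `fs_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$change_pairs))
    y$change_pairs <- lapply(y$change_pairs, unlist)
  if (!is.null(y$scenario$road_growth))
    y$scenario$road_growth <- lapply(y$scenario$road_growth, unlist)
  if (!is.null(y$scenario$nfc_coefficients))
    y$scenario$nfc_coefficients <- unlist(y$scenario$nfc_coefficients)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulates the scenario, compares backends by cross-validated NMSE on the
#' observed periods, fits the winning backend, reconstructs NFC for every
#' period, computes change rates, per-indicator explanatory power and the
#' main-vs-secondary variation partition for each configured period pair,
#' and maps Gi* hot/cold spots of NFC change. When `out_dir` is given the
#' bundle is written there (grid and roads GeoJSON, rasters as ASCII grids,
#' CSV tables, hot-spot GeoJSONs, and a JSON manifest).
#'
#' @param config an `fs_pipeline_config` (or path to its YAML file).
#' @param out_dir output directory (created); NULL returns results only.
#' @return List of class `fs_pipeline_result`: `sim`, `comparison`, `model`,
#'   `predictions`, `predicted_table`, `changes`, `indicator_power`,
#'   `partitions`, `nfc_vs_rate`, `hotspots`, `total_nfc`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "fs_pipeline_config"))
  scn <- config$scenario
  periods <- scn$periods
  years <- stats::setNames(scn$period_years, periods)

  sim <- simulate_scenario(scn, masks = config$masks)
  tab <- sim$cell_table

  comparison <- compare_backends(tab, backends = config$backends,
                                 periods = config$observed_periods,
                                 k = config$cv_folds,
                                 seed = config$seed + 11L)
  model <- fit_nfc_model(tab, backend = comparison$winner,
                         periods = config$observed_periods,
                         seed = config$seed + 23L)
  predictions <- do.call(rbind, lapply(periods, function(p) hindcast(model, tab, p)))

  # reconstructed series: model predictions for every period
  ptab <- tab
  ptab$NFC <- predictions$NFC_pred[match(paste(ptab$cell, ptab$period),
                                         paste(predictions$cell, predictions$period))]
  total_nfc <- vapply(periods, function(p) mean(ptab$NFC[ptab$period == p]),
                      numeric(1))

  changes <- lapply(config$change_pairs,
                    function(pr) change_table(ptab, pr[1], pr[2], years))
  names(changes) <- vapply(config$change_pairs, paste, "", collapse = ":")
  power <- indicator_power(do.call(rbind, changes))
  partitions <- lapply(changes, variation_partition)
  nfc_vs_rate <- nfc_vs_rate_slope(ptab, periods[1], periods[length(periods)], years)

  weights <- build_weights(sim$grid, config$weights_scheme)
  hotspots <- lapply(changes, function(ch) hotspot_report(sim$grid, ch$d_nfc, weights))

  manifest <- list(
    package_version = as.character(utils::packageVersion("forestscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    scenario_seed = scn$seed,
    periods = periods,
    observed_periods = config$observed_periods,
    winner_backend = comparison$winner,
    weights_scheme = config$weights_scheme,
    n_retained_cells = nrow(retained_cells(sim$grid)),
    config_hash = config_hash(config))

  res <- structure(list(sim = sim, comparison = comparison, model = model,
                        predictions = predictions, predicted_table = ptab,
                        changes = changes, indicator_power = power,
                        partitions = partitions, nfc_vs_rate = nfc_vs_rate,
                        hotspots = hotspots, total_nfc = total_nfc,
                        manifest = manifest),
                   class = "fs_pipeline_result")
  if (!is.null(out_dir)) write_bundle(res, config, out_dir)
  res
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 15)), collapse = "\n")
  # small stable FNV-1a style hash; enough to fingerprint the config
  h <- 2166136261 %% 2147483648
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

write_bundle <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  sim <- res$sim
  write_grid_geojson(sim$grid, p("grid.geojson"))
  write_polygons_geojson(sim$island$polygon, p("land_mask.geojson"))
  write_roads_geojson(sim$roads, config$scenario$periods, p("roads.geojson"))
  write_ascii_grid(sim$elevation, p("elevation.asc"))
  write_ascii_grid(sim$slope, p("slope.asc"))
  write_ascii_grid(sim$cpp, p("cpp.asc"))
  write_table_csv(sim$cell_table, p("cell_table.csv"))
  write_table_csv(res$comparison$table, p("nmse_comparison.csv"))
  write_table_csv(res$predictions, p("hindcast.csv"))
  write_table_csv(res$indicator_power, p("indicator_power.csv"))
  part <- do.call(rbind, lapply(names(res$partitions), function(nm) {
    pt <- res$partitions[[nm]]
    data.frame(period_pair = nm, adj_r2_main = pt$adj_r2_main,
               adj_r2_secondary = pt$adj_r2_secondary,
               adj_r2_combined = pt$adj_r2_combined,
               unique_main = pt$unique_main,
               unique_secondary = pt$unique_secondary, shared = pt$shared)
  }))
  write_table_csv(part, p("variation_partition.csv"))
  for (nm in names(res$hotspots)) {
    safe <- gsub(":", "_", nm)
    write_hotspots_geojson(sim$grid, res$hotspots[[nm]],
                           p(sprintf("hotspots_%s.geojson", safe)),
                           scheme = config$weights_scheme)
    write_table_csv(res$hotspots[[nm]], p(sprintf("hotspots_%s.csv", safe)))
  }
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fs_pipeline_result <- function(x, ...) {
  cat("<forestscape pipeline result>\n")
  cat(sprintf("  retained cells: %d\n", x$manifest$n_retained_cells))
  cat(sprintf("  winner backend: %s\n", x$manifest$winner_backend))
  cat("  period-mean reconstructed NFC:\n")
  print(round(x$total_nfc, 4))
  invisible(x)
}
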