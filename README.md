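# forestscape

Grid-based analysis of natural forest cover (NFC) change and its association
with road-network expansion, for landscape ecologists and conservation
analysts working with multi-period forest maps and road networks.

The package implements the full analysis chain for a tropical island whose
natural forest has been retreating as the road network densifies:

1. **Gridding** — a regular 5 × 5 km cell lattice over a land mask; cells
   with less than half their area on land are excluded. Per-cell NFC is the
   exact area fraction of natural forest in the cell, and terrain covariates
   (mean elevation ELE, slope SLO, climatic potential productivity CPP) are
   averaged over source pixels by the pixel-centroid rule.
2. **Road indicators** — per cell, road class (main / secondary) and period:
   road length density SRL (km km⁻²), distance from the cell centroid to the
   nearest road DNR (km), planar-graph node density NON (km⁻²) and mean node
   degree MND. Networks are planarized first: crossings become shared nodes,
   degree-2 shape points dissolve.
3. **Hindcasting** — NFC ~ covariates fitted with pluggable backends (GLM,
   GAM, single-layer neural network, random forest), compared by
   cross-validated *normalised mean square error*
   NMSE = MSE / Var(observed), with folds assigned by cell so no cell leaks
   across periods. The winning model reconstructs NFC for periods without
   forest maps, using period-specific road metrics and static topography.
4. **Change analysis** — per-cell NFC change rates (per decade), the
   explanatory power (adjusted R², %) of each road-indicator change in
   simple linear regressions, and variation partitioning of main- vs
   secondary-road effects (unique and shared adjusted-R² components).
5. **Hot spots** — the Getis–Ord Gi\* statistic over the cell lattice,

   z_i = (Σ_j w_ij x_j − X̄ Σ_j w_ij) / ( S·√[(n Σ_j w_ij² − (Σ_j w_ij)²)/(n−1)] ),

   with binary queen/rook/distance-band weights including the self-weight,
   classified at the 90/95/99% two-sided normal thresholds into hot and cold
   spots of NFC change.

Because multi-period forest and road maps are rarely redistributable, the
package ships a **synthetic island generator** (`synthetic_scenario()`,
`simulate_scenario()`) producing terrain, productivity, a two-class road
network that grows over four periods (the secondary network saturates after
the second period), and per-cell NFC from a known inverse-logit truth — so
the whole pipeline is reproducible and testable without any external data.

## Worked example

```r
library(forestscape)

# a reduced island keeps the example quick; defaults give the study-scale run
cfg <- pipeline_config(
  seed = 42,
  scenario = list(island_radius_km = 40, n_towns = 10, relief_max_m = 750,
                  road_growth = list(main = c(120, 130, 50, 200),
                                     secondary = c(270, 270, 0, 0))),
  backends = c("linear", "forest"),
  cv_folds = 5)
res <- run_pipeline(cfg, out_dir = "forestscape_out")
print(res)
#> <forestscape pipeline result>
#>   retained cells: 204
#>   winner backend: forest
#>   period-mean reconstructed NFC:
#>  1950s  1970s  1990s  2010s
#> 0.3294 0.3026 0.2989 0.2937
res$comparison$table
#>   backend      nmse n_folds_failed
#> 1  linear 0.1334598              0
#> 2  forest 0.1323549              0
res$nfc_vs_rate
#> slope 0.02109, adj R2 9.49%, F 22.3, p 4.37e-06, n 204
```

Reading the output: 204 grid cells pass the half-land filter; the random
forest attains the lowest cross-validated NMSE and is used to reconstruct
NFC in all four periods; the reconstructed period means decline
monotonically (forest loss as roads grow); and the positive NFC-vs-rate
slope says cells that start with *less* forest lose forest *faster* — the
spatial signature of road-driven deforestation concentrating in already
settled lowlands. `res$indicator_power` tabulates the adjusted R² of each
road indicator's change per period pair (main-road length change is the
strongest correlate), `res$partitions` splits the combined explained
variance into main-road, secondary-road and shared components, and
`res$hotspots` maps Gi\* hot/cold clusters of NFC change per period pair.

`run_pipeline(cfg, out_dir = ...)` writes the full bundle: grid and roads
GeoJSON, elevation/slope/productivity as ASCII grids, the cell table,
NMSE comparison, hindcast, indicator-power and variation-partition CSVs,
per-pair hot-spot GeoJSON/CSV layers, and a JSON manifest with the seed and
config fingerprint. A thin CLI wrapper is installed at
`inst/scripts/forestscape.R`:

```sh
Rscript inst/scripts/forestscape.R run --config config.yaml --out outdir
```

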