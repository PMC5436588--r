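---
title: "Methods: grid-based natural-forest-cover change analysis"
author: "forestscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based natural-forest-cover change analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
the package, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open choices were resolved.

## The analysis problem

A tropical island's natural forest cover (NFC) — the fraction of each
5 × 5 km grid cell covered by arboreal forest, shrub land and open woodland
— declines over several decades while the road network densifies. Forest
maps exist only for some periods; road maps exist for all. The analysis
(i) summarises forest and roads per grid cell, (ii) fits NFC against
topography, climatic potential productivity and road-network indicators,
(iii) reconstructs NFC for unmapped periods from period-specific road
metrics, and (iv) characterises the change pattern: per-cell change rates,
the explanatory power of each road indicator, main-vs-secondary road
variation partitioning, and Gi\* hot/cold spots of change.

Two standing assumptions: topography (ELE, SLO) and climatic productivity
(CPP) are treated as constant over the study horizon, so only road metrics
vary between periods on a given cell; and the cell, not the forest patch,
is the unit of analysis.

## Gridding conventions

* **Land filter.** Cells with `land_fraction >= 0.5` are retained. The
  boundary is closed from below: a cell with exactly half its area on land
  stays in ("less than 50% excluded" excludes only strictly-less cells).
* **Origin.** The lattice is anchored at the land-mask bounding-box
  lower-left corner snapped down to a multiple of the cell size, and the
  origin is recorded in the grid's attributes, so the lattice is a pure
  function of the mask.
* **Half-open assignment.** Pixels (for raster averaging) and planar nodes
  (for NON/MND) belong to the cell whose half-open extent
  `[x0, x1) x [y0, y1)` contains them — each point counts in exactly one
  cell.
* **Exact overlay.** With polygon forest input, NFC is computed by exact
  rectangle clipping (Sutherland–Hodgman) and the shoelace formula, not by
  rasterised approximation; binary forest rasters are overlaid by pixel
  counting, exact up to one pixel-area quantum.
* **Units.** All geometry lives in a local planar frame in kilometres —
  every reported unit (SRL in km km⁻², DNR in km, 5-km cells) is km-based,
  so no unit conversions appear anywhere in the code.

## Road indicators

The network of each class and period is planarized: pairwise segment
crossings become shared vertices, coincident endpoints are merged (snap
tolerance 10⁻⁶ km), and degree-2 pass-through vertices are dissolved. The
*node* set is junctions (degree ≥ 3) plus terminals (degree 1) — the
standard planar simplification, and the one that makes mean node degree
meaningful. Consequences worth knowing:

* NON is **not** monotone under network growth: a terminal that gains a
  second incident edge becomes a pass-through vertex and dissolves. SRL is
  monotone non-decreasing and DNR monotone non-increasing as segments are
  added; those two invariants are tested.
* MND is reported **per unit cell area** by default (`mnd_per_area = TRUE`),
  matching the convention in which the indicator is printed in
  "ea km⁻²"-style units; plain mean degree is one switch away.
* DNR is network-wide (nearest segment of the class anywhere, not only
  inside the cell). A class with no segments at all yields a missing DNR,
  imputed at model time with 1.5 × the maximum observed DNR of that class
  plus a missingness indicator column — "no road anywhere" is informatively
  far, and an explicit indicator beats a silent magic number.
* Exact duplicate segments (digitisation artifacts) are removed before
  planarization; zero-length segments are dropped with a warning.

## Models and NMSE

Four backends sit behind one interface: `linear` (OLS), `additive`
(`mgcv::gam` with small thin-plate smoothers, k = 5), `neural`
(`nnet`, one hidden layer of 8 units, decay 10⁻³, scaled inputs) and
`forest` (`randomForest`, 500 trees, `mtry = floor(p/3)`, node size 5 —
conventional regression-forest defaults). The additive and neural backends
are deliberately thin: they exist as comparators, not products. One model
is trained on the pooled (cell, period) rows of the observed periods,
without a period feature; predictions are clipped to [0, 1].

**NMSE** is defined as mean squared error divided by the *population*
variance of the observations: 0 for perfect prediction, exactly 1 for the
global-mean predictor. Values above 1 (worse than the mean) are possible;
the useful range is [0, 1]. Backends are compared by pooled out-of-fold
NMSE under 10-fold cross-validation with **fold assignment by cell** — all
periods of a cell share a fold, so a backend can never score by memorising
a cell seen in another period.

The winner reconstructs ("hindcasts") NFC for every period from that
period's road metrics and the static covariates. On the default synthetic
scenario the single-hidden-layer neural backend can edge out the random
forest: the synthetic truth is an additive-logistic surface with one smooth
interaction, which is a sigmoid network's ideal target. Real forest-cover
data are rougher, which is where tree ensembles earn their reputation; the
comparison harness, not any fixed winner, is the contract.

## Change analysis

* **Change rate** is ΔNFC per decade: `(NFC(t2) − NFC(t1)) / ((y2 − y1)/10)`.
  Raw ΔNFC and relative ΔNFC/NFC(t1) variants are available (`rate =`);
  the relative variant drops cells with zero initial NFC.
* **Explanatory power** of an indicator is the adjusted R² (reported in
  percent) of the simple linear regression of the change rate on the
  indicator's change, with the two-sided F-test p-value; no
  multiple-testing correction is applied. Indicators whose change is
  constant in a pair (e.g. the saturated secondary network in later
  periods) are skipped with a log message.
* **Variation partitioning** fits three multiple regressions (4 main
  indicator changes; 4 secondary; all 8) and decomposes by the standard
  adjusted-R² algebra: `unique_main = combined − secondary`,
  `unique_secondary = combined − main`, `shared = main + secondary −
  combined`; the three components sum to the combined value by identity.
  A group whose predictors are all constant contributes an intercept-only
  model with adjusted R² = 0, which keeps the identity exact instead of
  propagating NA.
* **NFC-vs-rate slope** regresses the change rate on initial NFC. A
  positive slope — cells with less forest losing forest faster — appears
  when road growth concentrates in the already-settled, low-NFC lowlands
  while steep, high-NFC cells are shielded. Note the mechanics: with a
  bounded response, absolute change saturates near NFC = 0, so the
  qualitative finding depends on the generator (or the landscape) actually
  coupling road growth to low-NFC cells, as the default scenario does.

## Getis–Ord Gi\*

For values x over n cells with weights w (binary, self-weight included):

z_i = (Σ_j w_ij x_j − X̄ Σ_j w_ij) / ( S·√[(n Σ_j w_ij² − (Σ_j w_ij)²)/(n−1)] ),
S = √(Σ_j x_j²/n − X̄²).

The statistic is already a z-score; cells are classified at ±1.645, ±1.960,
±2.576 (90/95/99%, two-sided). Conventions:

* Default weights: queen contiguity with self-weight 1. Rook and
  centroid-distance-band schemes are available, and the scheme is recorded
  in the output metadata, because published hot-spot maps rarely document
  it and the classification can change with it.
* A constant field makes S = 0; the result is an explicit *undefined* flag
  on every cell, never a silent 0/0.
* Distance-band cells with no neighbour keep a self-only weight row and a
  warning.
* Exact invariances (tested): translation invariance, z(ax) = sign(a)·z(x),
  and antisymmetry under sign flip. In a change field, *negative* z marks
  clusters of NFC decrease (deforestation cold/hot spots depending on the
  map's framing); the package labels negative clusters `cold*`.

## The synthetic island

`synthetic_scenario()` defines, and `simulate_scenario()` realises, the
study conditions:

* **Island and terrain.** A star-shaped coastline (low-order cosine
  harmonics on a 100-km radius, ≈31,000 km², ≈1,260 retained cells), a
  central mountain dome (peak 1,800 m) plus Gaussian-smoothed noise at
  0.5-km resolution; slope by finite differences; productivity declining
  with elevation plus a smooth regional gradient.
* **Roads.** Towns (default 24) sit mostly on the coastal lowlands; main
  roads connect them (minimum spanning tree, then near-neighbour and
  distance-decayed densification links rendered as ≈4-km jittered
  segments), secondary roads branch off the contemporaneous network. Counts
  per period are chosen so mean main-road SRL grows ≈0.10 → 0.45 km km⁻²
  across the four periods while the secondary network saturates after
  period 2 (≈0.17 → 0.34, then flat) — the temporal signature of a main
  network that keeps growing and a rural network that was essentially
  complete early.
* **NFC truth.** Inverse-logit of a linear predictor over standardised
  covariates (fixed reference scales: ELE/300 m, SLO/4°, (CPP−8000)/2000,
  SRL raw, DNR/10 km) plus a *positive* SRL×slope interaction implementing
  the accessibility argument: steep cells are shielded from road-driven
  clearing. I.i.d. Gaussian noise (SD 0.05) is added and clipped to [0,1];
  clipping beyond 5% of values raises a warning. The default coefficients
  were fixed once, by construction, so that the period-mean NFC declines
  from ≈0.41 and road growth concentrates in low-NFC cells (producing the
  positive NFC-vs-rate slope); they are not fitted to anything downstream.
* **Forest masks.** Per-cell NFC is rasterised at 100-m pixels (2,500 per
  cell; quantum 4 × 10⁻⁴) by marking the `round(NFC × 2500)` most suitable
  pixels as forest, suitability being elevation plus fine noise shared
  across periods — forest loss is therefore spatially nested over time, and
  the polygon/pixel overlay recovers the true NFC to within half a quantum.
* **Determinism.** Every stage draws from a seed derived from the scenario
  seed by fixed offsets; identical seeds give bit-identical outputs, which
  the pipeline's manifest (seed + config hash) makes reproducible.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: spatial autocorrelation in the NFC noise (noise
is i.i.d. by design, keeping recovery tests interpretable), reforestation
(the truth is monotone declining; real mountains can regrow after logging
bans), digitisation-scale artefacts in road geometry (real networks are far
more vertex-dense, so absolute NON/MND magnitudes differ), cloud/sensor
error in forest maps, and any socio-economic dynamics of road placement
beyond "near towns and existing roads".

## Problem sizes and numerical choices

The default scenario (≈1,260 cells × 4 periods) runs the full pipeline in
about two minutes on one core; the unit-test fixtures use a 30-km island
(≈120 cells) so the suite stays fast. Cross-validation uses 10 folds at
study scale and fewer in the small fixtures. Geometric tolerances: segment
snapping 10⁻⁶ km; split-parameter rounding 10⁻¹²; conservation checks at
10⁻⁶ of a cell area. Collinear regression columns are dropped with a
warning (`lm`'s NA coefficients are detected); degenerate predictors raise
errors rather than silently returning zero-variance fits. Rasters are
written as plain-text ESRI ASCII grids and vectors as GeoJSON in the local
km frame, formats chosen so every artefact in a run bundle is
human-readable and diffable.

## Known limitations

* The cross-sectional NFC-vs-rate regression is one of two readings of a
  "site-specific NFC/change-rate relationship"; the per-cell temporal
  variant can be assembled from `change_table()` output but is not built
  in.
* Gi\* p-values are pointwise; no false-discovery-rate control is applied
  to the hot-spot maps, matching common GIS practice but inviting caution
  at cell-level interpretation.
* The hindcast carries no uncertainty interval; the NMSE comparison ranks
  backends but does not propagate model error into change statistics.
* Exact reproduction of any published cell-level map would additionally
  require the original projection, grid origin and weighting scheme, which
  published analyses rarely document; the package records all three in its
  own outputs.
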