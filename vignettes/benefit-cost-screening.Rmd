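---
title: "Screening road development: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening road development: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadscape)
```

## The problem

Road building is often justified by its potential to raise agricultural
output: better access lowers input and transport costs and cuts
post-harvest waste, which matters most where farms are isolated and
yields fall well short of what the local climate allows. The same roads,
however, open remaining natural habitat to conversion, with losses to
biodiversity, carbon storage, and the local climate regulation that
intact vegetation provides. `roadscape` implements a screening framework
that makes this trade-off spatially explicit on a raster landscape: one
aggregate surface for the potential food-production benefit of improved
access, one for the potential environmental cost of the habitat
conversion roads tend to trigger, and machinery to intersect the two,
probe their robustness, and grade individual road proposals.

The framework is a screening tool, not an impact assessment: it ranks
where finer-scale study is most worthwhile, and its outputs are
relative (decile) scores, not absolute predictions.

## Equal-area decile rescaling

Every layer that enters a product or an average is first mapped to
[0, 1] by the empirical rank transform `(rank - 0.5) / n` over the data
cells, with midranks for ties. Each tenth of the cells then occupies one
decile interval, so no layer's units or outliers can dominate a
combination. Three consequences are worth noting:

* the transform is invariant under any strictly increasing change of
  units (minutes vs hours, t vs kt);
* an all-constant layer maps to 0.5 everywhere (one big tie group) —
  documented behaviour, not an error;
* tie groups are kept together (midrank), so equal inputs always get
  equal scores; decile bins then deviate from exact equal counts only by
  the size of a tie group spanning a boundary.

Cells are treated as the unit of account. At the default 0.0833° cell
size, true cell area varies with latitude by only a few percent across a
subregional study area, and prioritisation maps conventionally bin by
cell count; we therefore do not area-weight ranks.

A degenerate case follows from rescale-then-multiply: if the production
gap is zero everywhere, its factor collapses to the constant 0.5 and the
benefit aggregate ranks by travel time alone. This is the faithful
consequence of the pipeline's order of operations (factors are rescaled
*before* multiplication), and the test suite pins it down.

## The benefit surface

For each crop `c`, the closable production gap of a cell is
`yield_gap_c (t/ha/y) x harvested_area_c (ha) x energy_c (GJ/t)`, summed
over crops — the extra food energy attainable *without* cropland
expansion, weighted by each crop's current areal importance. Cells with
no cropland get 0, not NoData: they genuinely have nothing to close, and
they should occupy the lowest ranks rather than disappear from the map.
The aggregate benefit is
`rescale( rescale(production_gap) x rescale(travel_time) )`:
isolated cells with large gaps score highest. The final rescale is the
default (`final_rescale = TRUE`) so the aggregate is itself a decile
surface; the raw product is available for users who prefer the
unrescaled overlay.

The population-based variant substitutes population density for the
production gap and measures how many people might benefit from access
rather than how much food could be grown.

## The cost surface

Three component layers, each 0-1 rescaled, then combined:

1. **Terrestrial vertebrates.** Per class (mammals, birds, amphibians),
   each cell sums `cell_area / global_range_area` over the species whose
   range intersects the cell, times the proportion of the cell still
   under natural vegetation; class totals are rescaled and averaged.
   Small-ranged species dominate, as they should in an irreplaceability
   measure. Presence is *any* overlap between range polygon and cell
   square — presence/absence, not fractional, matching how range
   intersections are conventionally computed at this resolution.
2. **Carbon.** Net loss on conversion = all biomass carbon minus a 10%
   *gain* in the top-30 cm soil stock (paddy management raises soil
   carbon), floored at zero: a soil-rich, biomass-poor cell would
   otherwise register a negative "cost", which the framework has no
   interpretation for. The per-ha loss is multiplied by natural cover
   and cell area before rescaling.
3. **Local climate regulation.** Per-ecoregion heat (°C) and moisture
   (mm/d) regulation indices are assigned to cells, each index rescaled,
   weighted by natural cover, and averaged; the mean is rescaled once
   more so the component enters the aggregate on the decile scale (the
   global rescale-before-combining rule; the alternative — not rescaling
   the mean — changes only the marginal distribution, not the ranking
   logic).

The aggregate is the per-cell mean (default) or, as a sensitivity
variant, the per-cell maximum, rescaled again.

## Intersection, sensitivity, roads

The bivariate classification bins both 0-1 surfaces into `n_bins`
(default 10) classes — `floor(v x n_bins)` with 1.0 clamped into the top
bin — and summarises four quadrants at the 0.5 midpoint. The 0.5 split
is a convenience over a continuous gradient; outputs flag it as such.

Each sensitivity substitution (alternative yield-gap data, max cost
rule, population benefit) changes exactly one aggregate, so its effect
is the per-cell difference `new - original`, bounded in [-1, 1]. The
headline statistic is the fraction of cells with `|delta|` *strictly*
greater than the threshold (default 0.2); strictness is immaterial for
continuous surfaces and pinned down by a test.

Existing-road density is total clipped road length (km) over cell area
(km²) for road levels 1-3; level 4 (tracks and footpaths) is excluded
everywhere by default as unusable by vehicles. Road buffers use
cell-centre distance to the polyline at a default half-width of 10 km —
deliberately equal to the analysis resolution — and summaries are
unweighted cell means (cell-area weights would change buffer means by
well under the noise level at subregional latitude spans). Along-route
profiles list cells in traversal order, one entry per cell at first
entry.

## Geometry and numerical choices

* All spherical computation (cell areas, polyline lengths) uses a
  sphere of radius 6371.0088 km; cell area is the exact band formula
  `R² Δλ (sin φ_top − sin φ_bot)`. Tests check it against an
  independent WGS84 ellipsoid computation (agreement well within 0.5%).
* Segments and polygon edges are straight in lon/lat; segment-to-cell
  attribution splits each segment exactly at the grid lines it crosses,
  so per-cell road lengths are exact under that model (verified against
  an independent per-cell parametric clipping oracle to 1e-6 relative).
* Point-to-segment distances use a tangent-plane approximation anchored
  at the segment; at buffer scales (~10 km) this agrees with geodesic
  distances to well under 1%.
* NoData propagates; it is never imputed. Water/out-of-region cells are
  NoData in every surface; rescaling, means, and changed fractions use
  data cells only.
* Rasters are exchanged as plain-text ESRI ASCII grids written with 17
  significant digits, so round trips are exact; vectors as GeoJSON;
  manifests as YAML.

## The synthetic landscape generator

`generate_landscape()` produces complete input bundles with the
statistical structure the screening assumes, so the entire pipeline is
testable without external GIS data:

* **travel time** = spherical distance to the nearest of `n_cities`
  cities at `travel_speed_kmh` (default 40 km/h), with mild
  multiplicative noise;
* **natural cover** = logistic in travel time (low near cities) with
  steepness `conversion_steepness` (default 0.05 per minute, i.e. the
  conversion frontier spans roughly 80 minutes of travel) *plus* a
  spatially smoothed noise field with standard deviation `noise_sd`
  (default 0.15) representing conversion variance that access does not
  explain (soils, terrain, settlement history), clipped to [0, 1];
* **crops**: harvested area only on the converted fraction of each cell
  (90% of it, split among crops by fixed shares), yield gaps linear in
  travel time with slope `yieldgap_isolation_slope` (default
  0.004 t/ha/y per minute) plus noise — the slope is recoverable by
  regression, which the tests exploit; an independently drawn
  alternative crop set (fewer crops, 0.7x slope, a smoothed lognormal
  disagreement field) stands in for a second yield-gap database;
* **carbon stocks** increase with natural cover; **population** decays
  from cities; **ecoregions** are a nearest-seed (Voronoi) partition
  with per-ecoregion heat/moisture indices; **species ranges** are
  ellipses with log-uniform areas over 100-50,000 km² centred
  preferentially on high-cover cells; **roads** connect city pairs,
  and **proposals** run from converted to intact regions.

The construction embeds the empirical signature of heavily converted,
biodiverse regions: production-dependent benefit needs cropland
(converted, accessible cells) while every cost layer scales with
natural cover (intact, remote cells). The benefit and cost aggregates
on default landscapes are therefore negatively correlated in space.
The strength of that association is governed by the cover variance
*independent* of travel time: if cover were an exact function of travel
time, the rank algebra of the benefit product makes the correlation
cancel to ~0. The default `noise_sd` supplies that independent
component at a realistic level, and the association holds across seeds
(checked over 20 replicates in the tests).

What the generator does **not** emulate: real yield-gap magnitudes or
crop mixes, commission/omission errors of range maps, plantation
removal from cover estimates, terrain- or river-following road
geometry, and any calibration to a particular subregion. Tests passing
on synthetic data therefore validate the *machinery* — rescaling,
accounting, intersection, zonal statistics — not the realism of any
particular input layer.

One master seed feeds independent named sub-streams (mask, cities,
cover, crops, ranges, roads, ...), so adding a generator stage never
perturbs the draws of another, and every bundle is reproducible bit for
bit from `params`.

## Problem sizes

The test suite runs oracle comparisons on 50 x 50 grids (20 random
instances per operation), structural-recovery checks on the default
100 x 100 landscape over 20 seeds, and everything else on 10-30 cell
grids; the whole suite completes in well under five minutes on one CPU.
These sizes were chosen as the smallest at which each property is
sharply testable (e.g. 10,000 cells make decile counts exact at 1,000
per bin).

## Worked example

```{r example, eval = FALSE}
params <- landscape_params(seed = 1)
run <- run_pipeline(pipeline_config(params = params))
summary(run)
plot(run)

# one proposal in detail
subset(run$road_summaries, road_id == "P01")
head(subset(run$road_profiles, road_id == "P01"))
```

## Known limitations

* Quadrants use a fixed 0.5 split of decile scores; published verbal
  categories of benefit-cost overlays have no numeric definition, and we
  make no claim of reproducing them.
* Species presence is binary per cell; a fractional-overlap option is a
  natural extension but changes raw scores only at range boundaries.
* The framework omits, by design, freshwater biodiversity,
  invertebrates and plants, hunting/erosion/connectivity effects, and
  any absolute (rather than relative) valuation — all reasons its
  outputs should direct scrutiny, not decide it.
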