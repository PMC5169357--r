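# roadscape

Spatially explicit screening of road-development plans: where could new
or improved roads raise food production a lot at limited environmental
cost, and where would they do little for agriculture while putting
biodiversity, carbon stocks, and local climate regulation at risk?

The package is aimed at conservation scientists and infrastructure
planners working at subregional scales (grids of ~10 km cells), where
road corridors are actually proposed and compared. It works either from
real GIS layers (plain-text ASCII grid rasters, GeoJSON vectors) or
from a built-in synthetic landscape generator, so every stage is
testable end to end without external data.

## The framework

All layers are put on a common 0–1 scale by **equal-area decile
rescaling** — the rank transform `(rank − ½)/n` with midranks for ties —
before any multiplication or averaging, so no layer's units or outliers
dominate.

**Potential benefit.** Per cell, the closable production gap is

> G = Σ_c  yieldgap_c (t/ha/y) × area_c (ha) × energy_c (GJ/t)

summed over crops `c` — extra food energy attainable without cropland
expansion. The aggregate benefit is
`rescale( rescale(G) × rescale(traveltime) )`,
so isolated cells with large gaps rank highest. A population-based
variant replaces `G` with population density.

**Potential cost.** The mean (or, in sensitivity mode, the maximum) of
three 0–1 layers, rescaled again:

1. *Vertebrates*: per class (mammal/bird/amphibian),
   Σ over species present of `cellarea / rangearea`, × proportion of
   natural cover; classes rescaled and averaged;
2. *Carbon*: `max(biomass − 0.10 × soil30, 0)` t/ha × cover × cell
   area (all biomass carbon lost, 10% soil-carbon gain under paddy
   conversion);
3. *Climate regulation*: per-ecoregion heat (°C) and moisture (mm/d)
   regulation indices, rescaled, × cover, averaged.

**Intersection and roads.** The two aggregates are jointly binned
(default 10 × 10) with a four-quadrant summary at 0.5; sensitivity
substitutions are reported as difference maps in [−1, 1] and the
fraction of cells changed by more than a threshold (default 0.2); road
proposals get unweighted buffer-zone means (default 10 km half-width)
of benefit, cost, travel time, population, and existing-road density
(levels 1–3, km/km²), plus along-route cell profiles.

## Worked example

```r
library(roadscape)
params <- landscape_params(seed = 1)        # default 100 x 100 landscape
run <- run_pipeline(pipeline_config(params = params))
summary(run)
```

```
Benefit-cost screening summary
------------------------------
Total closable production gap: 6.335e+08 GJ/y over 9972 cells

Quadrant shares (0.5 split of the 0-1 scales):
  high-benefit/low-cost        2699 (27.1%)
  low-benefit/low-cost         2287 (22.9%)
  low-benefit/high-cost        2699 (27.1%)
  high-benefit/high-cost       2287 (22.9%)

Cells changed by >|0.2| under each substitution:
  alt_yieldgap           6.6%
  max_cost_rule          2.6%
  population_benefit     40.7%

Road proposals assessed: 8 (buffer 10 km)
  lowest mean cost: P08, P06, P01
```

The surplus of the two "off-diagonal" quadrants (high-benefit/low-cost
and low-benefit/high-cost, 27.1% each, vs 22.9% for the diagonal ones)
is the spatial trade-off the screening looks for: converted, accessible
land with closable yield gaps is largely *not* the land that still
carries high environmental value, so benefit and cost are negatively
associated (Pearson r = −0.048 on this landscape; `print(run)` reports
it). Per-proposal lines give the buffer means used to compare schemes:

```r
subset(run$road_summaries, road_id == "P01")
#   road_id n_buffer_cells mean_benefit mean_cost mean_travel_time
#       P01            113         0.53     0.496              283
#   mean_population mean_road_density
#              4.24                 0
```

`plot(run)` draws the benefit, cost, and quadrant maps. A command-line
wrapper with subcommands (`simulate`, `benefit`, `cost`, `intersect`,
`sensitivity`, `roads`, `run`) is installed at
`system.file("cli/roadscape.R", package = "roadscape")`.

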