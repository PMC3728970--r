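# corridorcast

Least-cost connectivity modelling over categorical land-cover rasters, and
validation of the model predictions against GPS telemetry. The package is
aimed at movement ecologists and conservation planners who need to predict
where an animal — the motivating case is the gray squirrel moving through
fragmented British farmland — will cross the landscape matrix between
habitat patches, and to test those predictions against collar data.

## What it computes

Movement cost follows the standard cost-distance contract: each land-cover
category has a resistance r ≥ 1 (habitat woodland = 1, improved/arable
matrix = 40, up to buildings/rock = 1000; the full table ships with the
package), and moving d metres through it accumulates r × d *cost units*.
On the 8-connected raster graph a step between cells a, b costs
((r_a + r_b)/2) × d, with d the cell size (rook) or √2 × cell size
(diagonal). From multi-source Dijkstra accumulated-cost surfaces the
package builds three connectivity models as binary masks:

- **LCN** (least-cost network): habitat plus all cells within a
  dispersal-derived cost threshold (8 km → 8000 cost units);
- **LCP** (buffered least-cost paths): pairwise cheapest routes between
  visited patches, buffered 40 m either side;
- **LCC** (least-cost corridor): per pair, the cells where
  cost_A(x) + cost_B(x) is within 1600 cost units (= 40 m at matrix
  resistance 40) of the optimal path cost.

The telemetry side segments 3-minute GPS fix series into dwell clusters
and inter-patch movements, measures land-cover and linear-feature use, and
scores each model with the ratio

    statistic = (% of the fixes' convex polygon covered by the mask)
              / (% of movement fixes inside the mask)

where lower is better. A hinge (breakpoint) regression of
distance-to-feature on distance-to-habitat locates the distance at which
animals re-orientate toward linear features. A synthetic-landscape and
biased-random-walk simulator generates reproducible end-to-end test data.

## Worked example

```r
library(corridorcast)

cfg <- run_config(output_dir = "run1", seed = 1, n_animals = 3,
                  duration_h = 24)
rep <- run_pipeline(cfg)
#> [corridorcast] stage landscape
#> [corridorcast] stage simulate: 3 track(s)
#> [corridorcast] stage movement
#> [corridorcast] stage connectivity
#> [corridorcast] stage validation
#> [corridorcast] stage outputs

rep$comparison$LCN
#> <comparison_result> LCN: area 100%, points 100%, statistic 1.00
rep$comparison$LCP
#> <comparison_result> LCP: area 38.38%, points 47.8%, statistic 0.80
rep$comparison$LCC
#> <comparison_result> LCC: area 71.51%, points 88.19%, statistic 0.81

head(rep$movements[, c("animal_id", "n_locations", "expected_locations",
                       "euclidean_km", "path_km", "duration_min",
                       "success_pct")], 3)
#>   animal_id n_locations expected_locations euclidean_km   path_km duration_min success_pct
#> 1      sim1           9                  8   0.39178327 0.4076718           24   100.00000
#> 2      sim1           6                  7   0.03764748 0.3296337           21    85.71429
#> 3      sim1           3                  2   0.01429750 0.1088850            6   100.00000
```

The comparison statistics say: the network model covers essentially the
whole polygon for its points (ratio ≈ 1), while the focused path and
corridor models capture movement fixes out of proportion to the area they
occupy (ratio ≈ 0.8) — the focused models predict movements better per
unit area. Every movement's along-track length
exceeds its straight-line length: the simulated squirrels, like real ones,
detour along field edges, verges and the river corridor rather than
crossing open ground.

A thin CLI over the same pipeline lives at `inst/scripts/corridorcast.R`
(subcommands `simulate | network | paths | corridor | movements | validate
| all`).

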