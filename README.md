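# karstprior

Grid-based conservation prioritization of karst caves from invertebrate
survey data.

Karst regions concentrate exceptional subterranean biodiversity — including
troglobionts, species restricted to caves with no viable surface
populations — while facing intense pressure from limestone mining,
agriculture and urbanization. When thousands of caves compete for limited
protection, managers need a transparent, repeatable way to decide *which
places* matter most. `karstprior` implements a map-algebra prioritization
for exactly that audience: speleobiologists, conservation planners and
environmental consultants working with cave inventories and species
occurrence tables.

## The method

Every cave *c* is rated on four criteria:

| criterion | definition |
|---|---|
| nTS | non-troglobite species richness of the cave |
| TbS | troglobite (subterranean-restricted) species richness |
| EnD | stenoendemic count — troglobites known **only** from this cave |
| VuL | number of distinct anthropogenic impact types (pasture, agriculture/forestry, mining, urbanization, paved road) with a site within 250 m of the cave |

Each criterion is mapped to a category Low / Average / High / Extreme with
weights w = (100, 250, 500, 1000). nTS uses data-driven equal-interval bins
over the observed range `[min, max]` (upper bound of class i is
`floor(min + i·(max−min)/4)`); TbS, EnD and VuL use fixed integer bins
(e.g. TbS ≥ 7 → Extreme; VuL ∈ {4,5} → Extreme).

The study extent is tiled by an `ncols × nrows` grid (default 40 × 30 = 1200
cells of 1 km²). For each occupied cell *g* and each attribute *a*, the cell
layer takes the **maximum** score among the caves it contains, and the
layers are summed (map algebra) into a composite conservation value

    PiC(g) = Σ_a  max_{c ∈ g} score_a(c)   ∈ [0, 4000]

Occupied cells are then classified into priority tiers (low / medium / high /
extreme) with an exact Fisher–Jenks natural-breaks algorithm: the contiguous
partition of the sorted PiC values minimizing the total within-class sum of
squared deviations, computed by dynamic programming with a deterministic
lexicographic tie-break.

Survey completeness of the troglobiont assemblage is estimated with the
first-order jackknife, `S_jack1 = S_obs + Q1·(n−1)/n`, where `Q1` is the
number of species found in a single cave and `n` the number of caves
surveyed; completeness is `S_obs / S_jack1`.

A seeded generator (`simulate_karst()`) produces complete synthetic
landscapes — clustered caves, species occurrences with planted stenoendemics,
typed impact sites — together with a ground-truth record, so the whole
pipeline is testable without access to any field dataset.

## Worked example

```r
library(karstprior)

sim <- simulate_karst(karst_sim_params(), seed = 42)   # 105 synthetic caves
fit <- prioritize(sim$caves, sim$occurrences, sim$impacts)
fit
#> Cave conservation prioritization
#>   105 caves on a 40 x 30 grid; 84 occupied cells
#>   priority classes: low=28, medium=23, high=20, extreme=13
#>   troglobiont completeness: 32 observed / 52.8 estimated = 60.6%

summary(fit)
#> Caves: 105; grid cells: 1200; occupied cells: 84
#> nTS categories: None=0, Low=23, Average=35, High=34, Extreme=13
#> TbS categories: None=59, Low=40, Average=5, High=1, Extreme=0
#> EnD categories: None=0, Low=85, Average=19, High=1, Extreme=0
#> VuL categories: None=0, Low=46, Average=47, High=11, Extreme=1
#> Priority classes: low=28 (33%), medium=23 (27%), high=20 (24%), extreme=13 (15%)
#> Troglobiont completeness: S_obs=32, Q1=21, n=105, S_jack1=52.8 (60.6%)

plot(fit)                                   # priority map of the grid
export_priority(fit, "priority.geojson", "cells.csv")
```

Reading the output: 105 caves fall in 84 of the 1200 grid cells; the
natural-breaks classifier puts 13 of those cells in the *extreme* tier —
the candidate priority areas. The jackknife says the 32 troglobiont species
observed represent about 61% of the richness the survey pattern implies
(21 of the 32 species are known from a single cave, so substantial
undetected richness is expected).

To run on real data, prepare `caves.csv` (`cave_id,name,x,y,length_m,season`,
planar meters), `occurrences.csv` (`cave_id,species_id,troglobiont`) and
`impacts.csv` (`impact_type,x,y`), then:

```r
run_pipeline(caves = "caves.csv", occurrences = "occurrences.csv",
             impacts = "impacts.csv", config = study_config(),
             out_dir = "out")   # attributes/scores/cells CSVs + GeoJSON + report
```

A command-line wrapper with `simulate`, `run` and `classify` subcommands is
installed at `inst/cli/karstprior.R`.

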