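# lapmd

Assessing how a land-use plan will change a city's air quality, before it
is implemented, is a standard task in strategic environmental assessment.
`lapmd` implements a complete desk-scale workflow for it, aimed at
planners and environmental modellers working at the city/county scale
with coarse (hundreds of metres) raster data:

1. **Land-use-based emission inventory.** Annual SO₂ and PM₁₀ emissions
   are tabulated per land-use source category (key industrial plots,
   urban and rural residential land, agricultural land, transportation
   land) rather than per industry. SO₂ from fossil-fuel combustion uses
   the sulfur mass balance

   *E* = (M_SO₂/M_S) · S · ω · ε · (1 − η) · 10³ kg,

   with sulfur content *S*, fuel consumption ω (ton/yr), sulfur
   conversion rate ε and desulfurization rate η. Everything else uses
   emission factors: area sources as activity × EF (kg/ton), vehicles as
   *E* = Σⱼ Pⱼ · Mⱼ · EFⱼ · 10⁻³ kg with fleet size *P*, annual mileage
   *M* (km) and EF in g/km per vehicle.

2. **Rasterization.** Each category's emission is divided evenly over its
   raster cells (key plots may instead be placed cell-by-cell), giving a
   per-cell source intensity *Q* plus source height ΔH and ground
   elevation *H* layers.

3. **Long-term multi-source dispersion.** An annual-average, eight-sector
   Gaussian model: each source's *Q* is split across the 45° wind sectors
   by the wind-rose frequencies and smeared uniformly over the sector
   arc,

   c(x) = [Q_s / (2π ū σ_y σ_z)] · exp(−h²/2σ_z²) / (π x Δα/180) · T,

   with per-sector mean speed ū and Pasquill–Gifford power-law σ(x)
   driven by a stability class derived from daily cloud cover, solar
   elevation and wind speed. The field is the superposition over all
   source cells.

4. **Assessment.** Concentration fields are classified into pollution
   levels (bins anchored on the Chinese ambient air quality standard
   GB 3095-2012), overlaid with a planning map to tabulate affected area
   (hm²) per planning category, and compared between a reference and a
   target year.

A seeded synthetic *toy city* generator produces every input layer
(land-use raster, DEM, daily meteorology, inventory parameters, planning
map), so the full pipeline runs and is tested without any external data.

## Worked example

```r
library(lapmd)

# published per-source rows of a city inventory, shipped with the package
rows <- published_inventory_rows(2010)
inv  <- build_inventory(rows$sources, rows$fleet, year = 2010)
inventory_total(inv, "SO2", "point_area")
#> [1] 35135.45

# toy city end to end
city <- make_toy_city(toy_city_spec(seed = 42))
rose <- build_wind_rose(city$met, latitude = city$spec$latitude)
inv  <- build_inventory(city$params$sources, city$params$fleet)
sf   <- rasterize_emissions(inv, city$landuse, city$legend,
                            city$params$heights, city$dem, "SO2")
conc <- disperse(sf, rose)
cls  <- classify_field(conc, level_scheme("SO2"))
cls
#> <lapmd_classification> SO2, mean 4.8803e-06 mg/m^3
#>  level      label cells area_hm2 pct
#>      1     <0.005  1600    14400 100
#>      2 0.005-0.01     0        0   0
#>      3  0.01-0.02     0        0   0
#>      4  0.02-0.06     0        0   0
#>      5   0.06-0.1     0        0   0
#>      6       >0.1     0        0   0
```

The first number is the 2010 point+area SO₂ total in ton/yr, recomputed
from the per-source rows. The classification table reports, per pollution
level, the number of 300-m cells, their area in hectares (one cell =
9 hm²) and the share of the grid; the toy city's annual mean SO₂ of
~5 × 10⁻⁶ mg/m³ puts every cell below the cleanest-level edge of
0.005 mg/m³, as expected for a small town's emissions spread over a
12 × 12 km grid.

A command-line interface wraps the same steps:

```sh
Rscript inst/cli/lapmd.R fixtures --out toydata --seed 42
Rscript inst/cli/lapmd.R run-all --config toydata/run_config.json --out results_dir
```

`run-all` writes per-year inventory CSVs, concentration and level rasters
(ESRI ASCII grids), overlay and comparison tables, a wind-rose JSON, and
a `.prov.json` provenance sidecar for every artifact.

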