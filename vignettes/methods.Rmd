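---
title: "Methods: land-use emission inventories and long-term sector-averaged dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use emission inventories and long-term sector-averaged dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapmd)
```

## The problem

A land-use plan fixes, years ahead, where a city's industry, housing,
roads and farmland will sit. Because each of those land uses emits air
pollutants in a characteristic way, the plan largely determines the
future spatial pattern of SO₂ and PM₁₀ concentrations. `lapmd`
operationalizes a screening-level assessment of that pattern: an
emission inventory organized by land-use category, a climatological
(annual-average) dispersion model, and tabulations of the area exposed
at each concentration level under the current and the planned layout.
Everything targets the coarse scale at which plans are drawn — raster
cells of a few hundred metres over thousands of square kilometres — not
the plant-by-plant fidelity of a permitting study.

## Emission inventory

Two estimation methods cover all source categories.

**Sulfur mass balance** (SO₂ from fossil-fuel combustion — key
industrial plots and urban residential heating/cooking):

$$E = \frac{M_{SO_2}}{M_S}\, S\, \omega\, \varepsilon\, (1-\eta)\times
10^{3}\ \mathrm{kg/yr},$$

with the molecular-weight ratio $M_{SO_2}/M_S = 64/32 = 2$, sulfur mass
fraction $S$, fuel burned $\omega$ (ton/yr), the fraction $\varepsilon$
of fuel sulfur actually converted (default 0.8 for coal, 1.0 for oil)
and the desulfurization rate $\eta$ (default 0 for residential sources,
which have no controls; industrial plots carry their measured average).
Whether a plot-level or a category-average $\eta$ is used is up to the
input table; the package treats the supplied value as a category
average.

**Emission factors** (everything else): area sources as activity ×
EF, with activity in ton/yr of fuel or crop residue burned and EF in
kg/ton; vehicles as $E_i=\sum_j P_j M_j\,EF_{i,j}\times10^{-3}$ kg with
fleet size $P_j$, annual mileage $M_j$ (km/vehicle) and $EF_{i,j}$ in
g/km per vehicle. Published inventory tables sometimes label vehicle
factors "kg/ton"; the rate formula is only dimensionally consistent
with g/km·vehicle, which is what the package uses. The identity
$E_{PM_{10}}/E_{SO_2} = EF_{PM_{10}}/EF_{SO_2}$ per vehicle class is
unit-independent and is used as a cross-check in the tests.

Percentage shares are computed within each reporting group (point+area
sources vs. transportation) because the two are tabulated separately;
values are stored at full precision and rounded only for display or CSV
export. When re-aggregating the shipped published rows, the 2010
transportation PM₁₀ group sums to 8805.23 t where the printed total is
8805.24 t — a rounding slip in the source table; the package reports
the exact sum.

**Rasterization.** A category's emission is divided by its cell count
and assigned uniformly — including road (line) sources, which are
spread over transportation-land cells under the same rule, since no
per-road apportionment is available at planning scale. Key plots can
instead be placed as per-cell point sources with individual tonnages;
the tonnages must reproduce the category's inventoried total, which
keeps the conservation invariant $\sum_{cells} Q = \sum$ inventory
exact. When several categories emit in one cell the source height ΔH is
their emission-weighted mean.

## Meteorology

The wind rose uses eight 45° sectors centred on the principal compass
points. Intervals are $(\alpha_1, \alpha_2]$, so a direction exactly on
a boundary joins the lower-angle sector — an arbitrary but deterministic
tie-break. Directions are where the wind blows *from*; transport is
toward the opposite bearing. Days with speed below 0.5 m/s are treated
as calm, excluded from the rose and reported as a calm fraction.
Sector frequencies are data-driven (each sector's share of non-calm
days); an `equal_freq` toggle forces the uniform 1/8 rose for
sensitivity checks, since the uniform assumption is sometimes stated
alongside data-driven practice.

Each day gets a Pasquill stability class from wind speed, solar
elevation (noon value from date and latitude when not supplied) and
cloud cover, using the classic surface-observation table; split entries
resolve to the more unstable member and the rare night class G is
reported as F. Each sector's annual-representative class is the mode of
its days' classes — one σ-model per sector, matching the single-σ
long-term formulation.

Dispersion parameters are pure power laws $\sigma = a\,(x/1000)^b$
(x in metres). The defaults are the published mid-range power-law fits
to the Pasquill–Gifford curves: lateral $a_y$ = 213, 156, 104, 68,
50.5, 34 m for classes A–F with a common exponent 0.894, and vertical
$(a_z, b_z)$ = (440.8, 1.941), (106.6, 1.149), (61, 0.911),
(33.2, 0.725), (22.8, 0.678), (14.35, 0.740). The small additive
offsets of the published vertical fits are dropped to keep the pure
power-law form; the error is a few metres at most over the 0.1–10 km
range a city grid spans. The coefficient table is an ordinary data
frame argument, so an alternative set can be swapped in without
touching code.

## The dispersion model

For one source cell and one sector, the annual-mean near-ground
concentration at downwind distance $x$ is

$$c(x) = \frac{Q_s}{2\pi \bar u\, \sigma_y \sigma_z}
\exp\!\left(-\frac{h^2}{2\sigma_z^2}\right)
\bigg/ \frac{\pi x (\alpha_2-\alpha_1)}{180}\ \times T,$$

where $Q_s = Q f_s$ is the cell's emission allocated to sector $s$ by
the rose frequency, $\bar u$ the sector mean speed, and the divisor the
arc width of the sector at distance $x$ — the plume is smeared
uniformly across the sector, the standard climatological
approximation. $T$ is a pollutant-specific scalar attenuation
(deposition/decay lumped into one dimensionless factor; 1 by default).
Multiplying $c$ by the arc width recovers the crosswind-integrated flux
$Q_s/(2\pi\bar u\sigma_y\sigma_z)\exp(-h^2/2\sigma_z^2)\,T$ exactly;
`crosswind_integral_check()` exposes the identity. Note that with the
sector-uniform profile and $T \ne 1$ the field does not integrate back
to $Q$ over all space; that property is documentation of the ideal
continuous model, not an invariant the discrete model can satisfy.

The effective height is $h = \Delta H + H$ by default: stack or
building height above ground plus ground elevation above sea level
(a 30-m stack at 200 m elevation releases at 230 m). This *absolute*
convention is the model's stated one and is appropriate for study areas
near sea level, but it suppresses concentrations wholesale when the
whole terrain is high; a *relative* option
($\Delta H + H_{src} - H_{rec}$, floored at $\Delta H$) is provided for
such terrain. Both conventions agree at sea level.

Distances are planar cell-centre to cell-centre, floored at
`min_distance` (default half a cell) to keep the $1/x$ arc finite; a
source's own cell is evaluated at the floor distance, summed over all
sectors with their frequencies (set `self_cell = "zero"` to drop the
self term). Units are centralized: ton/yr → g/s via $3.1536\times10^7$
s/yr, output in mg/m³.

The grid engine loops over emitting cells and superposes vectorized
per-sector contributions; a receptor receives each source through
exactly one sector (the one opposite its bearing from the source). The
tests hold the engine to a brute-force scalar per-cell re-evaluation at
$10^{-10}$ relative tolerance on grids up to 30 × 30, and to exact
superposition and Q/T linearity.

## Classification, overlay and comparison

Concentration fields are binned with lower-closed intervals
$[\ell, u)$ — a value exactly at an edge belongs to the higher level,
a documented choice where printed bin labels ("<0.005", "0.005–0.02")
leave the boundary open. The default six-level edges are 0.005, 0.01,
0.02, 0.06, 0.1 mg/m³ for SO₂ and 0.005, 0.02, 0.04, 0.07, 0.14 for
PM₁₀, anchored on the GB 3095-2012 annual standard; the coarser
three-level reading of the standard is available by passing three
edges. Areas are reported in hm² (one 300-m cell = 9 hm²). The overlay
takes a categorical planning raster congruent with the grid (polygon
layers should be rasterized by cell-centre containment upstream);
per-category percentages sum to 100 and a planning layer covering the
whole grid reproduces the whole-grid table exactly — both are tested
invariants. Scenario comparison re-tabulates both years and reports
per-level area changes, mean-concentration change and the cellwise
difference raster; the verdict on whether a plan is "environmentally
friendly" is left to the analyst reading those tables.

## The toy city generator

`make_toy_city()` emulates the input stack of a real assessment at a
testable size: a 40 × 40 grid at 300 m (the working resolution of
city-scale assessments, making the unit arithmetic identical to a real
run), a contiguous urban core, rural patches, an agricultural
background, a one-cell road cross, three key-plot cells, a gently
sloping DEM, 365 days of meteorology with a southeast prevailing sector
(30% of days, mean speed 3.2 m/s — a temperate coastal monsoon
profile), and inventory parameters in the ranges of a coal-burning
mid-size city (sulfur content ~1%, conversion 0.8, key-plot
desulfurization 0.6, none for residential; rural/agricultural emission
factors 0.4 and 3.74/10 kg/ton). All draws derive from one integer
seed; regeneration is bit-identical, which the byte-reproducibility
tests rely on.

What the toy city does **not** emulate: real geography (coastlines,
terrain channelling), hourly meteorology, seasonal activity cycles,
plume rise, chemistry, or spatially heterogeneous emission factors.
Passing tests on it demonstrate the arithmetic, conservation,
determinism and invariances of the pipeline — not predictive accuracy
for any real city, which depends on the quality of the local inventory
and meteorology fed in.

## Numerical and interface choices

* Rasters are plain matrices with an attached grid geometry; files move
  as ESRI ASCII grids — a transparent text format every GIS reads —
  with CSV tables and JSON configs/sidecars around them. Whole-number
  cell values (category codes) are written exactly regardless of the
  precision setting.
* Row 1 of every raster is the north edge; areas are computed in the
  projected coordinate system of the inputs.
* All spatial layers must share one geometry; the pipeline validates
  congruence rather than resampling silently.
* Pipeline outputs are staged in a temporary directory and moved into
  place only on success, so failed runs leave no partial artifacts;
  every artifact carries a timestamp-free `.prov.json` sidecar (config
  hash, package version, file hash) so re-runs are byte-identical.
* Problem sizes in the tests (grids of 9–41 cells a side, 365-day
  meteorology, 25–30-cell oracle comparisons) keep the full suite
  around half a minute while exercising every code path; the brute-force
  oracle grows quartically with grid side and is the binding size
  constraint.

## Known limitations

Uniform spreading within a category ignores intra-category emission
gradients (a motorway vs. a lane; dense vs. sparse housing). The
single modal stability class per sector compresses the joint
frequency distribution of stability and wind direction. The scalar
attenuation $T$ has no distance dependence, so it cannot represent
near-source deposition differently from far-field decay. The absolute
height convention is physically questionable over elevated terrain —
use the relative option there. And the model is annual-average by
construction: it says nothing about episodes, which need an hourly
model and data this workflow deliberately avoids.
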