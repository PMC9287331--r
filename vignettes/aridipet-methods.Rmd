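---
title: "Methods: reference evapotranspiration and aridity index computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference evapotranspiration and aridity index computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aridipet)
```

## The model

`aridipet` estimates reference evapotranspiration ET~0~ — the evaporative
demand of the atmosphere over a hypothetical, well-watered grass surface —
with the FAO-56 Penman-Monteith combination equation, and derives the
aridity index AI as mean annual precipitation over mean annual ET~0~.
The combination equation merges the radiative energy balance with
aerodynamic mass transfer:

$$ET_0 = \frac{\Delta (R_n - G) + \rho_a c_p (e_s - e_a)/r_a}
              {\Delta + \gamma (1 + r_s/r_a)}$$

where $\Delta$ is the slope of the saturation vapour pressure curve at the
mean air temperature (kPa °C^-1^), $R_n$ the net radiation and $G$ the
soil heat flux (MJ m^-2^ day^-1^), $\rho_a$ the air density, $c_p$ the
specific heat of moist air, $e_s - e_a$ the vapour pressure deficit (kPa),
$\gamma$ the psychrometric constant (kPa °C^-1^), and $r_s$, $r_a$ the
bulk surface and aerodynamic resistances (s m^-1^).

For the standardized reference surface — grass of height 0.12 m, albedo
0.23, bulk surface resistance fixed at 70 s m^-1^, measurements at 2 m —
the equation collapses to the familiar simplified daily form implemented
by `et0_daily()`:

$$ET_0 = \frac{0.408\,\Delta (R_n - G) +
   \gamma \frac{900}{T + 273}\, u_2 (e_s - e_a)}
   {\Delta + \gamma (1 + 0.34\, u_2)}$$

Both forms are implemented. `et0_general()` evaluates the energy-balance
form with explicit resistances; its agreement with the simplified form
(within 2% over realistic conditions; the 900 coefficient is FAO-56's
rounding of $86400\,\epsilon/(1.01 R \times 208) \approx 891$) is asserted
by the test-suite, so the two routes cross-check each other.

### Assumptions

* **Monthly climatology.** Inputs are multi-decade monthly normals, not
  time series. Daily ET~0~ is evaluated once per month at the
  representative mid-month day $J = \mathrm{round}(30.4\,m - 15)$ and
  scaled by non-leap month lengths (February = 28 days). The annual
  standard deviation layer is the population standard deviation of the 12
  monthly totals — with normals as input, across-month spread is the only
  dispersion that exists.
* **Soil heat flux ignored** ($G = 0$): at monthly scale over vegetated
  surfaces the storage term is small, and estimating soil heat capacity
  per cell would add more error than it removes.
* **Kelvin offsets are kept as conventionally printed**: the longwave
  emission term uses K = °C + 273.16, while the virtual-temperature and
  combination-equation denominators use the rounded 273. Harmonizing them
  would change results by well under 0.1% but would no longer reproduce
  the standard formulation term for term.
* **365-day year** in the solar geometry (no leap handling), the printed
  FAO-56 periodicity.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| crop height | 0.12 | m | reference grass standard |
| albedo | 0.23 | — | green grass reference |
| bulk surface resistance | 70 | s m^-1^ | fixed reference value; the raw stomatal/LAI formula gives 69.44 and is exposed via `bulk_surface_resistance(reference_override = FALSE)` for non-reference crops, but 70 is what the 0.34 wind coefficient presumes |
| measurement height | 2 | m | wind at 10 m is converted with the log-profile factor $4.87/\ln(67.8 z - 5.42)$ |
| wind floor | 0.5 | m s^-1^ | $r_a = 208/u_2$ is singular in calm air; FAO practice floors the wind, and the run report counts how often |
| soil heat flux | 0 | MJ m^-2^ day^-1^ | see above |

## Numerical choices and degenerate inputs

* **Supersaturation clip.** Gridded vapour pressure and temperature are
  interpolated independently, so $e_a > e_s$ can occur. $e_a$ is clipped
  to $e_s$ (keeping the deficit non-negative, as the combination equation
  presumes) and every clip is counted in the run report.
* **Cloudiness ratio clamp.** $R_s/R_{so}$ is clamped to at most 1 before
  the net-longwave cloudiness factor; interpolated radiation grids can
  exceed the clear-sky envelope slightly and would otherwise produce
  super-clear-sky longwave loss. There is no lower clamp.
* **Polar night.** Where both $R_s = 0$ and $R_{so} = 0$ the cloudiness
  ratio is undefined; the conventional mid value 0.5 is used (cloudiness
  is unobservable without sun). $R_{so} = 0$ with $R_s > 0$ is physically
  inconsistent and propagates nodata.
* **Negative ET~0~** (net radiative loss with near-saturated air) is
  clamped to zero and counted — distributed totals are non-negative.
* **Zero ET~0~ in the aridity denominator** yields nodata, never
  infinity; monthly AI uses monthly precipitation over monthly ET~0~
  (mirroring the 12 monthly AI layers), while the annual AI uses annual
  totals and therefore survives polar-winter months.
* **UNEP class boundaries** are lower-inclusive (0.03, 0.2, 0.5), and the
  humid boundary is strict: AI = 0.65 is Dry sub-humid, anything above is
  Humid — this respects the strict inequality conventionally printed at
  the humid end.
* **Integer AI encoding** rounds half away from zero at the ×10,000
  scale, giving a deterministic round-trip error of at most 5×10^-5^.

## The raster engine

Rasters are exchanged as ESRI ASCII grids (`.asc`), a plain-text
GDAL-standard format carrying the corner-registered geotransform and a
nodata sentinel; coordinates are geographic WGS84 and cell-centre
latitudes drive the solar geometry. The engine applies the scalar chain
elementwise, which yields its central correctness property: every grid
cell equals the scalar chain run on that cell's values, bit for bit, and
block-streamed execution (any `block_size`) is identical to whole-array
execution. The test-suite asserts both on an 8×8 tile; the stream design
means memory scales with block size, not grid size. Nodata is the
per-cell union across the variables a computation touches. Output
floating rasters use a −9999 sentinel; integer-encoded AI uses −32768.

Output naming follows the distribution convention
`{et0_v3|ai_v3}_{01..12|yr|yr_sd}.asc`.

## Station validation

`regression_stats()` fits ordinary least squares of the model values on
the reference values and reports r² (squared Pearson correlation), the
standard error of estimate $\sqrt{\sum e_i^2/(n-2)}$, and bias as
mean(model − reference) — the sign convention being "first-listed minus
second-listed". Grid sampling at station coordinates is nearest-cell
(the cell containing the point, half-open `[left, right)` convention),
not interpolated. Stations are ingested from a documented CSV schema
(`inst/extdata/station_schema.md`); rows failing range checks are
quarantined with reasons, and sunshine-hours tables are rejected because
sunshine-to-radiation conversion is out of scope.

## The synthetic generator

`synth_climate_stack()` builds deterministic, physically plausible
monthly stacks: temperature falls with latitude (0.6 °C per degree) and
elevation (6.5 °C km^-1^), the seasonal cycle grows poleward and is
phase-shifted six months between hemispheres, solar radiation is a
uniform cloudiness fraction (0.3–0.8) of the package's own clear-sky
radiation (guaranteeing $R_s \le R_{so}$ at zero noise; raise the upper
bound above 1 to stress the clamp deliberately), vapour pressure is a
humidity fraction (0.45–0.95) of saturation at the minimum temperature
(no supersaturation at zero noise), and precipitation follows a
wet-equator / dry-subtropics profile. The canonical fixture cited by the
tests is an 8×8 tile of 0.5° cells with seed 42.

`synth_station_table()` samples distinct cell centres of such a stack and
fills the reported ET~0~ columns with the scalar-chain values, optionally
Gaussian-perturbed. Closed-loop validation — running the grid engine on
the same stack and regressing the sampled annual ET~0~ against the
stations — is therefore exact (r² = 1, SE ≈ 0, bias ≈ 0) at zero noise,
and r² degrades monotonically as noise grows. What the generator does
*not* emulate: spatial covariance of real climate fields, orographic
precipitation, coastal gradients, or observation error structure. Passing
tests certify the numerical pipeline, not agreement with any real-world
station network; validating against real stations requires real forcing
data, which this package deliberately does not download.

## Problem sizes

The test-suite and the acceptance script run on tiles of at most 8×8
cells and 12–30 synthetic stations, a 1000-point parameter sweep for the
two-form equivalence, and a 52-point latitude/day grid for the radiation
integration check — sizes chosen so the whole suite re-runs in well under
a minute while exercising every code path; the engine itself streams, so
the same code scales to continental grids.

## Known limitations

* No reprojection or resampling: inputs must already be aligned
  geographic grids.
* Sunshine-duration inputs are rejected rather than converted.
* The monthly chain evaluates radiation at one representative day per
  month rather than averaging the solar geometry over days; at monthly
  climatology scale the difference is small but nonzero near the poles.
* February uses 28 days; normals averaged over leap-containing periods
  are thus fractionally underweighted (about 0.07%).
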