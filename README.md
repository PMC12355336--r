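# farmcf

Farm-level carbon-footprint accounting and benchmarking in R.

Agriculture is a major greenhouse-gas emitter, yet there is no accredited
standard for computing the carbon footprint (CF) of a whole farm. farmcf
implements a GHG-Protocol-aligned accounting framework for farms and the
benchmarking statistics needed to compare them. It is aimed at
agri-environmental analysts and researchers who have per-farm annual
activity data (livestock, fertilization, fuels, energy, purchases, land
use, waste) and an emission-factor registry, and want reproducible,
auditable whole-farm footprints and cohort comparisons.

## The model

Every emission is activity × factor, converted to CO2-equivalents with
100-year GWPs (CO2 = 1, CH4 = 28, N2O = 265; refrigerants by their own
GWPs) and booked into one of ten reporting flows. The net total is

```
CF = Scope 1 direct emissions
   + Scope 2 purchased-energy emissions
   + Scope 3 input-manufacturing emissions
   + Scope 3 waste & wastewater emissions
   - Scope 1 carbon sinks
```

Scope 1 covers enteric fermentation, manure management (by storage
system), soil N2O from applied nitrogen (×44/28), fuel combustion,
refrigerant leakage, on-site composting/biogas/wastewater (uncertified
biogas plants leak exactly 5% of gross CH4 production; certified plants
leak zero) and soil carbon sinks (stored C × −44/12, with no-till
cropland credited separately). Scope 2 is purchased electricity, heat and
cold. Scope 3 is input manufacturing — with machinery and solar panels
amortized straight-line over their lifespan on the *total stock* — plus
off-site waste and wastewater treatment.

From the footprint, farmcf derives emission intensities (CF per 1000 EUR
turnover, per hectare, per employee), the share of animal husbandry
`SoAH = (enteric + manure + animal-input manufacturing) / CF`, signed
flow shares and scope shares, and cohort statistics: Spearman rank
correlations for the size, scale and SoAH effects, and greedy SoAH-matched
farm pairing with per-flow decomposition of intensity differences.

All coefficients live in a user-supplied registry CSV
(`process,item,gas,factor,unit,source`); the package ships a clearly
labelled illustrative registry of round Tier-1-style numbers for tests,
examples and synthetic cohorts.

## A worked example

```r
library(farmcf)
reg <- illustrative_registry()
gwp <- gwp_illustrative()

farm <- farm_record(
  "demo_dairy", turnover_keur = 580, employees = 9,
  land = land_portfolio(cropland_tillage_ha = 250, grassland_ha = 100,
                        builtup_ha = 6),
  livestock = tibble::tibble(category = "dairy_cattle", heads = 120,
    anaerobic_digester = 0, liquid_storage = 0.73, solid_storage = 0.27,
    daily_spread = 0, pasture = 0),
  nitrogen = tibble::tibble(source = c("synthetic_fertilizer", "manure"),
                            n_kg = c(18000, 6000)),
  fuels = tibble::tibble(fuel = "diesel", quantity = 21000, unit = "L"),
  energy = tibble::tibble(carrier = "electricity", quantity_kwh = 90000),
  purchases = tibble::tibble(group = "animal_inputs",
                             item = "industrial_feed", quantity = 260,
                             unit = "t", year = 2022L),
  capital = tibble::tibble(item = "tractor", count = 3,
                           lifespan_years = 12))

fp <- assemble_footprint(farm, reg, gwp)
fp
#> <farm_footprint> demo_dairy
#>   total CF: 756.8 t CO2eq/yr
#>   scopes (t): S1 gross 544.2 | sinks -29.3 | S2 45.0 | S3 inputs 197.0 | S3 waste 0.0
#>   flows (t):
#>     ENTERIC_FERMENTATION        336.0
#>     MANURE_MANAGEMENT            51.5
#>     FERTILIZER_USE               99.9
#>     ENERGY_USE                  101.7
#>     INPUTS_ANIMAL               182.0
#>     INPUTS_OTHER                 15.0
#>     CARBON_SINKS                -29.3

str(relative_cfs(fp, farm))
#> List of 3
#>  $ cf_per_turnover: num 1305
#>  $ cf_per_area    : num 2126
#>  $ cf_per_employee: num 84093
round(soah(fp), 2)
#> [1] 0.75
```

The 120-cow herd dominates: enteric fermentation (336 t) plus manure
management and feed manufacturing put three quarters of the footprint
(SoAH 0.75) on animal husbandry, while the grassland sink offsets 29 t.
These numbers use the illustrative registry and demonstrate the method,
not any real farm.

Cohort-level analysis works the same way on many farms (or on synthetic
cohorts from `generate_cohort()`): `cohort_table()` →
`cohort_correlations()` / `soah_pairing()` / `pair_comparison()`.
A thin command-line front-end with `compute`, `cohort`, `synth` and
`validate` subcommands is installed at
`system.file("cli", "farmcf.R", package = "farmcf")`, operating on
per-farm directories of CSV tables (see `?read_farm`).

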