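---
title: "Farm-level carbon footprint accounting with farmcf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Farm-level carbon footprint accounting with farmcf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmcf)
```

## The accounting model

farmcf computes the annual greenhouse-gas carbon footprint (CF) of a whole
farm under the GHG Protocol scope classification. Every emission is an
activity quantity multiplied by an emission factor, converted to
CO2-equivalents with 100-year global warming potentials (CO2 = 1, CH4 = 28,
N2O = 265; refrigerants by their own GWPs), and booked into one of ten
reporting flows. The net total is

```
total CF = Scope 1 direct emissions
         + Scope 2 purchased-energy emissions
         + Scope 3 input-manufacturing emissions
         + Scope 3 waste and wastewater emissions
         - Scope 1 carbon sinks
```

Scope 1 covers what happens inside the farm boundary: enteric fermentation
(CH4 per head, by livestock category), manure management (CH4 and N2O per
head, split across anaerobic digester / liquid storage / solid storage /
daily spread / pasture by allocation fractions), soil N2O from nitrogen
applied by source (direct factors in kg N2O-N per kg N, multiplied by
44/28), fuel combustion (CO2/CH4/N2O per unit of fuel), refrigerant
leakage (mass times refrigerant GWP), on-site composting, biogas and
wastewater treatment, and soil carbon sinks. Scope 2 covers purchased
electricity, heat and cold per kWh. Scope 3 covers the manufacture of
purchased inputs and the treatment of waste handed over, with off-site
wastewater deliberately using the same COD coefficient as on-site
treatment so the routing of a load never changes its CO2eq.

Three modelling rules deserve emphasis:

* **Biogas leakage.** Uncertified biogas plants are assigned a CH4 leak of
  exactly 5% of gross production; a valid no-leakage certificate sets the
  leak to zero. The rate is the IPCC-recommended default for unmonitored
  plants.
* **Capital amortization.** Machinery and solar panels enter through the
  total stock, not annual purchases: each item contributes
  `count x EF / lifespan_years` per year. Straight-line division is exactly
  conserving (the lifespan-summed emissions equal the full manufacturing
  emissions) and smooths the investment spikes that would otherwise
  dominate small farms' footprints in purchase years.
* **Carbon sinks.** Sink factors are stored as positive kg C per hectare
  per year (or per hectare of conversion, already annualized) and enter
  the footprint as `-stored_C x 44/12` kg CO2eq. Cropland under
  no-tillage management is credited 60 kg C/ha/yr in the illustrative
  registry, a deliberately conservative value; conversions that lose
  carbon carry negative factors and therefore produce emissions. The
  conversion factors are taken as already annualized because amortization
  periods for land-use change are not standardized; users amortizing over
  e.g. 20 years should encode that in the registry value.

Molar-mass conversions (44/28 for N2O-N to N2O, 44/12 for C to CO2) are
fixed stoichiometry, not tunable parameters.

## The emission-factor registry

No emission factor is hard-coded except the three Kyoto-gas GWPs, the 5%
biogas leak rate and the two molar-mass ratios. Everything else lives in a
user-supplied registry CSV keyed by `(process, item, gas)`, because
coefficient sets are jurisdiction-specific (national inventory reports,
Ecoinvent, DESNZ/Defra) and mostly not redistributable. The package ships
`illustrative_registry()`: round, Tier-1-style numbers used by the tests,
examples and the synthetic generator. Its values are plausible in
magnitude but are **not** any inventory's coefficients, and footprints
computed with it are method demonstrations, not farm assessments.

Lookups are strict by default — a missing factor for a non-zero activity
is an error — because a permissive zero silently biases totals downward.
Permissive mode (zero plus a logged warning) exists for exploratory runs
on incomplete registries. Scope 3 manufacturing factors are aggregate
CO2-equivalents; they are stored under the pseudo-gas `CO2eq` (GWP 1)
rather than per-gas rows, matching how life-cycle databases publish them.

Soil N2O supports optional indirect pathways (volatilization, leaching):
they are computed only if the registry carries `SOIL_N2O_INDIRECT`
entries, because published farm studies differ on whether indirect N2O is
included and the choice should be visible in the registry, not buried in
code.

## Indicators and benchmarking

Absolute CFs scale with farm size, so the package derives emission
intensities: CF per 1000 EUR of turnover, per hectare of farm area
(cropland + grassland + built-up), and per employee. The share of animal
husbandry,

```
SoAH = (enteric fermentation + manure management + animal-input
        manufacturing) / total CF
```

isolates the flows unambiguously attributable to livestock; energy partly
used for animals is excluded because farms do not meter energy by
enterprise. Flow shares are signed (sinks negative, so positive shares can
sum above 100%); scope shares default to Scope 1 *net* of sinks so the
three shares total 100%, with a `"gross"` convention available that
reports the sink deduction separately — the choice is a presentation
convention, and both use the net total as denominator.

`cohort_correlations()` computes nine Spearman rank correlations: the size
effect (absolute CF vs turnover/area/employees), the scale effect (each
size variable vs its matching intensity; a cohort driven purely by
economies of scale would approach -1) and the SoAH effect (SoAH vs each
intensity). Ties receive average ranks — the standard convention —
and degenerate inputs (n < 3, constant sequences) are errors rather than
NaN so a malformed cohort cannot silently produce a "correlation".
`soah_pairing()` operationalizes "farms with similar SoAH" as a greedy
matching by ascending SoAH distance under a tolerance; published pairings
do not document their rule, so determinism (ties broken by table order)
was the design priority. `pair_comparison()` then decomposes the
per-turnover CF difference of a matched pair by flow.

## The synthetic cohort generator

Real activity data for cohorts are rarely publishable, so
`generate_cohort()` manufactures farm records whose *computed* properties
are controlled. Each farm gets a turnover drawn log-uniformly over
24.4–33368.7 thousand EUR (the three-orders-of-magnitude span of the
reference cohort) and a SoAH target in 0–0.8 (the observed range). Area
and employees follow power laws in turnover fitted to the smallest and
largest reference farms (`area = e^0.81 * T^0.74`,
`employees = e^-2.24 * T^0.7`, lognormal noise). Emission intensity is
`450 * (1 + 9 * SoAH)` kg CO2eq per 1000 EUR — chosen once so that
intensities span roughly the observed 427–4557 kg/kEUR range — times an
optional scale-effect term `(T/1000)^-gamma` and lognormal noise
(sd 0.25).

The generator then *inverts* the engines: the animal-side target is
converted to a dairy-herd size via the per-head emission of enteric
fermentation, manure management (under the cohort spec's liquid/solid
split) and
feed purchases; the non-animal target is split over fixed budget shares
(fertilizer N2O 30%, diesel 25%, electricity 15%, crop inputs 18%,
capital/other 6%, refrigerant 2%, waste/biogas 4%) and each budget is
divided by its registry factor. Tractor counts are rounded down and the
residue is re-assigned to a divisible input, so a generated farm's SoAH
equals its target exactly and its net total equals the sampled total.
Targets above 0.9 are rejected as infeasible since some non-animal
activity is always assigned.

What the generator does **not** emulate: agronomic structure (yields,
weather, prices, herd demography), correlations between management choices
and size, multi-category herds, and real registry heterogeneity. Passing
cohort tests therefore demonstrates that the *accounting and benchmarking
machinery* behaves correctly under the study's statistical conditions —
not that any particular real cohort will show the same correlations.

## Numerical choices and degenerate inputs

* Manure allocations must sum to 1 within 1e-9; heads may be fractional
  (annual averages).
* Footprint identities (total = signed flow sum = scope formula) hold to
  better than 1e-9 relative; tests assert them at that level on 1000
  synthetic farms.
* Shares and intensities with zero or negative denominators are defined
  errors (or per-indicator `NA` with a warning in cohort assembly, so one
  degenerate farm does not abort a cohort run).
* Registry round-trips are bit-identical: numbers are written in shortest
  round-tripping decimal form.
* The Spearman implementation is average-rank + Pearson via `rank()` and
  `cor()`; the test suite checks it against an independent loop-based
  definition oracle on every short tied sequence pair and against
  `cor(method = "spearman")` on random data.

Test and demonstration problem sizes — 12-farm cohorts, 100-seed
replicate sets, 1000-farm identity sweeps — were chosen as the smallest
sizes that exercise the cohort statistics meaningfully while keeping the
default suite quick to run.

## Known limitations

* No product-level (per litre of milk, per tonne of wheat) footprints:
  those need enterprise-disaggregated activity data the whole-farm form
  does not collect.
* The 20–50% uncertainty typical of Tier-1 inventory coefficients is not
  propagated; results are point estimates and should be compared across
  farms computed with the same registry, where biases are shared.
* No multivariate regression of intensities on SoAH and size; with
  cohorts of a dozen farms the rank correlations and matched pairs are
  the defensible tools.
* Farm-worker commuting and food, and on-farm incinerators/landfills, are
  outside the system boundary.

## A worked example

```{r example, eval = FALSE}
reg <- illustrative_registry()
gwp <- gwp_illustrative()
cohort <- generate_cohort(cohort_spec(n_farms = 12, seed = 1), reg, gwp)
tab <- cohort_table(cohort, reg, gwp)
cohort_correlations(tab)
soah_pairing(tab, tolerance = 0.04)
```
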