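# Scope 1: direct on-farm emissions and soil carbon sinks.
#
# All engines are linear activity x factor calculations: additive over
# input partitions and homogeneous of degree 1 in activity quantities, so
# zero activity always yields an exactly-zero ledger.

N2O_PER_N <- 44 / 28  # kg N2O per kg N2O-N (molar masses)
CO2_PER_C <- 44 / 12  # kg CO2 per kg C
BIOGAS_LEAK_RATE <- 0.05  # share of gross CH4 production, uncertified plants

#' Enteric fermentation methane
#'
#' CH4 from ruminant digestion: `heads * EF(category)` per livestock
#' category, with enteric factors in kg CH4 per head per year under
#' registry process `ENTERIC`.
#'
#' @param livestock Livestock tibble (see [farm_record()]).
#' @param registry A [read_registry()] registry.
#' @param gwp A [gwp_table()].
#' @return A ledger tibble (flow `ENTERIC_FERMENTATION`, scope S1).
#' @export
enteric_fermentation <- function(livestock, registry, gwp = gwp_default()) {
  if (nrow(livestock) == 0) return(empty_ledger())
  check_nonneg(livestock$heads, "Livestock heads")
  ef <- lookup_factors(registry, "ENTERIC", livestock$category, "CH4")
  new_ledger("ENTERIC_FERMENTATION", "S1", "ENTERIC", livestock$category,
             "CH4", livestock$heads * ef$factor, gwp)
}

#' Manure management CH4 and N2O
#'
#' Per livestock category, heads are split over the five manure management
#' systems by the allocation fractions; each (category, system) pair carries
#' a CH4 and an N2O factor in kg gas per head per year, stored under process
#' `MANURE` with item `"<category>:<system>"`. N2O factors are kg N2O (not
#' N2O-N).
#'
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `MANURE_MANAGEMENT`, scope S1).
#' @export
manure_management <- function(livestock, registry, gwp = gwp_default()) {
  if (nrow(livestock) == 0) return(empty_ledger())
  alloc <- rowSums(as.matrix(livestock[MANURE_SYSTEMS]))
  bad <- livestock$heads > 0 & abs(alloc - 1) > 1e-9
  if (any(bad)) {
    cf_abort(paste0("Manure allocation for category '",
                    livestock$category[bad][1], "' sums to ",
                    format(alloc[bad][1]), "; must sum to 1."),
             "farmcf_validation_error")
  }
  rows <- list()
  for (i in seq_len(nrow(livestock))) {
    if (livestock$heads[i] == 0) next
    for (sys in MANURE_SYSTEMS) {
      frac <- livestock[[sys]][i]
      if (frac == 0) next
      item <- paste0(livestock$category[i], ":", sys)
      for (gas in c("CH4", "N2O")) {
        f <- lookup_factor(registry, "MANURE", item, gas)
        rows[[length(rows) + 1]] <- new_ledger(
          "MANURE_MANAGEMENT", "S1", "MANURE", item, gas,
          livestock$heads[i] * frac * f$factor, gwp)
      }
    }
  }
  if (length(rows) == 0) return(empty_ledger())
  dplyr::bind_rows(rows)
}

#' Soil N2O from nitrogen applications
#'
#' Direct N2O from nitrogen applied to soils:
#' `n_kg * EF(source) * 44/28` per source, with per-source factors in
#' kg N2O-N per kg N under process `SOIL_N2O`. If the registry supplies
#' indirect-pathway fractions (process `SOIL_N2O_INDIRECT`, items
#' `volatilization` and/or `leaching`, in kg N2O-N per kg N applied), those
#' pathways are computed on total applied N and added to the same flow;
#' otherwise only the direct pathway is reported.
#'
#' @param nitrogen Nitrogen tibble (see [farm_record()]).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `FERTILIZER_USE`, scope S1).
#' @export
soil_n2o <- function(nitrogen, registry, gwp = gwp_default()) {
  if (nrow(nitrogen) == 0) return(empty_ledger())
  check_nonneg(nitrogen$n_kg, "Applied nitrogen")
  ef <- lookup_factors(registry, "SOIL_N2O", nitrogen$source, "N2O")
  led <- new_ledger("FERTILIZER_USE", "S1", "SOIL_N2O", nitrogen$source,
                    "N2O", nitrogen$n_kg * ef$factor * N2O_PER_N, gwp)
  total_n <- sum(nitrogen$n_kg)
  for (pathway in c("volatilization", "leaching")) {
    if (registry_has(registry, "SOIL_N2O_INDIRECT", pathway, "N2O")) {
      f <- lookup_factor(registry, "SOIL_N2O_INDIRECT", pathway, "N2O")
      led <- dplyr::bind_rows(led, new_ledger(
        "FERTILIZER_USE", "S1", "SOIL_N2O_INDIRECT", pathway, "N2O",
        total_n * f$factor * N2O_PER_N, gwp))
    }
  }
  led
}

#' Fuel combustion emissions
#'
#' CO2, CH4 and N2O per unit of fuel burned in machinery, equipment and
#' buildings. Factors sit under process `FUEL`, one row per gas; the
#' activity unit declared in the fuels table must match the registry's.
#'
#' @param fuels Fuels tibble (see [farm_record()]).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `ENERGY_USE`, scope S1).
#' @export
fuel_combustion <- function(fuels, registry, gwp = gwp_default()) {
  if (nrow(fuels) == 0) return(empty_ledger())
  check_nonneg(fuels$quantity, "Fuel quantity")
  rows <- lapply(c("CO2", "CH4", "N2O"), function(gas) {
    ef <- lookup_factors(registry, "FUEL", fuels$fuel, gas)
    mismatch <- !is.na(ef$unit) & ef$unit != fuels$unit
    if (any(mismatch)) {
      j <- which(mismatch)[1]
      cf_abort(paste0("Unit mismatch for fuel '", fuels$fuel[j],
                      "': data says '", fuels$unit[j],
                      "', registry expects '", ef$unit[j], "'."),
               "farmcf_unit_error")
    }
    new_ledger("ENERGY_USE", "S1", "FUEL", fuels$fuel, gas,
               fuels$quantity * ef$factor, gwp)
  })
  dplyr::bind_rows(rows)
}

#' Refrigerant leakage
#'
#' Leaked refrigerant mass converted with the refrigerant's own GWP; no
#' registry factor is involved, only the GWP table.
#'
#' @param refrigerants Refrigerants tibble (see [farm_record()]).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `OTHER_FARM_ACTIVITIES`, scope S1).
#' @export
refrigerant_emissions <- function(refrigerants, gwp = gwp_default()) {
  if (nrow(refrigerants) == 0) return(empty_ledger())
  check_nonneg(refrigerants$mass_kg, "Refrigerant leakage")
  new_ledger("OTHER_FARM_ACTIVITIES", "S1", "REFRIGERANT_LEAK",
             refrigerants$code, refrigerants$code, refrigerants$mass_kg, gwp)
}

#' On-site waste, biogas and wastewater emissions
#'
#' Composting CH4 and N2O per tonne composted (process `COMPOST`, item
#' `composted_waste`); biogas CH4 leakage of 5% of gross production unless
#' the plant holds a valid no-leakage certificate (then exactly zero); and
#' wastewater CH4 per kg COD treated (process `WASTEWATER`, item `cod`).
#'
#' @param ops On-site waste list (see [farm_record()] `waste_onsite`).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `WASTE_WASTEWATER`, scope S1).
#' @export
onsite_waste_emissions <- function(ops, registry, gwp = gwp_default()) {
  ops <- utils::modifyList(default_waste_onsite(), ops)
  check_nonneg(c(ops$composted_t, ops$wastewater_cod_kg, ops$biogas_ch4_kg),
               "On-site waste quantities")
  rows <- list()
  if (ops$composted_t > 0) {
    for (gas in c("CH4", "N2O")) {
      f <- lookup_factor(registry, "COMPOST", "composted_waste", gas)
      rows[[length(rows) + 1]] <- new_ledger(
        "WASTE_WASTEWATER", "S1", "COMPOST", "composted_waste", gas,
        ops$composted_t * f$factor, gwp)
    }
  }
  if (ops$biogas_ch4_kg > 0) {
    leak <- if (isTRUE(ops$biogas_certified)) 0 else
      BIOGAS_LEAK_RATE * ops$biogas_ch4_kg
    rows[[length(rows) + 1]] <- new_ledger(
      "WASTE_WASTEWATER", "S1", "BIOGAS", "ch4_leakage", "CH4", leak, gwp)
  }
  if (ops$wastewater_cod_kg > 0) {
    f <- lookup_factor(registry, "WASTEWATER", "cod", "CH4")
    rows[[length(rows) + 1]] <- new_ledger(
      "WASTE_WASTEWATER", "S1", "WASTEWATER", "cod", "CH4",
      ops$wastewater_cod_kg * f$factor, gwp)
  }
  if (length(rows) == 0) return(empty_ledger())
  dplyr::bind_rows(rows)
}

#' Soil and biomass carbon sinks
#'
#' Annual net carbon storage per land use (process `SINK`, kg C/ha/yr;
#' cropland under no-tillage management is credited separately from tilled
#' cropland) plus land-use conversion effects (process `SINK_CONVERSION`,
#' item `"<from>_to_<to>"`, annualized kg C/ha). Stored carbon enters the
#' footprint as `-stored_C * 44/12` kg CO2eq, so positive carbon factors
#' produce a negative flow and carbon-losing conversions (negative factors)
#' produce emissions.
#'
#' @param land A [land_portfolio()].
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `CARBON_SINKS`, scope S1, CO2eq <= 0 when
#'   all carbon factors are >= 0).
#' @export
carbon_sinks <- function(land, registry, gwp = gwp_default()) {
  stopifnot(inherits(land, "land_portfolio"))
  uses <- c(cropland_tillage = land$cropland_tillage_ha,
            cropland_no_till = land$cropland_no_till_ha,
            grassland = land$grassland_ha,
            builtup = land$builtup_ha)
  rows <- list()
  for (use in names(uses)) {
    if (uses[[use]] == 0) next
    f <- lookup_factor(registry, "SINK", use, "CO2")
    rows[[length(rows) + 1]] <- new_ledger(
      "CARBON_SINKS", "S1", "SINK", use, "CO2",
      -uses[[use]] * f$factor * CO2_PER_C, gwp)
  }
  conv <- land$conversions
  for (i in seq_len(nrow(conv))) {
    if (conv$area_ha[i] == 0) next
    item <- paste0(conv$from_use[i], "_to_", conv$to_use[i])
    f <- lookup_factor(registry, "SINK_CONVERSION", item, "CO2")
    rows[[length(rows) + 1]] <- new_ledger(
      "CARBON_SINKS", "S1", "SINK_CONVERSION", item, "CO2",
      -conv$area_ha[i] * f$factor * CO2_PER_C, gwp)
  }
  if (length(rows) == 0) return(empty_ledger())
  dplyr::bind_rows(rows)
}
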