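# Scope 2 (purchased energy) and Scope 3 (input manufacturing, off-site
# waste and wastewater) indirect emissions.

#' Purchased energy emissions (Scope 2)
#'
#' CO2, CH4 and N2O per kWh of purchased electricity, heat or cold (cold is
#' expressed in kWh-equivalent cooling energy). Factors sit under registry
#' process `ENERGY_S2`, one row per gas.
#'
#' @param energy Energy-purchase tibble (see [farm_record()]).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `ENERGY_USE`, scope S2).
#' @export
scope2_emissions <- function(energy, registry, gwp = gwp_default()) {
  if (nrow(energy) == 0) return(empty_ledger())
  check_nonneg(energy$quantity_kwh, "Purchased energy")
  rows <- lapply(c("CO2", "CH4", "N2O"), function(gas) {
    ef <- lookup_factors(registry, "ENERGY_S2", energy$carrier, gas)
    new_ledger("ENERGY_USE", "S2", "ENERGY_S2", energy$carrier, gas,
               energy$quantity_kwh * ef$factor, gwp)
  })
  dplyr::bind_rows(rows)
}

# Routing of purchase groups to reporting flows. Energy carriers' upstream
# manufacture goes to INPUTS_OTHER (their combustion is Scope 1), as does
# purchased-refrigerant manufacture (use-phase leakage is Scope 1).
route_group <- function(group) {
  ifelse(group == "crop_inputs", "INPUTS_CROP",
         ifelse(group == "animal_inputs", "INPUTS_ANIMAL", "INPUTS_OTHER"))
}

#' Input manufacturing emissions (Scope 3)
#'
#' Emissions embodied in purchased farm inputs, attributed to the year of
#' purchase, plus straight-line amortization of the capital stock: each
#' capital item (machinery, solar panels, ...) contributes
#' `count * EF(item) / lifespan_years` per year, computed on the total
#' stock rather than annual purchases so that infrequent investments do not
#' spike small farms' footprints. Consumable factors sit under process
#' `INPUT` (aggregate CO2eq per activity unit), capital factors under
#' `CAPITAL` (CO2eq per unit manufactured).
#'
#' Routing: group `crop_inputs` feeds flow `INPUTS_CROP`, `animal_inputs`
#' feeds `INPUTS_ANIMAL`, every other group and all capital feed
#' `INPUTS_OTHER`.
#'
#' @param purchases Purchases tibble (see [farm_record()]).
#' @param capital Capital tibble (see [farm_record()]).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flows `INPUTS_CROP`/`INPUTS_ANIMAL`/
#'   `INPUTS_OTHER`, scope S3).
#' @export
input_manufacturing <- function(purchases, capital, registry,
                                gwp = gwp_default()) {
  rows <- list()
  if (nrow(purchases) > 0) {
    check_nonneg(purchases$quantity, "Purchase quantity")
    ef <- lookup_factors(registry, "INPUT", purchases$item, "CO2eq")
    mismatch <- !is.na(ef$unit) & ef$unit != purchases$unit
    if (any(mismatch)) {
      j <- which(mismatch)[1]
      cf_abort(paste0("Unit mismatch for purchased item '",
                      purchases$item[j], "': data says '", purchases$unit[j],
                      "', registry expects '", ef$unit[j], "'."),
               "farmcf_unit_error")
    }
    rows[[1]] <- new_ledger(route_group(purchases$group), "S3", "INPUT",
                            purchases$item, "CO2eq",
                            purchases$quantity * ef$factor, gwp)
  }
  if (nrow(capital) > 0) {
    check_nonneg(capital$count, "Capital item count")
    life <- capital$lifespan_years
    if (any(!is.finite(life)) || any(life < 1) || any(life != round(life))) {
      cf_abort("Capital lifespan_years must be an integer >= 1.",
               "farmcf_validation_error")
    }
    ef <- lookup_factors(registry, "CAPITAL", capital$item, "CO2eq")
    rows[[length(rows) + 1]] <- new_ledger(
      "INPUTS_OTHER", "S3", "CAPITAL", capital$item, "CO2eq",
      capital$count * ef$factor / life, gwp)
  }
  if (length(rows) == 0) return(empty_ledger())
  dplyr::bind_rows(rows)
}

#' Off-site waste and wastewater emissions (Scope 3)
#'
#' Treatment of waste handed over by the farm, per fraction (paper, plastic,
#' metal, bio, glass, construction, municipal, other; process
#' `WASTE_OFFSITE`, aggregate CO2eq per tonne) plus off-site wastewater by
#' COD, which deliberately reuses the on-site `WASTEWATER` coefficient so
#' that identical COD loads yield identical CO2eq wherever treated.
#'
#' @param waste Off-site waste tibble (see [farm_record()] `waste_offsite`):
#'   rows with `item` a waste fraction (`unit = "t"`) or `"wastewater"`
#'   (`unit = "kg COD"`).
#' @inheritParams enteric_fermentation
#' @return A ledger tibble (flow `WASTE_WASTEWATER`, scope S3).
#' @export
offsite_waste_emissions <- function(waste, registry, gwp = gwp_default()) {
  if (nrow(waste) == 0) return(empty_ledger())
  check_nonneg(waste$quantity, "Off-site waste quantity")
  bad <- !waste$item %in% c(WASTE_FRACTIONS, "wastewater")
  if (any(bad)) {
    cf_abort(paste0("Unknown off-site waste fraction '",
                    waste$item[bad][1], "'."),
             "farmcf_validation_error")
  }
  rows <- list()
  solid <- waste[waste$item != "wastewater", , drop = FALSE]
  if (nrow(solid) > 0) {
    ef <- lookup_factors(registry, "WASTE_OFFSITE", solid$item, "CO2eq")
    mismatch <- !is.na(ef$unit) & ef$unit != solid$unit
    if (any(mismatch)) {
      j <- which(mismatch)[1]
      cf_abort(paste0("Unit mismatch for waste fraction '", solid$item[j],
                      "': data says '", solid$unit[j],
                      "', registry expects '", ef$unit[j], "'."),
               "farmcf_unit_error")
    }
    rows[[1]] <- new_ledger("WASTE_WASTEWATER", "S3", "WASTE_OFFSITE",
                            solid$item, "CO2eq",
                            solid$quantity * ef$factor, gwp)
  }
  ww <- waste[waste$item == "wastewater", , drop = FALSE]
  if (nrow(ww) > 0) {
    if (any(ww$unit != "kg COD")) {
      cf_abort(paste0("Off-site wastewater must be quantified in 'kg COD', ",
                      "got '", ww$unit[ww$unit != "kg COD"][1], "'."),
               "farmcf_unit_error")
    }
    f <- lookup_factor(registry, "WASTEWATER", "cod", "CH4")
    rows[[length(rows) + 1]] <- new_ledger(
      "WASTE_WASTEWATER", "S3", "WASTEWATER", "cod", "CH4",
      sum(ww$quantity) * f$factor, gwp)
  }
  if (length(rows) == 0) return(empty_ledger())
  dplyr::bind_rows(rows)
}
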