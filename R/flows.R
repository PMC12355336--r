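# Reporting flows and the signed CO2eq ledger shared by all engines.
#
# Every engine returns a "ledger": a tibble with one row per
# (flow, scope, process, item, gas) carrying the gas mass and its CO2eq.
# CARBON_SINKS is the only flow permitted negative values.

FLOW_IDS <- c(
  "ENTERIC_FERMENTATION", "MANURE_MANAGEMENT", "FERTILIZER_USE",
  "ENERGY_USE", "INPUTS_CROP", "INPUTS_ANIMAL", "INPUTS_OTHER",
  "OTHER_FARM_ACTIVITIES", "WASTE_WASTEWATER", "CARBON_SINKS"
)

# Permitted (flow, scope) attributions.
FLOW_SCOPES <- list(
  ENTERIC_FERMENTATION = "S1",
  MANURE_MANAGEMENT = "S1",
  FERTILIZER_USE = "S1",
  ENERGY_USE = c("S1", "S2"),
  INPUTS_CROP = "S3",
  INPUTS_ANIMAL = "S3",
  INPUTS_OTHER = "S3",
  OTHER_FARM_ACTIVITIES = "S1",
  WASTE_WASTEWATER = c("S1", "S3"),
  CARBON_SINKS = "S1"
)

#' Reporting flows of the farm footprint
#'
#' The ten GHG flows a footprint is decomposed into, with their scope
#' attribution. `CARBON_SINKS` is the only flow that may carry a negative
#' CO2eq value.
#'
#' @return A tibble with columns `flow` and `scopes`.
#' @export
cf_flows <- function() {
  tibble::tibble(
    flow = FLOW_IDS,
    scopes = vapply(FLOW_SCOPES[FLOW_IDS], paste, character(1), collapse = "+")
  )
}

# Permitted flow:scope keys, precomputed for the hot path.
FLOW_SCOPE_KEYS <- unlist(lapply(names(FLOW_SCOPES), function(f) {
  paste0(f, ":", FLOW_SCOPES[[f]])
}), use.names = FALSE)

empty_ledger <- function() {
  tibble::new_tibble(
    list(flow = character(), scope = character(), process = character(),
         item = character(), gas = character(),
         mass_kg = double(), co2eq_kg = double()),
    nrow = 0
  )
}

# Build ledger rows; vector arguments are recycled to a common length.
new_ledger <- function(flow, scope, process, item, gas, mass_kg, gwp) {
  n <- max(length(flow), length(scope), length(item), length(gas),
           length(mass_kg), length(process))
  if (n == 0) return(empty_ledger())
  flow <- rep_len(flow, n); scope <- rep_len(scope, n)
  process <- rep_len(process, n); item <- rep_len(item, n)
  gas <- rep_len(gas, n); mass_kg <- rep_len(as.numeric(mass_kg), n)
  ok <- paste0(flow, ":", scope) %in% FLOW_SCOPE_KEYS
  if (!all(ok)) {
    j <- which(!ok)[1]
    if (!flow[j] %in% FLOW_IDS) {
      cf_abort(paste0("Unknown reporting flow '", flow[j], "'."),
               "farmcf_validation_error")
    }
    cf_abort(paste0("Scope ", scope[j], " is not a valid attribution for ",
                    "flow ", flow[j], "."),
             "farmcf_validation_error")
  }
  tibble::new_tibble(
    list(flow = flow, scope = scope, process = process, item = item,
         gas = gas, mass_kg = mass_kg,
         co2eq_kg = mass_kg * gwp_lookup(gwp, gas)),
    nrow = n
  )
}
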