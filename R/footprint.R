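# FarmFootprint: the signed CO2eq ledger of one farm, aggregated by
# reporting flow and scope, plus the net total carbon footprint.

#' Assemble a farm's carbon footprint
#'
#' Runs every Scope 1, 2 and 3 engine on a farm record, merges the resulting
#' ledgers, and computes scope totals and the net total footprint
#'
#' `total_cf = S1_gross + S2 + S3_inputs + S3_waste - |S1_sinks|`
#'
#' where `S1_gross` is direct emissions excluding sinks and `S1_sinks` is
#' the (non-positive) carbon-sink flow. The same total is, by construction,
#' the signed sum over all ten reporting flows.
#'
#' @param farm A [farm_record()].
#' @param registry A [read_registry()] registry covering all non-zero
#'   activities.
#' @param gwp A [gwp_table()]; must cover any refrigerant codes used.
#' @return A list of class `farm_footprint` with elements `farm_id`,
#'   `ledger` (row-level gas detail), `flows` (kg CO2eq by flow and scope),
#'   `flow_totals` (named vector, one signed value per reporting flow),
#'   `scope_totals` (named vector: S1_gross, S1_sinks, S2, S3_inputs,
#'   S3_waste) and `total_cf` (kg CO2eq per year).
#' @examples
#' reg <- illustrative_registry()
#' farm <- farm_record("demo", turnover_keur = 100, employees = 2,
#'   land = land_portfolio(grassland_ha = 10),
#'   livestock = tibble::tibble(category = "dairy_cattle", heads = 5,
#'     anaerobic_digester = 0, liquid_storage = 0.5, solid_storage = 0.5,
#'     daily_spread = 0, pasture = 0))
#' assemble_footprint(farm, reg)
#' @export
assemble_footprint <- function(farm, registry, gwp = gwp_default()) {
  if (!inherits(farm, "farm_record")) {
    cf_abort("`farm` must be a farm_record.", "farmcf_validation_error")
  }
  ledger <- withCallingHandlers(
    dplyr::bind_rows(
      enteric_fermentation(farm$livestock, registry, gwp),
      manure_management(farm$livestock, registry, gwp),
      soil_n2o(farm$nitrogen, registry, gwp),
      fuel_combustion(farm$fuels, registry, gwp),
      refrigerant_emissions(farm$refrigerants, gwp),
      onsite_waste_emissions(farm$waste_onsite, registry, gwp),
      scope2_emissions(farm$energy, registry, gwp),
      input_manufacturing(farm$purchases, farm$capital, registry, gwp),
      offsite_waste_emissions(farm$waste_offsite, registry, gwp),
      carbon_sinks(farm$land, registry, gwp)
    ),
    error = function(e) {
      if (inherits(e, "farmcf_error")) {
        cf_abort(paste0("Farm '", farm$farm_id, "': ",
                        conditionMessage(e)),
                 class(e)[1], parent = e)
      }
    })

  # Aggregate over the full flow x scope grid so absent flows report 0.
  keys <- FLOW_SCOPE_KEYS
  sums <- numeric(length(keys))
  if (nrow(ledger) > 0) {
    idx <- match(paste0(ledger$flow, ":", ledger$scope), keys)
    sums <- vapply(seq_along(keys), function(k) {
      sum(ledger$co2eq_kg[idx == k])
    }, numeric(1))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  flows <- tibble::new_tibble(
    list(flow = vapply(parts, `[`, character(1), 1),
         scope = vapply(parts, `[`, character(1), 2),
         co2eq_kg = sums),
    nrow = length(keys))

  flow_totals <- vapply(FLOW_IDS, function(f) {
    sum(flows$co2eq_kg[flows$flow == f])
  }, numeric(1))

  scope_totals <- c(
    S1_gross = sum(flows$co2eq_kg[flows$scope == "S1" &
                                    flows$flow != "CARBON_SINKS"]),
    S1_sinks = unname(flow_totals["CARBON_SINKS"]),
    S2 = sum(flows$co2eq_kg[flows$scope == "S2"]),
    S3_inputs = sum(flows$co2eq_kg[flows$scope == "S3" &
                                     flows$flow != "WASTE_WASTEWATER"]),
    S3_waste = sum(flows$co2eq_kg[flows$scope == "S3" &
                                    flows$flow == "WASTE_WASTEWATER"])
  )
  total_cf <- scope_totals[["S1_gross"]] + scope_totals[["S2"]] +
    scope_totals[["S3_inputs"]] + scope_totals[["S3_waste"]] +
    scope_totals[["S1_sinks"]]

  structure(list(farm_id = farm$farm_id, ledger = ledger, flows = flows,
                 flow_totals = flow_totals, scope_totals = scope_totals,
                 total_cf = total_cf),
            class = "farm_footprint")
}

#' @export
print.farm_footprint <- function(x, ...) {
  cat("<farm_footprint> ", x$farm_id, "\n", sep = "")
  cat(sprintf("  total CF: %.1f t CO2eq/yr\n", x$total_cf / 1000))
  st <- x$scope_totals / 1000
  cat(sprintf("  scopes (t): S1 gross %.1f | sinks %.1f | S2 %.1f | S3 inputs %.1f | S3 waste %.1f\n",
              st[["S1_gross"]], st[["S1_sinks"]], st[["S2"]],
              st[["S3_inputs"]], st[["S3_waste"]]))
  nz <- x$flow_totals[x$flow_totals != 0]
  if (length(nz) > 0) {
    cat("  flows (t):\n")
    for (f in names(nz)) cat(sprintf("    %-22s %10.1f\n", f, nz[[f]] / 1000))
  }
  invisible(x)
}
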