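# FarmRecord: one farm's characteristics and annual activity data.

MANURE_SYSTEMS <- c("anaerobic_digester", "liquid_storage", "solid_storage",
                    "daily_spread", "pasture")
N_SOURCES <- c("synthetic_fertilizer", "manure", "sewage_sludge", "digestate",
               "compost", "crop_residues", "urine_dung")
FUEL_TYPES <- c("coal", "natural_gas", "petrol", "diesel", "biomass")
ENERGY_CARRIERS <- c("electricity", "heat", "cold")
PURCHASE_GROUPS <- c("crop_inputs", "animal_inputs", "water", "refrigerants",
                     "energy_carriers", "packaging", "building_materials")
WASTE_FRACTIONS <- c("paper", "plastic", "metal", "bio", "glass",
                     "construction", "municipal", "other")
LAND_USES <- c("cropland", "grassland", "forest")

#' Land portfolio of a farm
#'
#' Areas by management type plus land-use conversions. Forest is excluded as
#' a holding but may appear in conversions. Farm area (the denominator of
#' CF per hectare) is cropland (both managements) + grassland + built-up.
#'
#' @param cropland_tillage_ha,cropland_no_till_ha,grassland_ha,builtup_ha
#'   Areas in hectares.
#' @param conversions A data frame with columns `from_use`, `to_use`,
#'   `area_ha`; uses drawn from cropland/grassland/forest.
#' @return A list of class `land_portfolio`.
#' @export
land_portfolio <- function(cropland_tillage_ha = 0, cropland_no_till_ha = 0,
                           grassland_ha = 0, builtup_ha = 0,
                           conversions = NULL) {
  conversions <- conversions %||%
    tibble::tibble(from_use = character(), to_use = character(),
                   area_ha = double())
  conversions <- tibble::as_tibble(conversions)
  areas <- c(cropland_tillage_ha, cropland_no_till_ha, grassland_ha,
             builtup_ha, conversions$area_ha)
  check_nonneg(areas, "Land areas")
  bad <- !(conversions$from_use %in% LAND_USES &
             conversions$to_use %in% LAND_USES)
  if (any(bad)) {
    cf_abort(paste0("Unknown land use in conversion '",
                    conversions$from_use[bad][1], "' -> '",
                    conversions$to_use[bad][1], "'."),
             "farmcf_validation_error")
  }
  structure(list(cropland_tillage_ha = cropland_tillage_ha,
                 cropland_no_till_ha = cropland_no_till_ha,
                 grassland_ha = grassland_ha, builtup_ha = builtup_ha,
                 conversions = conversions),
            class = "land_portfolio")
}

#' @rdname land_portfolio
#' @param land A `land_portfolio` or `farm_record`.
#' @export
area_ha <- function(land) {
  if (inherits(land, "farm_record")) land <- land$land
  land$cropland_tillage_ha + land$cropland_no_till_ha +
    land$grassland_ha + land$builtup_ha
}

empty_livestock <- function() {
  tibble::as_tibble(c(list(category = character(), heads = double()),
                      stats::setNames(rep(list(double()), 5),
                                      MANURE_SYSTEMS)))
}
empty_nitrogen <- function() tibble::tibble(source = character(), n_kg = double())
empty_fuels <- function() tibble::tibble(fuel = character(), quantity = double(),
                                         unit = character())
empty_refrigerants <- function() tibble::tibble(code = character(),
                                                mass_kg = double())
empty_energy <- function() tibble::tibble(carrier = character(),
                                          quantity_kwh = double())
empty_purchases <- function() tibble::tibble(group = character(),
                                             item = character(),
                                             quantity = double(),
                                             unit = character(),
                                             year = integer())
empty_capital <- function() tibble::tibble(item = character(), count = double(),
                                           lifespan_years = double())
empty_waste_offsite <- function() tibble::tibble(item = character(),
                                                 quantity = double(),
                                                 unit = character())

default_waste_onsite <- function() {
  list(composted_t = 0, wastewater_cod_kg = 0,
       biogas_ch4_kg = 0, biogas_certified = FALSE)
}

#' Construct a farm record
#'
#' Bundles one farm's characteristics (turnover, employees, land) with all
#' annual activity inputs the calculation engines consume. All activity
#' tables default to empty (zero activity); invariants (non-negative
#' quantities, manure allocations summing to 1, known enum levels) are
#' validated on construction.
#'
#' @param farm_id Character identifier.
#' @param turnover_keur Annual turnover in thousand EUR.
#' @param employees Number of employees (>= 0; >= 1 required for the
#'   per-employee intensity).
#' @param land A [land_portfolio()].
#' @param livestock Tibble: `category`, `heads`, and one allocation column
#'   per manure system (`anaerobic_digester`, `liquid_storage`,
#'   `solid_storage`, `daily_spread`, `pasture`) summing to 1 per row.
#' @param nitrogen Tibble: `source` (one of the recognised N sources),
#'   `n_kg` applied per year.
#' @param fuels Tibble: `fuel`, `quantity`, `unit`.
#' @param refrigerants Tibble: `code`, `mass_kg` leaked per year.
#' @param energy Tibble: `carrier` (electricity/heat/cold), `quantity_kwh`.
#' @param purchases Tibble: `group`, `item`, `quantity`, `unit`, `year`.
#' @param capital Tibble: `item`, `count` in stock, `lifespan_years`.
#' @param waste_onsite List: `composted_t`, `wastewater_cod_kg`,
#'   `biogas_ch4_kg` (gross CH4 production), `biogas_certified`.
#' @param waste_offsite Tibble: `item` (a waste fraction or `"wastewater"`),
#'   `quantity`, `unit` (`"t"` for fractions, `"kg COD"` for wastewater).
#' @return A list of class `farm_record`.
#' @export
farm_record <- function(farm_id, turnover_keur, employees,
                        land = land_portfolio(),
                        livestock = empty_livestock(),
                        nitrogen = empty_nitrogen(),
                        fuels = empty_fuels(),
                        refrigerants = empty_refrigerants(),
                        energy = empty_energy(),
                        purchases = empty_purchases(),
                        capital = empty_capital(),
                        waste_onsite = default_waste_onsite(),
                        waste_offsite = empty_waste_offsite()) {
  farm <- structure(
    list(farm_id = as.character(farm_id),
         turnover_keur = as.numeric(turnover_keur),
         employees = as.numeric(employees),
         land = land,
         livestock = tibble::as_tibble(livestock),
         nitrogen = tibble::as_tibble(nitrogen),
         fuels = tibble::as_tibble(fuels),
         refrigerants = tibble::as_tibble(refrigerants),
         energy = tibble::as_tibble(energy),
         purchases = tibble::as_tibble(purchases),
         capital = tibble::as_tibble(capital),
         waste_onsite = utils::modifyList(default_waste_onsite(),
                                          waste_onsite),
         waste_offsite = tibble::as_tibble(waste_offsite)),
    class = "farm_record")
  validate_farm_record(farm)
  farm
}

validate_farm_record <- function(farm) {
  if (length(farm$farm_id) != 1 || is.na(farm$farm_id) ||
      !nzchar(farm$farm_id)) {
    cf_abort("farm_id must be a non-empty string.", "farmcf_validation_error")
  }
  check_nonneg(farm$turnover_keur, "Turnover")
  check_nonneg(farm$employees, "Employees")
  if (!inherits(farm$land, "land_portfolio")) {
    cf_abort("`land` must be a land_portfolio.", "farmcf_validation_error")
  }

  ls <- farm$livestock
  need <- c("category", "heads", MANURE_SYSTEMS)
  if (!all(need %in% names(ls))) {
    cf_abort(paste0("livestock table must have columns ",
                    paste(need, collapse = ", "), "."),
             "farmcf_validation_error")
  }
  check_nonneg(ls$heads, "Livestock heads")
  check_nonneg(unlist(ls[MANURE_SYSTEMS]), "Manure allocation fractions")
  if (nrow(ls) > 0) {
    alloc <- rowSums(as.matrix(ls[MANURE_SYSTEMS]))
    bad <- ls$heads > 0 & abs(alloc - 1) > 1e-9
    if (any(bad)) {
      j <- which(bad)[1]
      cf_abort(paste0("Manure allocation for category '", ls$category[j],
                      "' sums to ", format(alloc[j]), "; must sum to 1."),
               "farmcf_validation_error")
    }
  }

  if (nrow(farm$nitrogen) > 0) {
    bad <- !farm$nitrogen$source %in% N_SOURCES
    if (any(bad)) {
      cf_abort(paste0("Unknown nitrogen source '",
                      farm$nitrogen$source[bad][1], "'."),
               "farmcf_validation_error")
    }
    check_nonneg(farm$nitrogen$n_kg, "Applied nitrogen")
  }
  if (nrow(farm$fuels) > 0) {
    bad <- !farm$fuels$fuel %in% FUEL_TYPES
    if (any(bad)) {
      cf_abort(paste0("Unknown fuel '", farm$fuels$fuel[bad][1], "'."),
               "farmcf_validation_error")
    }
    check_nonneg(farm$fuels$quantity, "Fuel quantity")
  }
  check_nonneg(farm$refrigerants$mass_kg, "Refrigerant leakage")
  if (nrow(farm$energy) > 0) {
    bad <- !farm$energy$carrier %in% ENERGY_CARRIERS
    if (any(bad)) {
      cf_abort(paste0("Unknown energy carrier '",
                      farm$energy$carrier[bad][1], "'."),
               "farmcf_validation_error")
    }
    check_nonneg(farm$energy$quantity_kwh, "Purchased energy")
  }
  if (nrow(farm$purchases) > 0) {
    bad <- !farm$purchases$group %in% PURCHASE_GROUPS
    if (any(bad)) {
      cf_abort(paste0("Unknown purchase group '",
                      farm$purchases$group[bad][1], "'."),
               "farmcf_validation_error")
    }
    check_nonneg(farm$purchases$quantity, "Purchase quantity")
  }
  if (nrow(farm$capital) > 0) {
    check_nonneg(farm$capital$count, "Capital item count")
    life <- farm$capital$lifespan_years
    if (any(!is.finite(life)) || any(life < 1) || any(life != round(life))) {
      cf_abort("Capital lifespan_years must be an integer >= 1.",
               "farmcf_validation_error")
    }
  }
  wo <- farm$waste_onsite
  check_nonneg(c(wo$composted_t, wo$wastewater_cod_kg, wo$biogas_ch4_kg),
               "On-site waste quantities")
  if (!is.logical(wo$biogas_certified) || length(wo$biogas_certified) != 1) {
    cf_abort("biogas_certified must be a single logical.",
             "farmcf_validation_error")
  }
  if (nrow(farm$waste_offsite) > 0) {
    bad <- !farm$waste_offsite$item %in% c(WASTE_FRACTIONS, "wastewater")
    if (any(bad)) {
      cf_abort(paste0("Unknown off-site waste fraction '",
                      farm$waste_offsite$item[bad][1], "'."),
               "farmcf_validation_error")
    }
    check_nonneg(farm$waste_offsite$quantity, "Off-site waste quantity")
  }
  invisible(farm)
}

#' @export
print.farm_record <- function(x, ...) {
  cat("<farm_record> ", x$farm_id, "\n", sep = "")
  cat("  turnover: ", x$turnover_keur, " kEUR;  area: ", area_ha(x),
      " ha;  employees: ", x$employees, "\n", sep = "")
  act <- c(livestock = nrow(x$livestock), nitrogen = nrow(x$nitrogen),
           fuels = nrow(x$fuels), refrigerants = nrow(x$refrigerants),
           energy = nrow(x$energy), purchases = nrow(x$purchases),
           capital = nrow(x$capital), waste_offsite = nrow(x$waste_offsite))
  cat("  activity rows:", paste(names(act), act, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
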