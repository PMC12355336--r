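# Shared fixtures: tiny registries and farm records built in code.

test_gwp <- function() gwp_table("R-404A" = 3943, "TESTGAS" = 1000)

# Minimal registry builder: rows given as list(process, item, gas, factor, unit)
mini_registry <- function(..., strict = TRUE) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(process = r[[1]], item = r[[2]], gas = r[[3]],
               factor = as.numeric(r[[4]]),
               unit = if (length(r) >= 5) r[[5]] else "x",
               source = "test")
  }))
  as_registry(df, strict = strict)
}

# One livestock row with a named manure allocation.
livestock_row <- function(category = "dairy_cattle", heads = 1,
                          liquid_storage = 0, solid_storage = 0,
                          anaerobic_digester = 0, daily_spread = 0,
                          pasture = 0) {
  tibble::tibble(category = category, heads = heads,
                 anaerobic_digester = anaerobic_digester,
                 liquid_storage = liquid_storage,
                 solid_storage = solid_storage,
                 daily_spread = daily_spread, pasture = pasture)
}

zero_farm <- function(id = "zero") farm_record(id, 100, 1)

empty_purch <- function() {
  tibble::tibble(group = character(), item = character(),
                 quantity = double(), unit = character(), year = integer())
}
empty_cap <- function() {
  tibble::tibble(item = character(), count = double(),
                 lifespan_years = double())
}
empty_offsite <- function() {
  tibble::tibble(item = character(), quantity = double(),
                 unit = character())
}

# A farm exercising every engine, against the illustrative registry.
full_farm <- function(id = "full") {
  farm_record(
    id, turnover_keur = 500, employees = 5,
    land = land_portfolio(
      cropland_tillage_ha = 100, cropland_no_till_ha = 20,
      grassland_ha = 50, builtup_ha = 5,
      conversions = tibble::tibble(from_use = "grassland",
                                   to_use = "cropland", area_ha = 2)),
    livestock = livestock_row(heads = 40, liquid_storage = 0.73,
                              solid_storage = 0.27),
    nitrogen = tibble::tibble(
      source = c("synthetic_fertilizer", "compost"), n_kg = c(5000, 1000)),
    fuels = tibble::tibble(fuel = c("diesel", "petrol"),
                           quantity = c(8000, 500), unit = "L"),
    refrigerants = tibble::tibble(code = "R-404A", mass_kg = 2),
    energy = tibble::tibble(carrier = c("electricity", "heat"),
                            quantity_kwh = c(30000, 10000)),
    purchases = tibble::tibble(
      group = c("animal_inputs", "crop_inputs", "packaging"),
      item = c("industrial_feed", "seeds", "plastic"),
      quantity = c(60, 3, 0.5), unit = "t", year = 2022L),
    capital = tibble::tibble(item = c("tractor", "computer"),
                             count = c(2, 5), lifespan_years = c(12, 5)),
    waste_onsite = list(composted_t = 12, wastewater_cod_kg = 300,
                        biogas_ch4_kg = 4000, biogas_certified = FALSE),
    waste_offsite = tibble::tibble(
      item = c("municipal", "plastic", "wastewater"),
      quantity = c(6, 1, 200), unit = c("t", "t", "kg COD"))
  )
}

# Spearman definition oracle: average ranks by explicit counting, Pearson
# by the definitional sum formula. Independent of rank()/cor().
oracle_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; eq <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) eq <- eq + 1
    }
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Independent brute-force footprint oracle: explicit per-record loops over
# the raw registry data frame, no engine code shared.
oracle_flow_totals <- function(farm, registry, gwp) {
  fac <- function(p, i, g) {
    hit <- registry$factor[registry$process == p & registry$item == i &
                             registry$gas == g]
    if (length(hit) != 1) stop("oracle: missing factor ", p, "/", i, "/", g)
    hit
  }
  gw <- function(g) unclass(gwp)[[g]]
  out <- stats::setNames(numeric(10), c(
    "ENTERIC_FERMENTATION", "MANURE_MANAGEMENT", "FERTILIZER_USE",
    "ENERGY_USE", "INPUTS_CROP", "INPUTS_ANIMAL", "INPUTS_OTHER",
    "OTHER_FARM_ACTIVITIES", "WASTE_WASTEWATER", "CARBON_SINKS"))
  systems <- c("anaerobic_digester", "liquid_storage", "solid_storage",
               "daily_spread", "pasture")
  for (i in seq_len(nrow(farm$livestock))) {
    r <- farm$livestock[i, ]
    out["ENTERIC_FERMENTATION"] <- out["ENTERIC_FERMENTATION"] +
      r$heads * fac("ENTERIC", r$category, "CH4") * gw("CH4")
    for (s in systems) {
      if (r[[s]] == 0 || r$heads == 0) next
      it <- paste0(r$category, ":", s)
      out["MANURE_MANAGEMENT"] <- out["MANURE_MANAGEMENT"] +
        r$heads * r[[s]] * (fac("MANURE", it, "CH4") * gw("CH4") +
                              fac("MANURE", it, "N2O") * gw("N2O"))
    }
  }
  for (i in seq_len(nrow(farm$nitrogen))) {
    r <- farm$nitrogen[i, ]
    out["FERTILIZER_USE"] <- out["FERTILIZER_USE"] +
      r$n_kg * fac("SOIL_N2O", r$source, "N2O") * (44 / 28) * gw("N2O")
  }
  for (i in seq_len(nrow(farm$fuels))) {
    r <- farm$fuels[i, ]
    for (g in c("CO2", "CH4", "N2O")) {
      out["ENERGY_USE"] <- out["ENERGY_USE"] +
        r$quantity * fac("FUEL", r$fuel, g) * gw(g)
    }
  }
  for (i in seq_len(nrow(farm$energy))) {
    r <- farm$energy[i, ]
    for (g in c("CO2", "CH4", "N2O")) {
      out["ENERGY_USE"] <- out["ENERGY_USE"] +
        r$quantity_kwh * fac("ENERGY_S2", r$carrier, g) * gw(g)
    }
  }
  for (i in seq_len(nrow(farm$refrigerants))) {
    r <- farm$refrigerants[i, ]
    out["OTHER_FARM_ACTIVITIES"] <- out["OTHER_FARM_ACTIVITIES"] +
      r$mass_kg * gw(r$code)
  }
  wo <- farm$waste_onsite
  if (wo$composted_t > 0) {
    out["WASTE_WASTEWATER"] <- out["WASTE_WASTEWATER"] +
      wo$composted_t * (fac("COMPOST", "composted_waste", "CH4") * gw("CH4") +
                          fac("COMPOST", "composted_waste", "N2O") * gw("N2O"))
  }
  if (wo$biogas_ch4_kg > 0 && !wo$biogas_certified) {
    out["WASTE_WASTEWATER"] <- out["WASTE_WASTEWATER"] +
      0.05 * wo$biogas_ch4_kg * gw("CH4")
  }
  if (wo$wastewater_cod_kg > 0) {
    out["WASTE_WASTEWATER"] <- out["WASTE_WASTEWATER"] +
      wo$wastewater_cod_kg * fac("WASTEWATER", "cod", "CH4") * gw("CH4")
  }
  for (i in seq_len(nrow(farm$purchases))) {
    r <- farm$purchases[i, ]
    flow <- switch(r$group, crop_inputs = "INPUTS_CROP",
                   animal_inputs = "INPUTS_ANIMAL", "INPUTS_OTHER")
    out[flow] <- out[flow] + r$quantity * fac("INPUT", r$item, "CO2eq")
  }
  for (i in seq_len(nrow(farm$capital))) {
    r <- farm$capital[i, ]
    out["INPUTS_OTHER"] <- out["INPUTS_OTHER"] +
      r$count * fac("CAPITAL", r$item, "CO2eq") / r$lifespan_years
  }
  for (i in seq_len(nrow(farm$waste_offsite))) {
    r <- farm$waste_offsite[i, ]
    if (r$item == "wastewater") {
      out["WASTE_WASTEWATER"] <- out["WASTE_WASTEWATER"] +
        r$quantity * fac("WASTEWATER", "cod", "CH4") * gw("CH4")
    } else {
      out["WASTE_WASTEWATER"] <- out["WASTE_WASTEWATER"] +
        r$quantity * fac("WASTE_OFFSITE", r$item, "CO2eq")
    }
  }
  uses <- c(cropland_tillage = farm$land$cropland_tillage_ha,
            cropland_no_till = farm$land$cropland_no_till_ha,
            grassland = farm$land$grassland_ha,
            builtup = farm$land$builtup_ha)
  for (u in names(uses)) {
    if (uses[[u]] == 0) next
    out["CARBON_SINKS"] <- out["CARBON_SINKS"] -
      uses[[u]] * fac("SINK", u, "CO2") * (44 / 12)
  }
  for (i in seq_len(nrow(farm$land$conversions))) {
    r <- farm$land$conversions[i, ]
    out["CARBON_SINKS"] <- out["CARBON_SINKS"] -
      r$area_ha * fac("SINK_CONVERSION",
                      paste0(r$from_use, "_to_", r$to_use), "CO2") * (44 / 12)
  }
  out
}
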