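# Scope 1 engines: direct emissions and carbon sinks.

test_that("enteric fermentation is heads x factor, converted at GWP 28", {
  reg <- mini_registry(list("ENTERIC", "dairy_cattle", "CH4", 100, "head"),
                       list("ENTERIC", "sheep", "CH4", 8, "head"))
  led <- enteric_fermentation(livestock_row(heads = 10, pasture = 1), reg)
  expect_equal(sum(led$mass_kg), 1000)
  expect_equal(sum(led$co2eq_kg), 28000)

  expect_equal(nrow(enteric_fermentation(livestock_row()[0, ], reg)), 0)

  # two categories: equals an explicit per-entry sum
  ls <- dplyr::bind_rows(livestock_row(heads = 7, pasture = 1),
                         livestock_row("sheep", heads = 30, pasture = 1))
  led2 <- enteric_fermentation(ls, reg)
  expect_equal(sum(led2$co2eq_kg), (7 * 100 + 30 * 8) * 28)
})

test_that("manure management splits heads over systems with per-gas factors", {
  reg <- mini_registry(
    list("MANURE", "dairy_cattle:liquid_storage", "CH4", 20, "head"),
    list("MANURE", "dairy_cattle:liquid_storage", "N2O", 0, "head"),
    list("MANURE", "dairy_cattle:solid_storage", "CH4", 2, "head"),
    list("MANURE", "dairy_cattle:solid_storage", "N2O", 0, "head"))
  led <- manure_management(livestock_row(heads = 100, liquid_storage = 1),
                           reg)
  expect_equal(sum(led$co2eq_kg), 56000)

  # registry encodes an order-of-magnitude liquid vs solid gap per head
  liq <- manure_management(livestock_row(heads = 1, liquid_storage = 1), reg)
  sol <- manure_management(livestock_row(heads = 1, solid_storage = 1), reg)
  expect_equal(sum(liq$co2eq_kg) / sum(sol$co2eq_kg), 10)

  # mixed allocation equals the fraction-weighted sum of the two systems
  mix <- manure_management(
    livestock_row(heads = 50, liquid_storage = 0.73, solid_storage = 0.27),
    reg)
  expect_equal(sum(mix$co2eq_kg),
               50 * (0.73 * sum(liq$co2eq_kg) + 0.27 * sum(sol$co2eq_kg)))

  expect_equal(nrow(manure_management(livestock_row(heads = 0), reg)), 0)
  expect_error(
    manure_management(livestock_row(heads = 5, liquid_storage = 0.7,
                                    solid_storage = 0.2), reg),
    "sum to 1", class = "farmcf_validation_error")
})

test_that("soil N2O applies the 44/28 N2O-N conversion and GWP 265", {
  reg <- mini_registry(list("SOIL_N2O", "synthetic_fertilizer", "N2O", 0.01,
                            "kg N"),
                       list("SOIL_N2O", "compost", "N2O", 0.01, "kg N"))
  led <- soil_n2o(tibble::tibble(source = "synthetic_fertilizer",
                                 n_kg = 1000), reg)
  expect_equal(sum(led$mass_kg), 1000 * 0.01 * 44 / 28)
  expect_equal(sum(led$co2eq_kg), 1000 * 0.01 * (44 / 28) * 265)

  expect_equal(nrow(soil_n2o(tibble::tibble(source = character(),
                                            n_kg = double()), reg)), 0)
  two <- soil_n2o(tibble::tibble(
    source = c("synthetic_fertilizer", "compost"), n_kg = c(600, 400)), reg)
  expect_equal(sum(two$co2eq_kg), (600 + 400) * 0.01 * (44 / 28) * 265)
  expect_error(soil_n2o(tibble::tibble(source = "compost", n_kg = -1), reg),
               class = "farmcf_validation_error")
})

test_that("indirect soil-N2O pathways are added only when the registry has them", {
  base <- list("SOIL_N2O", "synthetic_fertilizer", "N2O", 0.01, "kg N")
  reg0 <- mini_registry(base)
  reg1 <- mini_registry(
    base,
    list("SOIL_N2O_INDIRECT", "volatilization", "N2O", 0.001, "kg N"),
    list("SOIL_N2O_INDIRECT", "leaching", "N2O", 0.002, "kg N"))
  apps <- tibble::tibble(source = "synthetic_fertilizer", n_kg = 1000)
  expect_equal(sum(soil_n2o(apps, reg0)$co2eq_kg),
               1000 * 0.01 * (44 / 28) * 265)
  expect_equal(sum(soil_n2o(apps, reg1)$co2eq_kg),
               1000 * (0.01 + 0.001 + 0.002) * (44 / 28) * 265)
})

test_that("fuel combustion emits per-gas masses and checks units", {
  reg <- mini_registry(list("FUEL", "diesel", "CO2", 2.7, "L"),
                       list("FUEL", "diesel", "CH4", 0, "L"),
                       list("FUEL", "diesel", "N2O", 0, "L"),
                       list("FUEL", "petrol", "CO2", 2.3, "L"),
                       list("FUEL", "petrol", "CH4", 0, "L"),
                       list("FUEL", "petrol", "N2O", 0, "L"))
  led <- fuel_combustion(tibble::tibble(fuel = "diesel", quantity = 1000,
                                        unit = "L"), reg)
  expect_equal(sum(led$co2eq_kg), 2700)

  expect_equal(nrow(fuel_combustion(tibble::tibble(
    fuel = character(), quantity = double(), unit = character()), reg)), 0)

  both <- fuel_combustion(tibble::tibble(fuel = c("diesel", "petrol"),
                                         quantity = c(1000, 200),
                                         unit = "L"), reg)
  expect_equal(sum(both$co2eq_kg), 1000 * 2.7 + 200 * 2.3)

  err <- expect_error(
    fuel_combustion(tibble::tibble(fuel = "diesel", quantity = 1,
                                   unit = "kg"), reg),
    class = "farmcf_unit_error")
  expect_match(conditionMessage(err), "diesel")
  expect_match(conditionMessage(err), "kg")
  expect_match(conditionMessage(err), "L")
})

test_that("refrigerant leakage uses the refrigerant's own GWP", {
  gwp <- test_gwp()
  led <- refrigerant_emissions(tibble::tibble(code = "TESTGAS",
                                              mass_kg = 10), gwp)
  expect_equal(sum(led$co2eq_kg), 10000)
  expect_equal(nrow(refrigerant_emissions(tibble::tibble(
    code = character(), mass_kg = double()), gwp)), 0)
  two <- refrigerant_emissions(tibble::tibble(
    code = c("TESTGAS", "R-404A"), mass_kg = c(1, 2)), gwp)
  expect_equal(sum(two$co2eq_kg), 1000 + 2 * 3943)
  expect_error(refrigerant_emissions(tibble::tibble(code = "R-999",
                                                    mass_kg = 1), gwp),
               "R-999", class = "farmcf_missing_gwp")
})

test_that("biogas leaks 5% of production unless certified", {
  reg <- mini_registry(list("WASTEWATER", "cod", "CH4", 0.25, "kg COD"))
  uncert <- onsite_waste_emissions(
    list(biogas_ch4_kg = 10000, biogas_certified = FALSE), reg)
  expect_equal(sum(uncert$mass_kg), 500)
  expect_equal(sum(uncert$co2eq_kg), 14000)

  cert <- onsite_waste_emissions(
    list(biogas_ch4_kg = 10000, biogas_certified = TRUE), reg)
  expect_equal(sum(cert$co2eq_kg), 0)

  expect_equal(nrow(onsite_waste_emissions(list(), reg)), 0)
})

test_that("composting and wastewater emissions scale with their loads", {
  reg <- mini_registry(list("COMPOST", "composted_waste", "CH4", 4, "t"),
                       list("COMPOST", "composted_waste", "N2O", 0.12, "t"),
                       list("WASTEWATER", "cod", "CH4", 0.25, "kg COD"))
  led <- onsite_waste_emissions(
    list(composted_t = 10, wastewater_cod_kg = 400), reg)
  expect_equal(sum(led$co2eq_kg),
               10 * (4 * 28 + 0.12 * 265) + 400 * 0.25 * 28)
})

test_that("carbon sinks convert stored carbon at -44/12", {
  reg <- mini_registry(
    list("SINK", "cropland_no_till", "CO2", 60, "kg C per ha per yr"),
    list("SINK_CONVERSION", "grassland_to_cropland", "CO2", -500,
         "kg C per ha conversion"))
  led <- carbon_sinks(land_portfolio(cropland_no_till_ha = 100), reg)
  expect_equal(sum(led$co2eq_kg), -100 * 60 * 44 / 12)  # -22000

  expect_equal(nrow(carbon_sinks(land_portfolio(), reg)), 0)

  # a carbon-losing conversion flips sign into a positive emission
  conv <- carbon_sinks(land_portfolio(conversions = tibble::tibble(
    from_use = "grassland", to_use = "cropland", area_ha = 3)), reg)
  expect_equal(sum(conv$co2eq_kg), 3 * 500 * 44 / 12)

  # missing factor for a nonzero area is a strict error
  expect_error(carbon_sinks(land_portfolio(grassland_ha = 1), reg),
               class = "farmcf_missing_factor")
})

test_that("every Scope 1 engine returns exactly zero on zero activity", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  fp <- assemble_footprint(zero_farm(), reg, gwp)
  expect_identical(unname(fp$flow_totals), rep(0, 10))
  expect_identical(fp$total_cf, 0)
})

test_that("engines are homogeneous of degree 1 in activity quantities", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  f1 <- full_farm()
  k <- 2.5
  f2 <- farm_record(
    "scaled", f1$turnover_keur, f1$employees,
    land = land_portfolio(
      k * f1$land$cropland_tillage_ha, k * f1$land$cropland_no_till_ha,
      k * f1$land$grassland_ha, k * f1$land$builtup_ha,
      conversions = dplyr::mutate(f1$land$conversions,
                                  area_ha = k * area_ha)),
    livestock = dplyr::mutate(f1$livestock, heads = k * heads),
    nitrogen = dplyr::mutate(f1$nitrogen, n_kg = k * n_kg),
    fuels = dplyr::mutate(f1$fuels, quantity = k * quantity),
    refrigerants = dplyr::mutate(f1$refrigerants, mass_kg = k * mass_kg),
    energy = dplyr::mutate(f1$energy, quantity_kwh = k * quantity_kwh),
    purchases = dplyr::mutate(f1$purchases, quantity = k * quantity),
    capital = dplyr::mutate(f1$capital, count = k * count),
    waste_onsite = list(composted_t = k * 12, wastewater_cod_kg = k * 300,
                        biogas_ch4_kg = k * 4000, biogas_certified = FALSE),
    waste_offsite = dplyr::mutate(f1$waste_offsite, quantity = k * quantity))
  fp1 <- assemble_footprint(f1, reg, gwp)
  fp2 <- assemble_footprint(f2, reg, gwp)
  expect_equal(fp2$flow_totals, k * fp1$flow_totals, tolerance = 1e-12)
})

test_that("flows match an independent per-record loop oracle", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  farm <- full_farm()
  fp <- assemble_footprint(farm, reg, gwp)
  expect_equal(fp$flow_totals, oracle_flow_totals(farm, reg, gwp),
               tolerance = 1e-9)
})
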