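# Footprint assembly, relative CFs, SoAH and shares.

test_that("total CF follows the scope formula", {
  # S1_gross 100 t, S2 20 t, S3 inputs 30 t, S3 waste 10 t, sinks 15 t
  reg <- mini_registry(
    list("FUEL", "diesel", "CO2", 1, "L"),
    list("FUEL", "diesel", "CH4", 0, "L"),
    list("FUEL", "diesel", "N2O", 0, "L"),
    list("ENERGY_S2", "electricity", "CO2", 1, "kWh"),
    list("ENERGY_S2", "electricity", "CH4", 0, "kWh"),
    list("ENERGY_S2", "electricity", "N2O", 0, "kWh"),
    list("INPUT", "seeds", "CO2eq", 1000, "t"),
    list("WASTE_OFFSITE", "municipal", "CO2eq", 1000, "t"),
    list("SINK", "grassland", "CO2", 15000 * 12 / 44,
         "kg C per ha per yr"))
  farm <- farm_record(
    "formula", 100, 1,
    land = land_portfolio(grassland_ha = 1),
    fuels = tibble::tibble(fuel = "diesel", quantity = 100000, unit = "L"),
    energy = tibble::tibble(carrier = "electricity", quantity_kwh = 20000),
    purchases = tibble::tibble(group = "crop_inputs", item = "seeds",
                               quantity = 30, unit = "t", year = 2022L),
    waste_offsite = tibble::tibble(item = "municipal", quantity = 10,
                                   unit = "t"))
  fp <- assemble_footprint(farm, reg)
  expect_equal(unname(fp$scope_totals),
               c(100000, -15000, 20000, 30000, 10000))
  expect_equal(fp$total_cf, 145000)
  # the same total is the signed sum over the ten flows
  expect_equal(sum(fp$flow_totals), fp$total_cf)
})

test_that("an all-zero farm yields a zero footprint and flows", {
  fp <- assemble_footprint(zero_farm(), illustrative_registry())
  expect_equal(fp$total_cf, 0)
  expect_true(all(fp$flows$co2eq_kg == 0))
})

test_that("engine errors gain farm context", {
  reg <- mini_registry(list("FUEL", "diesel", "CO2", 1, "L"))
  farm <- farm_record("broken-farm", 1, 1,
                      livestock = livestock_row(heads = 1, pasture = 1))
  err <- expect_error(assemble_footprint(farm, reg),
                      class = "farmcf_missing_factor")
  expect_match(conditionMessage(err), "broken-farm")
})

test_that("relative CFs reproduce the pilot farms' printed intensities", {
  # Farm 2: CF/turnover 4557 kg/kEUR, turnover 577.4 kEUR, area 356 ha
  rel <- cf_intensities(4557 * 577.4, turnover_keur = 577.4, area_ha = 356,
                        employees = 9)
  expect_equal(rel$cf_per_turnover, 4557)
  expect_equal(rel$cf_per_area, 7397, tolerance = 0.005)
  # Farm 4: 427 kg/kEUR, turnover 958.9, 12 employees -> 34 t/employee
  rel4 <- cf_intensities(427 * 958.9, 958.9, 176, 12)
  expect_equal(round(rel4$cf_per_employee / 1000), 34)
  # zero total -> all zero
  rel0 <- cf_intensities(0, 100, 10, 2)
  expect_equal(unlist(rel0), c(cf_per_turnover = 0, cf_per_area = 0,
                               cf_per_employee = 0))
})

test_that("non-positive denominators leave only that indicator undefined", {
  expect_warning(rel <- cf_intensities(1000, 0, 10, 2),
                 class = "farmcf_undefined_indicator")
  expect_true(is.na(rel$cf_per_turnover))
  expect_equal(rel$cf_per_area, 100)
  expect_equal(rel$cf_per_employee, 500)
})

test_that("cross-indicator identity ties intensities back to the total", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  farm <- full_farm()
  fp <- assemble_footprint(farm, reg, gwp)
  rel <- relative_cfs(fp, farm)
  expect_equal(rel$cf_per_turnover * farm$turnover_keur, fp$total_cf)
  expect_equal(rel$cf_per_area * area_ha(farm), fp$total_cf)
  expect_equal(rel$cf_per_employee * farm$employees, fp$total_cf)
})

test_that("SoAH is the animal-flow share of the total", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  # crop-only farm: no livestock, no animal inputs -> exactly 0
  crop <- farm_record("crop", 100, 2,
                      nitrogen = tibble::tibble(source = "compost",
                                                n_kg = 2000),
                      fuels = tibble::tibble(fuel = "diesel",
                                             quantity = 1000, unit = "L"))
  expect_identical(soah(assemble_footprint(crop, reg, gwp)), 0)

  # mixed farm: SoAH equals the hand-computed flow ratio
  fp <- assemble_footprint(full_farm(), reg, gwp)
  ft <- fp$flow_totals
  expect_equal(soah(fp),
               unname((ft["ENTERIC_FERMENTATION"] + ft["MANURE_MANAGEMENT"] +
                         ft["INPUTS_ANIMAL"]) / fp$total_cf))
  expect_gt(soah(fp), 0)
  expect_lt(soah(fp), 1)

  # pure animal operation: numerator equals total -> 1
  pure <- farm_record("pure", 100, 1,
                      livestock = livestock_row(heads = 10,
                                                liquid_storage = 1))
  expect_equal(soah(assemble_footprint(pure, reg, gwp)), 1)

  expect_error(soah(assemble_footprint(zero_farm(), reg, gwp)),
               class = "farmcf_undefined_indicator")
})

test_that("SoAH is invariant under uniform scaling of all activities", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  f1 <- full_farm()
  fp1 <- assemble_footprint(f1, reg, gwp)
  f2 <- f1
  f2$livestock$heads <- 3 * f2$livestock$heads
  f2$nitrogen$n_kg <- 3 * f2$nitrogen$n_kg
  f2$fuels$quantity <- 3 * f2$fuels$quantity
  f2$refrigerants$mass_kg <- 3 * f2$refrigerants$mass_kg
  f2$energy$quantity_kwh <- 3 * f2$energy$quantity_kwh
  f2$purchases$quantity <- 3 * f2$purchases$quantity
  f2$capital$count <- 3 * f2$capital$count
  f2$waste_onsite$composted_t <- 3 * f2$waste_onsite$composted_t
  f2$waste_onsite$wastewater_cod_kg <- 3 * f2$waste_onsite$wastewater_cod_kg
  f2$waste_onsite$biogas_ch4_kg <- 3 * f2$waste_onsite$biogas_ch4_kg
  f2$waste_offsite$quantity <- 3 * f2$waste_offsite$quantity
  f2$land$cropland_tillage_ha <- 3 * f2$land$cropland_tillage_ha
  f2$land$cropland_no_till_ha <- 3 * f2$land$cropland_no_till_ha
  f2$land$grassland_ha <- 3 * f2$land$grassland_ha
  f2$land$builtup_ha <- 3 * f2$land$builtup_ha
  f2$land$conversions$area_ha <- 3 * f2$land$conversions$area_ha
  fp2 <- assemble_footprint(f2, reg, gwp)
  expect_equal(soah(fp2), soah(fp1), tolerance = 1e-12)
})

test_that("flow shares are signed and scope shares sum to 1", {
  # flows {80, 40, sinks -20}, total 100
  reg <- mini_registry(
    list("FUEL", "diesel", "CO2", 1, "L"),
    list("FUEL", "diesel", "CH4", 0, "L"),
    list("FUEL", "diesel", "N2O", 0, "L"),
    list("WASTE_OFFSITE", "municipal", "CO2eq", 1000, "t"),
    list("SINK", "grassland", "CO2", 20 * 12 / 44, "kg C per ha per yr"))
  farm <- farm_record(
    "shares", 10, 1, land = land_portfolio(grassland_ha = 1),
    fuels = tibble::tibble(fuel = "diesel", quantity = 80, unit = "L"),
    waste_offsite = tibble::tibble(item = "municipal", quantity = 0.04,
                                   unit = "t"))
  fp <- assemble_footprint(farm, reg)
  sh <- cf_shares(fp)
  expect_equal(unname(sh$flow_shares["ENERGY_USE"]), 0.8)
  expect_equal(unname(sh$flow_shares["WASTE_WASTEWATER"]), 0.4)
  expect_equal(unname(sh$flow_shares["CARBON_SINKS"]), -0.2)
  expect_equal(sum(sh$flow_shares), 1)
  expect_equal(sum(sh$flow_shares[sh$flow_shares > 0]), 1.2)
  expect_equal(sum(sh$scope_shares), 1)

  # gross convention reports Scope 1 gross plus a separate sink share
  shg <- cf_shares(fp, convention = "gross")
  expect_equal(unname(shg$scope_shares[["S1"]]), 0.8)
  expect_equal(unname(sh$scope_shares[["S1"]]), 0.6)  # net of sinks
  expect_equal(unname(shg$scope_shares[["sinks"]]), -0.2)
  expect_equal(sum(shg$scope_shares), 1)
})

test_that("without sinks the positive flow shares sum to exactly 1", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  farm <- full_farm()
  farm$land <- land_portfolio()  # drop all land, hence all sinks
  fp <- assemble_footprint(farm, reg, gwp)
  sh <- cf_shares(fp)
  expect_equal(unname(sh$flow_shares["CARBON_SINKS"]), 0)
  expect_equal(sum(sh$flow_shares), 1)
  expect_equal(sum(sh$flow_shares[sh$flow_shares > 0]), 1)
  expect_error(cf_shares(assemble_footprint(zero_farm(), reg, gwp)),
               class = "farmcf_undefined_indicator")
})

test_that("farm_indicators flattens totals, intensities and shares", {
  reg <- illustrative_registry()
  gwp <- gwp_illustrative()
  farm <- full_farm()
  fp <- assemble_footprint(farm, reg, gwp)
  row <- farm_indicators(fp, farm)
  expect_equal(row$total_cf_kg, fp$total_cf)
  expect_equal(row$soah, soah(fp))
  expect_equal(row$share_S1 + row$share_S2 + row$share_S3, 1)
  flow_cols <- paste0("flow_", names(fp$flow_totals))
  expect_equal(unname(unlist(row[flow_cols])), unname(fp$flow_totals))
})
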