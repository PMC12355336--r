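# Synthetic farm-cohort generator.
#
# The generator composes each farm backwards from two targets -- a turnover
# drawn log-uniformly over the cohort's size range and a target share of
# animal husbandry (SoAH) -- by inverting the linear activity x factor
# relations of the engines against a given registry. The computed SoAH of a
# generated farm therefore equals its target exactly (capital-equipment
# rounding residue is re-assigned to a divisible input), and every size and
# intensity relation the benchmarking module tests for is a controlled,
# documented property of the cohort rather than an accident of sampling.

#' Specification of a synthetic cohort
#'
#' Defaults emulate the 12-farm Czech pilot cohort: turnover log-uniform
#' over 24.4--33368.7 thousand EUR (three orders of magnitude), SoAH
#' targets spanning 0--0.8, area and employees tied to turnover by power
#' laws fitted to the smallest and largest pilot farms, and a baseline
#' emission intensity of 450 kg CO2eq per 1000 EUR that rises with SoAH
#' (gain 9) so that cohort intensities span roughly the observed
#' 427--4557 kg/kEUR range. Lognormal noise (sd 0.25) perturbs intensity,
#' area and employees.
#'
#' @param n_farms Number of farms (>= 1).
#' @param seed Integer seed; cohorts are deterministic given the spec.
#' @param turnover_range_keur Min/max turnover, thousand EUR (log-uniform).
#' @param soah_targets Either a length-2 range sampled uniformly or a
#'   vector of length `n_farms`; values in `[0, 0.9]` (the generator always
#'   assigns some non-animal activity, so a SoAH of 1 is infeasible).
#' @param intensity_base Baseline kg CO2eq per 1000 EUR at SoAH 0.
#' @param soah_gain Multiplier slope of intensity in SoAH:
#'   `intensity = intensity_base * (1 + soah_gain * soah)`.
#' @param scale_gamma Scale-effect exponent: intensity is additionally
#'   multiplied by `(turnover / 1000)^-scale_gamma`, so positive values
#'   make larger farms proportionally cleaner. Default 0 (off).
#' @param noise_sd Standard deviation of the lognormal noise.
#' @param liquid_manure_frac Share of manure allocated to liquid storage
#'   (the rest goes to solid storage).
#' @param no_till_frac Share of cropland under no-tillage management.
#' @param biogas_prob Probability a livestock farm operates a biogas plant.
#' @param biogas_cert_prob Probability such a plant holds a no-leakage
#'   certificate.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_farms = 12, seed = 1,
                        turnover_range_keur = c(24.4, 33368.7),
                        soah_targets = c(0, 0.8),
                        intensity_base = 450, soah_gain = 9,
                        scale_gamma = 0, noise_sd = 0.25,
                        liquid_manure_frac = 0.5, no_till_frac = 0,
                        biogas_prob = 0.25, biogas_cert_prob = 0.5) {
  if (n_farms < 1) cf_abort("n_farms must be >= 1.", "farmcf_spec_error")
  if (length(turnover_range_keur) != 2 ||
      any(turnover_range_keur <= 0) ||
      turnover_range_keur[1] > turnover_range_keur[2]) {
    cf_abort("turnover_range_keur must be a positive (min, max) pair.",
             "farmcf_spec_error")
  }
  if (!length(soah_targets) %in% c(2, n_farms)) {
    cf_abort("soah_targets must be a (min, max) range or one value per farm.",
             "farmcf_spec_error")
  }
  if (any(soah_targets < 0) || any(soah_targets > 0.9)) {
    cf_abort(paste0("SoAH targets must lie in [0, 0.9]: the generator always ",
                    "assigns non-animal activity, so higher shares are ",
                    "infeasible."),
             "farmcf_spec_error")
  }
  if (no_till_frac < 0 || no_till_frac > 1 || liquid_manure_frac < 0 ||
      liquid_manure_frac > 1) {
    cf_abort("Management fractions must lie in [0, 1].", "farmcf_spec_error")
  }
  structure(list(n_farms = n_farms, seed = seed,
                 turnover_range_keur = turnover_range_keur,
                 soah_targets = soah_targets,
                 intensity_base = intensity_base, soah_gain = soah_gain,
                 scale_gamma = scale_gamma, noise_sd = noise_sd,
                 liquid_manure_frac = liquid_manure_frac,
                 no_till_frac = no_till_frac, biogas_prob = biogas_prob,
                 biogas_cert_prob = biogas_cert_prob),
            class = "cohort_spec")
}

# Factor shorthand used by the inversion.
synth_factor <- function(registry, process, item, gas) {
  lookup_factor(registry, process, item, gas)$factor
}

#' Generate a synthetic farm cohort
#'
#' Draws `n_farms` farm records per the spec (see [cohort_spec()]),
#' inverting activity quantities from the registry's factors so that each
#' farm's footprint hits its sampled net total and its SoAH equals its
#' target. Farms with a SoAH target of 0 get no livestock and no
#' animal-input purchases.
#'
#' @param spec A [cohort_spec()].
#' @param registry Registry the cohort is calibrated against (default: the
#'   illustrative registry).
#' @param gwp GWP table; must cover R-404A (the refrigerant the generator
#'   assigns), hence the illustrative default.
#' @return A list of [farm_record()]s.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_farms = 3, seed = 42))
#' sapply(cohort, function(f) f$turnover_keur)
#' @export
generate_cohort <- function(spec, registry = illustrative_registry(),
                            gwp = gwp_illustrative()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_farms

  logt <- stats::runif(n, log(spec$turnover_range_keur[1]),
                       log(spec$turnover_range_keur[2]))
  turnover <- exp(logt)
  s <- if (length(spec$soah_targets) == n) spec$soah_targets else
    stats::runif(n, spec$soah_targets[1], spec$soah_targets[2])

  # Size relations fitted to the pilot cohort's endpoints.
  area <- exp(0.81 + 0.74 * log(turnover) + stats::rnorm(n, 0, 0.2))
  employees <- pmax(1, round(exp(-2.24 + 0.7 * log(turnover) +
                                   stats::rnorm(n, 0, spec$noise_sd))))
  intensity <- spec$intensity_base * (1 + spec$soah_gain * s) *
    (turnover / 1000)^(-spec$scale_gamma) *
    exp(stats::rnorm(n, 0, spec$noise_sd))
  total_target <- turnover * intensity  # net kg CO2eq/yr

  has_biogas <- stats::runif(n) < spec$biogas_prob & s > 0
  biogas_cert <- stats::runif(n) < spec$biogas_cert_prob

  lapply(seq_len(n), function(i) {
    synth_farm(i, turnover[i], area[i], employees[i], total_target[i], s[i],
               has_biogas[i], biogas_cert[i], spec, registry, gwp)
  })
}

synth_farm <- function(i, turnover, area, employees, total_target, s,
                       has_biogas, biogas_cert, spec, registry, gwp) {
  crop_ha <- 0.70 * area
  land <- land_portfolio(
    cropland_tillage_ha = crop_ha * (1 - spec$no_till_frac),
    cropland_no_till_ha = crop_ha * spec$no_till_frac,
    grassland_ha = 0.25 * area, builtup_ha = 0.05 * area)
  sink_kg <- sum(carbon_sinks(land, registry, gwp)$co2eq_kg)  # <= 0

  animal_target <- s * total_target
  nonanimal_target <- total_target - animal_target - sink_kg  # gross

  # -- animal side: dairy herd + feed, inverted from per-head emissions.
  liq <- spec$liquid_manure_frac
  per_head <-
    synth_factor(registry, "ENTERIC", "dairy_cattle", "CH4") * gwp[["CH4"]] +
    liq * (synth_factor(registry, "MANURE", "dairy_cattle:liquid_storage",
                        "CH4") * gwp[["CH4"]] +
             synth_factor(registry, "MANURE", "dairy_cattle:liquid_storage",
                          "N2O") * gwp[["N2O"]]) +
    (1 - liq) * (synth_factor(registry, "MANURE",
                              "dairy_cattle:solid_storage", "CH4") *
                   gwp[["CH4"]] +
                   synth_factor(registry, "MANURE",
                                "dairy_cattle:solid_storage", "N2O") *
                   gwp[["N2O"]]) +
    2 * synth_factor(registry, "INPUT", "industrial_feed", "CO2eq")
  heads <- animal_target / per_head  # annual average, may be fractional

  livestock <- if (heads > 0) {
    tibble::tibble(category = "dairy_cattle", heads = heads,
                   anaerobic_digester = 0, liquid_storage = liq,
                   solid_storage = 1 - liq, daily_spread = 0, pasture = 0)
  } else empty_livestock()
  purchases <- if (heads > 0) {
    tibble::tibble(group = "animal_inputs", item = "industrial_feed",
                   quantity = 2 * heads, unit = "t", year = NA_integer_)
  } else empty_purchases()

  # -- non-animal side: fixed budget split, inverted factor by factor.
  budget <- nonanimal_target *
    c(fert = 0.30, fuel = 0.25, elec = 0.15, crop = 0.18, other = 0.06,
      refr = 0.02, waste = 0.04)

  n2o_per_kgn <- synth_factor(registry, "SOIL_N2O", "synthetic_fertilizer",
                              "N2O") * (44 / 28) * gwp[["N2O"]]
  n_total <- budget[["fert"]] / n2o_per_kgn
  nitrogen <- tibble::tibble(
    source = c("synthetic_fertilizer", "compost", "digestate",
               "crop_residues"),
    n_kg = n_total * c(0.6, 0.2, 0.1, 0.1))

  fuels <- tibble::tibble(
    fuel = "diesel",
    quantity = budget[["fuel"]] /
      (synth_factor(registry, "FUEL", "diesel", "CO2") * gwp[["CO2"]]),
    unit = "L")
  energy <- tibble::tibble(
    carrier = "electricity",
    quantity_kwh = budget[["elec"]] /
      (synth_factor(registry, "ENERGY_S2", "electricity", "CO2") *
         gwp[["CO2"]]))

  crop_items <- c(synthetic_fertilizers = 0.7, pesticides = 0.2, seeds = 0.1)
  for (item in names(crop_items)) {
    purchases <- dplyr::bind_rows(purchases, tibble::tibble(
      group = "crop_inputs", item = item,
      quantity = budget[["crop"]] * crop_items[[item]] /
        synth_factor(registry, "INPUT", item, "CO2eq"),
      unit = "t", year = NA_integer_))
  }

  # Capital: whole tractors; the rounding residue goes to plastic packaging
  # so the non-animal total (and hence SoAH) stays exact.
  tractor_per_yr <- synth_factor(registry, "CAPITAL", "tractor", "CO2eq") / 12
  n_tractors <- floor(budget[["other"]] / tractor_per_yr)
  capital <- if (n_tractors > 0) {
    tibble::tibble(item = "tractor", count = n_tractors, lifespan_years = 12)
  } else empty_capital()
  residue <- budget[["other"]] - n_tractors * tractor_per_yr
  if (residue > 0) {
    purchases <- dplyr::bind_rows(purchases, tibble::tibble(
      group = "packaging", item = "plastic",
      quantity = residue / synth_factor(registry, "INPUT", "plastic",
                                        "CO2eq"),
      unit = "t", year = NA_integer_))
  }

  refrigerants <- tibble::tibble(
    code = "R-404A",
    mass_kg = budget[["refr"]] / gwp_lookup(gwp, "R-404A"))

  # Waste budget: half biogas leakage when an uncertified plant exists,
  # otherwise all off-site municipal waste.
  ww <- default_waste_onsite()
  waste_to_offsite <- budget[["waste"]]
  if (has_biogas && !biogas_cert) {
    ww$biogas_ch4_kg <- (budget[["waste"]] / 2) / (0.05 * gwp[["CH4"]])
    ww$biogas_certified <- FALSE
    waste_to_offsite <- budget[["waste"]] / 2
  } else if (has_biogas) {
    ww$biogas_ch4_kg <- 36.5 * max(heads, 1)  # produced but leak-free
    ww$biogas_certified <- TRUE
  }
  waste_offsite <- tibble::tibble(
    item = "municipal",
    quantity = waste_to_offsite /
      synth_factor(registry, "WASTE_OFFSITE", "municipal", "CO2eq"),
    unit = "t")

  farm_record(sprintf("synth_%03d", i), turnover, employees, land = land,
              livestock = livestock, nitrogen = nitrogen, fuels = fuels,
              refrigerants = refrigerants, energy = energy,
              purchases = purchases, capital = capital, waste_onsite = ww,
              waste_offsite = waste_offsite)
}
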