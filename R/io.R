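# Readers and writers for the farm data-form directory dialect.
#
# One directory per farm and reporting year, UTF-8 comma-separated tables
# with a header row and decimal points. `farm.csv` is required; every other
# table is optional and, when absent, read as zero activity. In strict mode
# unknown columns are rejected; every error names the file (and where
# meaningful the row and column) so form problems are locatable.

FARM_TABLES <- list(
  farm = c("farm_id", "turnover_keur", "employees", "cropland_tillage_ha",
           "cropland_no_till_ha", "grassland_ha", "builtup_ha"),
  conversions = c("from_use", "to_use", "area_ha"),
  livestock = c("category", "heads", MANURE_SYSTEMS),
  nitrogen = c("source", "n_kg"),
  fuels = c("fuel", "quantity", "unit"),
  refrigerants = c("code", "mass_kg"),
  energy_purchases = c("carrier", "quantity_kwh"),
  purchases = c("group", "item", "quantity", "unit", "year"),
  capital = c("item", "count", "lifespan_years"),
  waste_onsite = c("composted_t", "wastewater_cod_kg"),
  biogas = c("ch4_produced_kg", "certified"),
  waste_offsite = c("item", "quantity", "unit")
)

read_form_table <- function(dirpath, name, strict) {
  path <- file.path(dirpath, paste0(name, ".csv"))
  if (!file.exists(path)) return(NULL)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  expected <- FARM_TABLES[[name]]
  unknown <- setdiff(names(tab), expected)
  if (length(unknown) > 0 && strict) {
    cf_abort(paste0(basename(path), ": unknown column '", unknown[1], "'."),
             "farmcf_io_error")
  }
  missing <- setdiff(expected, names(tab))
  if (length(missing) > 0) {
    cf_abort(paste0(basename(path), ": missing column '", missing[1], "'."),
             "farmcf_io_error")
  }
  tab[expected]
}

# Parse a character column to numeric, naming file/row/column on failure.
parse_num <- function(x, file, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    cf_abort(paste0(file, ": row ", which(bad)[1], ", column '", column,
                    "': malformed numeric '", x[bad][1], "'."),
             "farmcf_io_error")
  }
  out[is.na(out)] <- NA_real_
  out
}

parse_lgl <- function(x, file, column) {
  out <- toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
  known <- toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES", "FALSE", "F",
                                     "0", "NO")
  if (any(!known)) {
    cf_abort(paste0(file, ": row ", which(!known)[1], ", column '", column,
                    "': malformed logical '", x[!known][1], "'."),
             "farmcf_io_error")
  }
  out
}

#' Read a farm data-form directory
#'
#' Reads and validates the delimited-text farm data form: `farm.csv`
#' (required; identifiers, turnover, employees, land areas) plus the
#' optional activity tables (`livestock.csv`, `nitrogen.csv`, `fuels.csv`,
#' `refrigerants.csv`, `energy_purchases.csv`, `purchases.csv`,
#' `capital.csv`, `waste_onsite.csv`, `biogas.csv`, `waste_offsite.csv`,
#' `conversions.csv`). Missing optional tables mean zero activity. All farm
#' record invariants are enforced on read; errors cite file, row and
#' column.
#'
#' @param dirpath Directory containing the form.
#' @param strict Reject unknown columns (default TRUE).
#' @return A [farm_record()].
#' @export
read_farm <- function(dirpath, strict = TRUE) {
  if (!dir.exists(dirpath)) {
    cf_abort(paste0("Farm directory not found: ", dirpath),
             "farmcf_io_error")
  }
  fm <- read_form_table(dirpath, "farm", strict)
  if (is.null(fm)) {
    cf_abort(paste0(dirpath, ": farm.csv is required."), "farmcf_io_error")
  }
  if (nrow(fm) != 1) {
    cf_abort("farm.csv: exactly one row expected.", "farmcf_io_error")
  }
  num <- function(tab, col, file) parse_num(tab[[col]], file, col)

  conv <- read_form_table(dirpath, "conversions", strict)
  conversions <- if (is.null(conv)) NULL else tibble::tibble(
    from_use = conv$from_use, to_use = conv$to_use,
    area_ha = num(conv, "area_ha", "conversions.csv"))
  land <- land_portfolio(
    cropland_tillage_ha = num(fm, "cropland_tillage_ha", "farm.csv"),
    cropland_no_till_ha = num(fm, "cropland_no_till_ha", "farm.csv"),
    grassland_ha = num(fm, "grassland_ha", "farm.csv"),
    builtup_ha = num(fm, "builtup_ha", "farm.csv"),
    conversions = conversions)

  ls <- read_form_table(dirpath, "livestock", strict)
  livestock <- if (is.null(ls)) empty_livestock() else {
    out <- tibble::tibble(category = ls$category,
                          heads = num(ls, "heads", "livestock.csv"))
    for (sys in MANURE_SYSTEMS) out[[sys]] <- num(ls, sys, "livestock.csv")
    if (nrow(out) > 0) {
      alloc <- rowSums(as.matrix(out[MANURE_SYSTEMS]))
      bad <- out$heads > 0 & abs(alloc - 1) > 1e-9
      if (any(bad)) {
        cf_abort(paste0("livestock.csv: row ", which(bad)[1],
                        ": manure allocation sums to ",
                        format(alloc[bad][1]), "; must sum to 1."),
                 "farmcf_validation_error")
      }
    }
    out
  }

  nt <- read_form_table(dirpath, "nitrogen", strict)
  nitrogen <- if (is.null(nt)) empty_nitrogen() else tibble::tibble(
    source = nt$source, n_kg = num(nt, "n_kg", "nitrogen.csv"))

  fl <- read_form_table(dirpath, "fuels", strict)
  fuels <- if (is.null(fl)) empty_fuels() else tibble::tibble(
    fuel = fl$fuel, quantity = num(fl, "quantity", "fuels.csv"),
    unit = fl$unit)

  rf <- read_form_table(dirpath, "refrigerants", strict)
  refrigerants <- if (is.null(rf)) empty_refrigerants() else tibble::tibble(
    code = rf$code, mass_kg = num(rf, "mass_kg", "refrigerants.csv"))

  en <- read_form_table(dirpath, "energy_purchases", strict)
  energy <- if (is.null(en)) empty_energy() else tibble::tibble(
    carrier = en$carrier,
    quantity_kwh = num(en, "quantity_kwh", "energy_purchases.csv"))

  pu <- read_form_table(dirpath, "purchases", strict)
  purchases <- if (is.null(pu)) empty_purchases() else tibble::tibble(
    group = pu$group, item = pu$item,
    quantity = num(pu, "quantity", "purchases.csv"), unit = pu$unit,
    year = as.integer(parse_num(pu$year, "purchases.csv", "year")))

  cp <- read_form_table(dirpath, "capital", strict)
  capital <- if (is.null(cp)) empty_capital() else tibble::tibble(
    item = cp$item, count = num(cp, "count", "capital.csv"),
    lifespan_years = num(cp, "lifespan_years", "capital.csv"))

  waste_onsite <- default_waste_onsite()
  wo <- read_form_table(dirpath, "waste_onsite", strict)
  if (!is.null(wo)) {
    if (nrow(wo) != 1) {
      cf_abort("waste_onsite.csv: exactly one row expected.",
               "farmcf_io_error")
    }
    waste_onsite$composted_t <- num(wo, "composted_t", "waste_onsite.csv")
    waste_onsite$wastewater_cod_kg <-
      num(wo, "wastewater_cod_kg", "waste_onsite.csv")
  }
  bg <- read_form_table(dirpath, "biogas", strict)
  if (!is.null(bg)) {
    if (nrow(bg) != 1) {
      cf_abort("biogas.csv: exactly one row expected.", "farmcf_io_error")
    }
    waste_onsite$biogas_ch4_kg <- num(bg, "ch4_produced_kg", "biogas.csv")
    waste_onsite$biogas_certified <-
      parse_lgl(bg$certified, "biogas.csv", "certified")
  }

  wf <- read_form_table(dirpath, "waste_offsite", strict)
  waste_offsite <- if (is.null(wf)) empty_waste_offsite() else tibble::tibble(
    item = wf$item, quantity = num(wf, "quantity", "waste_offsite.csv"),
    unit = wf$unit)

  farm_record(fm$farm_id, num(fm, "turnover_keur", "farm.csv"),
              num(fm, "employees", "farm.csv"), land = land,
              livestock = livestock, nitrogen = nitrogen, fuels = fuels,
              refrigerants = refrigerants, energy = energy,
              purchases = purchases, capital = capital,
              waste_onsite = waste_onsite, waste_offsite = waste_offsite)
}

#' Write a farm record as a data-form directory
#'
#' Inverse of [read_farm()]: numbers are written in shortest
#' round-tripping form, so write-then-read reproduces the record (and its
#' footprint) exactly.
#'
#' @param farm A [farm_record()].
#' @param dirpath Output directory (created if needed).
#' @return `dirpath`, invisibly.
#' @export
write_farm <- function(farm, dirpath) {
  stopifnot(inherits(farm, "farm_record"))
  dir.create(dirpath, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, name) {
    readr::write_csv(tab, file.path(dirpath, paste0(name, ".csv")),
                     progress = FALSE)
  }
  w(tibble::tibble(farm_id = farm$farm_id,
                   turnover_keur = farm$turnover_keur,
                   employees = farm$employees,
                   cropland_tillage_ha = farm$land$cropland_tillage_ha,
                   cropland_no_till_ha = farm$land$cropland_no_till_ha,
                   grassland_ha = farm$land$grassland_ha,
                   builtup_ha = farm$land$builtup_ha), "farm")
  if (nrow(farm$land$conversions) > 0) w(farm$land$conversions, "conversions")
  if (nrow(farm$livestock) > 0) w(farm$livestock, "livestock")
  if (nrow(farm$nitrogen) > 0) w(farm$nitrogen, "nitrogen")
  if (nrow(farm$fuels) > 0) w(farm$fuels, "fuels")
  if (nrow(farm$refrigerants) > 0) w(farm$refrigerants, "refrigerants")
  if (nrow(farm$energy) > 0) w(farm$energy, "energy_purchases")
  if (nrow(farm$purchases) > 0) w(farm$purchases, "purchases")
  if (nrow(farm$capital) > 0) w(farm$capital, "capital")
  w(tibble::tibble(composted_t = farm$waste_onsite$composted_t,
                   wastewater_cod_kg = farm$waste_onsite$wastewater_cod_kg),
    "waste_onsite")
  w(tibble::tibble(ch4_produced_kg = farm$waste_onsite$biogas_ch4_kg,
                   certified = farm$waste_onsite$biogas_certified), "biogas")
  if (nrow(farm$waste_offsite) > 0) w(farm$waste_offsite, "waste_offsite")
  invisible(dirpath)
}
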