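#' Emission-factor registry
#'
#' The registry holds one emission or sink factor per `(process, item, gas)`
#' key, together with the activity unit the factor applies to and a free-text
#' source label. It is the single place all calculation engines look up
#' coefficients; the package ships an illustrative registry of round
#' IPCC-Tier-1-style numbers (see [illustrative_registry()]) for tests and
#' synthetic cohorts, but real analyses are expected to load a
#' national-inventory or life-cycle-database registry supplied by the user.
#'
#' File format: UTF-8 comma-separated text with header
#' `process,item,gas,factor,unit,source`, decimal point, one factor per row.
#'
#' Sink conventions: processes `SINK` (per land use, unit
#' `"kg C per ha per yr"`) and `SINK_CONVERSION` (per land-use conversion,
#' unit `"kg C per ha conversion"`) store carbon in kg C; positive values
#' mean net storage and enter the footprint as negative CO2eq after the
#' stoichiometric 44/12 conversion.
#'
#' @param path Path of the registry CSV file.
#' @param strict Logical; in strict mode (default) a missing factor is an
#'   error, in permissive mode it is a warning and the factor is taken as 0.
#'   The mode is carried as an attribute and used by [lookup_factor()].
#'
#' @return A tibble of class `cf_registry`.
#' @export
read_registry <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    cf_abort(paste0("Registry file not found: ", path), "farmcf_io_error")
  }
  reg <- readr::read_csv(
    path,
    col_types = readr::cols(
      process = readr::col_character(),
      item = readr::col_character(),
      gas = readr::col_character(),
      factor = readr::col_double(),
      unit = readr::col_character(),
      source = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(reg)
  if (nrow(probs) > 0) {
    cf_abort(paste0("Malformed registry ", path, ": row ", probs$row[1],
                    ", column ", probs$col[1], " (", probs$expected[1], ")."),
             "farmcf_io_error")
  }
  as_registry(reg, strict = strict, origin = path)
}

#' @param entries A data frame with columns process, item, gas, factor, unit,
#'   source.
#' @param origin Optional label recording where the registry came from.
#' @rdname read_registry
#' @export
as_registry <- function(entries, strict = TRUE, origin = NULL) {
  required <- c("process", "item", "gas", "factor", "unit", "source")
  if (!all(required %in% names(entries))) {
    cf_abort(paste0("Registry must have columns ",
                    paste(required, collapse = ", "), "."),
             "farmcf_io_error")
  }
  entries <- tibble::as_tibble(entries)[required]
  key <- paste(entries$process, entries$item, entries$gas, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    parts <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    cf_abort(paste0("Duplicate registry key: process '", parts[1],
                    "', item '", parts[2], "', gas '", parts[3], "'."),
             "farmcf_duplicate_key")
  }
  if (any(!is.finite(entries$factor))) {
    cf_abort("Registry factors must be finite.", "farmcf_validation_error")
  }
  sinkish <- entries$process %in% c("SINK", "SINK_CONVERSION")
  ok_unit <- ifelse(entries$process == "SINK",
                    entries$unit == "kg C per ha per yr",
                    entries$unit == "kg C per ha conversion")
  if (any(sinkish & !ok_unit)) {
    bad <- which(sinkish & !ok_unit)[1]
    cf_abort(paste0("Sink factor (", entries$process[bad], ", ",
                    entries$item[bad], ") carries unit '", entries$unit[bad],
                    "'; expected 'kg C per ha per yr' or ",
                    "'kg C per ha conversion'."),
             "farmcf_validation_error")
  }
  structure(entries,
            class = c("cf_registry", class(tibble::tibble())),
            strict = isTRUE(strict), origin = origin)
}

#' Write a registry back to delimited text
#'
#' Numbers are written in the shortest round-tripping representation, so a
#' write/read cycle reproduces every factor bit-identically.
#'
#' @param registry A `cf_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "cf_registry"))
  readr::write_csv(tibble::as_tibble(unclass_registry(registry)), path,
                   progress = FALSE)
  invisible(path)
}

unclass_registry <- function(registry) {
  attr(registry, "strict") <- NULL
  attr(registry, "origin") <- NULL
  class(registry) <- class(tibble::tibble())
  registry
}

registry_strict <- function(registry) isTRUE(attr(registry, "strict"))

#' Look up an emission factor
#'
#' Retrieves the unique factor for a `(process, item, gas)` key. In strict
#' mode (the registry default) a missing key is an error naming the key; in
#' permissive mode the factor is returned as 0 with a warning, which is
#' logged rather than silently corrupting totals.
#'
#' @param registry A `cf_registry`.
#' @param process,item,gas Key components (scalars).
#' @param strict Override the registry's strict/permissive mode.
#' @return A list with elements `factor` and `unit`.
#' @export
lookup_factor <- function(registry, process, item, gas, strict = NULL) {
  res <- lookup_factors(registry, process, item, gas, strict = strict)
  list(factor = res$factor, unit = res$unit)
}

# Vectorized lookup over parallel key vectors (recycled to common length).
lookup_factors <- function(registry, process, item, gas, strict = NULL) {
  stopifnot(inherits(registry, "cf_registry"))
  strict <- strict %||% registry_strict(registry)
  n <- max(length(process), length(item), length(gas))
  process <- rep_len(process, n); item <- rep_len(item, n)
  gas <- rep_len(gas, n)
  key <- paste(process, item, gas, sep = "\r")
  regkey <- paste(registry$process, registry$item, registry$gas, sep = "\r")
  idx <- match(key, regkey)
  if (anyNA(idx)) {
    j <- which(is.na(idx))[1]
    msg <- paste0("No registry factor for process '", process[j],
                  "', item '", item[j], "', gas '", gas[j], "'.")
    if (strict) cf_abort(msg, "farmcf_missing_factor")
    cf_warn(paste0(msg, " Using 0 (permissive mode)."),
            "farmcf_missing_factor_warning")
  }
  list(factor = ifelse(is.na(idx), 0, registry$factor[idx]),
       unit = ifelse(is.na(idx), NA_character_, registry$unit[idx]))
}

# TRUE if the key is present (used for optional pathways).
registry_has <- function(registry, process, item, gas) {
  any(registry$process == process & registry$item == item &
        registry$gas == gas)
}

#' Illustrative emission-factor registry
#'
#' A registry of round, Tier-1-style numbers covering every process the
#' engines know about. It is a test and demonstration instrument: the values
#' are plausible in order of magnitude but are not the coefficients of any
#' national inventory or life-cycle database, and results computed with it
#' should never be read as real farm footprints.
#'
#' @param strict Strict/permissive lookup mode for the returned registry.
#' @return A `cf_registry`.
#' @export
illustrative_registry <- function(strict = TRUE) {
  read_registry(system.file("extdata", "registry_illustrative.csv",
                            package = "farmcf"),
                strict = strict)
}
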