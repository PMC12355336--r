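#' Global warming potential (GWP) tables
#'
#' A GWP table maps gas identifiers to 100-year global warming potentials in
#' kg CO2-equivalent per kg of gas. The default table carries the three
#' Kyoto gases used throughout the calculation engine (CO2 = 1, CH4 = 28,
#' N2O = 265) plus the pseudo-gas `CO2eq` (GWP 1) under which aggregate
#' life-cycle factors are stored in the registry. Refrigerant GWPs are not
#' part of the default set: they are supplied by the user, either through
#' `gwp_table()` or a YAML config read with [read_gwp()].
#'
#' @param ... Named GWP values (e.g. `"R-404A" = 3943`) added to, or
#'   overriding, the defaults.
#' @param .base Logical; include the default CO2/CH4/N2O/CO2eq entries.
#'
#' @return A named numeric vector of class `gwp_table`.
#' @examples
#' gwp_default()
#' gwp_table("R-404A" = 3943)
#' @export
gwp_table <- function(..., .base = TRUE) {
  extra <- c(...)
  if (length(extra) > 0 && (is.null(names(extra)) || any(names(extra) == ""))) {
    cf_abort("All GWP entries must be named by a gas identifier.",
             "farmcf_invalid_gwp")
  }
  base <- if (.base) c(CO2 = 1, CH4 = 28, N2O = 265, CO2eq = 1) else numeric(0)
  tab <- base
  tab[names(extra)] <- as.numeric(extra)
  if (any(!is.finite(tab)) || any(tab <= 0)) {
    cf_abort("GWP values must be finite and > 0.", "farmcf_invalid_gwp")
  }
  structure(tab, class = "gwp_table")
}

#' @rdname gwp_table
#' @export
gwp_default <- function() gwp_table()

#' Read a GWP config file
#'
#' Reads a YAML file with a top-level `gwp:` map of gas identifier to GWP
#' and merges it onto the defaults (entries in the file override defaults).
#'
#' @param path Path to a YAML file.
#' @return A `gwp_table`.
#' @export
read_gwp <- function(path) {
  if (!file.exists(path)) {
    cf_abort(paste0("GWP config not found: ", path), "farmcf_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$gwp) || !is.list(cfg$gwp)) {
    cf_abort(paste0("GWP config ", path, " lacks a 'gwp:' map."),
             "farmcf_invalid_gwp")
  }
  do.call(gwp_table, cfg$gwp)
}

#' Illustrative GWP table shipped with the package
#'
#' The default gases plus illustrative refrigerant GWPs (e.g. R-404A), as
#' used by the synthetic cohort generator and the examples. The refrigerant
#' values are round illustrative numbers, not an endorsement of any
#' inventory's figures.
#'
#' @return A `gwp_table`.
#' @export
gwp_illustrative <- function() {
  read_gwp(system.file("extdata", "gwp_illustrative.yaml", package = "farmcf"))
}

# Vectorized GWP lookup; errors on the first unknown gas.
gwp_lookup <- function(gwp, gas) {
  stopifnot(inherits(gwp, "gwp_table"))
  idx <- match(gas, names(gwp))
  if (anyNA(idx)) {
    missing <- unique(gas[is.na(idx)])[1]
    cf_abort(paste0("No GWP available for gas '", missing, "'."),
             "farmcf_missing_gwp")
  }
  unname(unclass(gwp)[idx])
}

#' Convert gas masses to CO2 equivalents
#'
#' Computes the GWP-weighted sum of a set of annual gas masses:
#' `sum(mass_kg * GWP(gas))`. The conversion is linear in each mass and
#' additive over concatenated records.
#'
#' @param gases A data frame with columns `gas` (identifier) and `mass_kg`
#'   (kg of gas per year). Zero rows give 0.
#' @param gwp A [gwp_table()].
#' @return Total kg CO2eq per year (a single number).
#' @examples
#' co2eq(data.frame(gas = "CH4", mass_kg = 1000), gwp_default())  # 28000
#' @export
co2eq <- function(gases, gwp = gwp_default()) {
  if (!is.data.frame(gases) || !all(c("gas", "mass_kg") %in% names(gases))) {
    cf_abort("`gases` must be a data frame with columns gas and mass_kg.",
             "farmcf_validation_error")
  }
  if (nrow(gases) == 0) return(0)
  sum(gases$mass_kg * gwp_lookup(gwp, gases$gas))
}

#' @export
print.gwp_table <- function(x, ...) {
  cat("<gwp_table> kg CO2eq per kg gas\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
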