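# Indicators: relative carbon footprints, SoAH, scope and flow shares.

#' Emission intensities from a total footprint and farm characteristics
#'
#' The three relative CFs: per thousand EUR of turnover, per hectare of farm
#' area and per employee. A non-positive denominator leaves that indicator
#' undefined (`NA`) with a warning; the others are still computed.
#'
#' @param total_cf Net total footprint, kg CO2eq/yr.
#' @param turnover_keur Turnover in thousand EUR.
#' @param area_ha Farm area (cropland + grassland + built-up), ha.
#' @param employees Number of employees.
#' @return A list with `cf_per_turnover` (kg CO2eq per 1000 EUR),
#'   `cf_per_area` (kg CO2eq per ha) and `cf_per_employee` (kg CO2eq per
#'   employee).
#' @examples
#' cf_intensities(4557 * 577.4, turnover_keur = 577.4, area_ha = 356,
#'                employees = 9)
#' @export
cf_intensities <- function(total_cf, turnover_keur, area_ha, employees) {
  one <- function(den, what) {
    if (!is.finite(den) || den <= 0) {
      cf_warn(paste0("CF per ", what, " undefined: non-positive ", what, "."),
              "farmcf_undefined_indicator")
      return(NA_real_)
    }
    total_cf / den
  }
  list(cf_per_turnover = one(turnover_keur, "turnover"),
       cf_per_area = one(area_ha, "area"),
       cf_per_employee = one(employees, "employee count"))
}

#' Relative CFs of a farm footprint
#'
#' @param footprint A [assemble_footprint()] result.
#' @param farm The matching [farm_record()] (denominators: turnover, area,
#'   employees).
#' @return See [cf_intensities()].
#' @export
relative_cfs <- function(footprint, farm) {
  stopifnot(inherits(footprint, "farm_footprint"),
            inherits(farm, "farm_record"))
  cf_intensities(footprint$total_cf, farm$turnover_keur, area_ha(farm),
                 farm$employees)
}

#' Share of animal husbandry (SoAH)
#'
#' The share of the total footprint unambiguously attributable to animal
#' husbandry: enteric fermentation, manure management and manufacturing of
#' purchased animal-husbandry inputs, divided by the net total CF. Energy
#' partly used for animals is deliberately excluded (its attribution would
#' require sub-metered energy data farms do not have). Reported in summary
#' tables rounded to 2 decimals; the returned value is exact.
#'
#' @param footprint A `farm_footprint`.
#' @return A dimensionless share (in `[0, 1]` whenever all non-sink flows
#'   are non-negative and the numerator does not exceed the total).
#' @export
soah <- function(footprint) {
  stopifnot(inherits(footprint, "farm_footprint"))
  if (footprint$total_cf <= 0) {
    cf_abort("SoAH undefined: total CF must be > 0.",
             "farmcf_undefined_indicator")
  }
  ft <- footprint$flow_totals
  unname((ft["ENTERIC_FERMENTATION"] + ft["MANURE_MANAGEMENT"] +
            ft["INPUTS_ANIMAL"]) / footprint$total_cf)
}

#' Scope and flow shares of the total footprint
#'
#' Flow shares are signed: each flow's CO2eq divided by the net total, so
#' carbon sinks yield negative shares and the positive shares can sum to
#' more than 1 exactly when sinks are negative; the signed shares always sum
#' to 1. Scope shares use, by default, Scope 1 net of sinks over the net
#' total (`convention = "net"`, the three shares sum to 1); with
#' `convention = "gross"` Scope 1 is reported gross of sinks and the sink
#' deduction appears as a separate negative `sinks` share.
#'
#' @param footprint A `farm_footprint`.
#' @param convention `"net"` (default) or `"gross"`.
#' @return A list with `flow_shares` (named, one per reporting flow) and
#'   `scope_shares`.
#' @export
cf_shares <- function(footprint, convention = c("net", "gross")) {
  stopifnot(inherits(footprint, "farm_footprint"))
  convention <- match.arg(convention)
  if (footprint$total_cf == 0) {
    cf_abort("Shares undefined: total CF is 0.",
             "farmcf_undefined_indicator")
  }
  tot <- footprint$total_cf
  st <- footprint$scope_totals
  flow_shares <- footprint$flow_totals / tot
  scope_shares <- if (convention == "net") {
    c(S1 = (st[["S1_gross"]] + st[["S1_sinks"]]) / tot,
      S2 = st[["S2"]] / tot,
      S3 = (st[["S3_inputs"]] + st[["S3_waste"]]) / tot)
  } else {
    c(S1 = st[["S1_gross"]] / tot,
      S2 = st[["S2"]] / tot,
      S3 = (st[["S3_inputs"]] + st[["S3_waste"]]) / tot,
      sinks = st[["S1_sinks"]] / tot)
  }
  list(flow_shares = flow_shares, scope_shares = scope_shares)
}

#' Full indicator set for one farm
#'
#' Combines the net total, the three relative CFs, SoAH and the scope and
#' flow shares into one flat tibble row, as written to `cohort.csv`.
#' Undefined indicators (zero total, non-positive denominators) come back
#' as `NA` with a warning rather than an error, so one degenerate farm does
#' not abort a cohort run.
#'
#' @inheritParams relative_cfs
#' @param convention Scope-share convention, see [cf_shares()].
#' @return A one-row tibble.
#' @export
farm_indicators <- function(footprint, farm, convention = "net") {
  rel <- relative_cfs(footprint, farm)
  sh <- tryCatch(cf_shares(footprint, convention), farmcf_error = function(e) {
    cf_warn(conditionMessage(e), "farmcf_undefined_indicator")
    list(flow_shares = stats::setNames(rep(NA_real_, length(FLOW_IDS)),
                                       FLOW_IDS),
         scope_shares = c(S1 = NA_real_, S2 = NA_real_, S3 = NA_real_))
  })
  so <- tryCatch(soah(footprint), farmcf_error = function(e) {
    cf_warn(conditionMessage(e), "farmcf_undefined_indicator")
    NA_real_
  })
  out <- tibble::tibble(
    farm_id = footprint$farm_id,
    turnover_keur = farm$turnover_keur,
    area_ha = area_ha(farm),
    employees = farm$employees,
    total_cf_kg = footprint$total_cf,
    cf_per_turnover = rel$cf_per_turnover,
    cf_per_area = rel$cf_per_area,
    cf_per_employee = rel$cf_per_employee,
    soah = so
  )
  for (s in names(sh$scope_shares)) {
    out[[paste0("share_", s)]] <- unname(sh$scope_shares[[s]])
  }
  for (f in FLOW_IDS) out[[paste0("flow_", f)]] <-
    unname(footprint$flow_totals[[f]])
  out
}
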