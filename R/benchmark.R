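# Cohort benchmarking: rank correlations and SoAH-matched comparisons.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive the average of
#' the ranks they span). Symmetric in its arguments and invariant under
#' strictly increasing transformations of either. Degenerate inputs are
#' errors rather than `NaN`: unequal lengths, fewer than 3 observations,
#' missing values, or zero rank variance (a constant sequence).
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return The correlation, in `[-1, 1]`.
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))  # 1
#' spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))  # 0.9487
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    cf_abort(paste0("Length mismatch: ", length(x), " vs ", length(y), "."),
             "farmcf_validation_error")
  }
  if (length(x) < 3) {
    cf_abort("Spearman correlation needs at least 3 observations.",
             "farmcf_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    cf_abort("Missing values are not allowed.", "farmcf_validation_error")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    cf_abort("Zero rank variance: a constant sequence has no rank order.",
             "farmcf_validation_error")
  }
  stats::cor(rx, ry)
}

#' Build a cohort table
#'
#' Assembles footprints for a list of farms and stacks their
#' [farm_indicators()] rows into one table, the input of the correlation
#' and pairing analyses.
#'
#' @param farms A list of [farm_record()]s.
#' @inheritParams assemble_footprint
#' @param convention Scope-share convention, see [cf_shares()].
#' @return A tibble of class `cohort_table`, one row per farm.
#' @export
cohort_table <- function(farms, registry, gwp = gwp_default(),
                         convention = "net") {
  stopifnot(length(farms) >= 1)
  rows <- lapply(farms, function(farm) {
    farm_indicators(assemble_footprint(farm, registry, gwp), farm,
                    convention)
  })
  tab <- dplyr::bind_rows(rows)
  if (anyDuplicated(tab$farm_id)) {
    cf_abort("farm_id must be unique across the cohort.",
             "farmcf_validation_error")
  }
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Cohort rank correlations: size, scale and SoAH effects
#'
#' The nine Spearman correlations used to benchmark a cohort:
#' * size effect — absolute CF vs turnover, area and employees (large farms
#'   emit more in absolute terms);
#' * scale effect — each size variable vs the matching relative CF (a
#'   purely scale-driven cohort would give -1);
#' * SoAH effect — SoAH vs each relative CF (animal-husbandry-heavy farms
#'   have higher emission intensities).
#'
#' Farms with any undefined indicator are excluded with a warning; at least
#' 3 usable farms are required.
#'
#' @param table A [cohort_table()].
#' @return A tibble with columns `effect`, `x`, `y`, `rho`.
#' @export
cohort_correlations <- function(table) {
  pairs <- list(
    c("size_effect", "turnover_keur", "total_cf_kg"),
    c("size_effect", "area_ha", "total_cf_kg"),
    c("size_effect", "employees", "total_cf_kg"),
    c("scale_effect", "turnover_keur", "cf_per_turnover"),
    c("scale_effect", "area_ha", "cf_per_area"),
    c("scale_effect", "employees", "cf_per_employee"),
    c("soah_effect", "soah", "cf_per_turnover"),
    c("soah_effect", "soah", "cf_per_area"),
    c("soah_effect", "soah", "cf_per_employee")
  )
  used <- unique(unlist(lapply(pairs, function(p) p[2:3])))
  ok <- stats::complete.cases(table[used])
  if (any(!ok)) {
    cf_warn(paste0("Excluding ", sum(!ok), " farm(s) with undefined ",
                   "indicators: ",
                   paste(table$farm_id[!ok], collapse = ", "), "."),
            "farmcf_excluded_farms")
    table <- table[ok, , drop = FALSE]
  }
  if (nrow(table) < 3) {
    cf_abort("Fewer than 3 farms with defined indicators.",
             "farmcf_validation_error")
  }
  dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(effect = p[1], x = p[2], y = p[3],
                   rho = spearman_rho(table[[p[2]]], table[[p[3]]]))
  }))
}

#' Pair farms with similar SoAH
#'
#' Greedily pairs farms whose SoAH values differ by at most `tolerance`,
#' taking candidate pairs in ascending order of SoAH distance (ties broken
#' by farm order in the table) so the result is deterministic. Each farm
#' joins at most one pair. Benchmarking within such pairs compares farms of
#' like production focus, which is where relative-CF differences are
#' actionable.
#'
#' @param table A data frame with columns `farm_id` and `soah`.
#' @param tolerance Maximum allowed absolute SoAH difference.
#' @return A tibble with columns `farm_a`, `farm_b`, `soah_a`, `soah_b`,
#'   `delta` (possibly zero rows).
#' @export
soah_pairing <- function(table, tolerance) {
  stopifnot(is.data.frame(table), all(c("farm_id", "soah") %in% names(table)),
            is.numeric(tolerance), tolerance >= 0)
  if (anyNA(table$soah)) {
    cf_abort("SoAH must be defined on all farms before pairing.",
             "farmcf_validation_error")
  }
  n <- nrow(table)
  empty <- tibble::tibble(farm_a = character(), farm_b = character(),
                          soah_a = double(), soah_b = double(),
                          delta = double())
  if (n < 2) return(empty)
  cand <- expand.grid(i = seq_len(n), j = seq_len(n))
  cand <- cand[cand$i < cand$j, , drop = FALSE]
  cand$delta <- abs(table$soah[cand$i] - table$soah[cand$j])
  cand <- cand[cand$delta <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$delta, cand$i, cand$j), , drop = FALSE]
  used <- rep(FALSE, n)
  keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      keep <- c(keep, k)
    }
  }
  if (length(keep) == 0) return(empty)
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(
    farm_a = as.character(table$farm_id[cand$i]),
    farm_b = as.character(table$farm_id[cand$j]),
    soah_a = table$soah[cand$i], soah_b = table$soah[cand$j],
    delta = cand$delta
  )
}

#' Pairwise flow-level comparison of two farms
#'
#' For a pair of (typically SoAH-matched) farms, the per-flow CF per
#' turnover of each farm and their difference, ordered by descending
#' absolute difference, with a `TOTAL` row appended. The signed flow rows
#' sum exactly to each farm's CF per turnover.
#'
#' @param footprint_a,footprint_b `farm_footprint`s.
#' @param farm_a,farm_b The matching [farm_record()]s (turnover > 0).
#' @return A tibble with columns `flow`, `a`, `b`, `diff` (kg CO2eq per
#'   1000 EUR).
#' @export
pair_comparison <- function(footprint_a, farm_a, footprint_b, farm_b) {
  per_turnover <- function(fp, farm) {
    if (!is.finite(farm$turnover_keur) || farm$turnover_keur <= 0) {
      cf_abort(paste0("Farm '", farm$farm_id,
                      "': turnover must be > 0 for a per-turnover ",
                      "comparison."),
               "farmcf_undefined_indicator")
    }
    fp$flow_totals / farm$turnover_keur
  }
  a <- per_turnover(footprint_a, farm_a)
  b <- per_turnover(footprint_b, farm_b)
  out <- tibble::tibble(flow = FLOW_IDS, a = unname(a[FLOW_IDS]),
                        b = unname(b[FLOW_IDS]))
  out$diff <- out$a - out$b
  out <- out[order(-abs(out$diff)), ]
  dplyr::bind_rows(out, tibble::tibble(flow = "TOTAL", a = sum(a), b = sum(b),
                                       diff = sum(a) - sum(b)))
}
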