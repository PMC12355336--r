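# End-to-end computation over one or more farm directories.

#' Compute footprints and cohort reports for a set of farms
#'
#' Reads each farm data-form directory, assembles its footprint, and writes
#' per-farm flow tables (`<farm_id>_flows.csv`: farm_id, flow, scope,
#' co2eq_kg), a cohort indicator table (`cohort.csv`) and, when at least
#' three farms have defined indicators, the nine benchmark correlations
#' (`correlations.csv`). Outputs are deterministic: re-running on the same
#' inputs produces byte-identical files.
#'
#' @param farm_dirs Character vector of farm data-form directories, or a
#'   list of [farm_record()]s.
#' @param registry A `cf_registry` or the path of a registry CSV.
#' @param out_dir Output directory (created if needed).
#' @param gwp A [gwp_table()].
#' @param strict Strict (error) vs permissive (zero + warning) factor
#'   lookup and column checking.
#' @param convention Scope-share convention, see [cf_shares()].
#' @return Invisibly, a list with `cohort` (tibble) and `correlations`
#'   (tibble or NULL).
#' @export
run_compute <- function(farm_dirs, registry, out_dir,
                        gwp = gwp_default(), strict = TRUE,
                        convention = "net") {
  if (is.character(registry)) registry <- read_registry(registry, strict)
  stopifnot(inherits(registry, "cf_registry"))
  attr(registry, "strict") <- isTRUE(strict)
  if (length(farm_dirs) < 1) {
    cf_abort("At least one farm is required.", "farmcf_validation_error")
  }
  farms <- lapply(farm_dirs, function(x) {
    if (inherits(x, "farm_record")) x else read_farm(x, strict = strict)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", length(farms))
  for (k in seq_along(farms)) {
    fp <- assemble_footprint(farms[[k]], registry, gwp)
    flows <- tibble::tibble(farm_id = fp$farm_id, flow = fp$flows$flow,
                            scope = fp$flows$scope,
                            co2eq_kg = fp$flows$co2eq_kg)
    readr::write_csv(flows,
                     file.path(out_dir, paste0(fp$farm_id, "_flows.csv")),
                     progress = FALSE)
    rows[[k]] <- farm_indicators(fp, farms[[k]], convention)
  }
  cohort <- dplyr::bind_rows(rows)
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"),
                   progress = FALSE)

  correlations <- NULL
  if (nrow(cohort) >= 3) {
    correlations <- tryCatch(cohort_correlations(cohort),
                             farmcf_error = function(e) {
                               cf_warn(paste0("Correlations skipped: ",
                                              conditionMessage(e)))
                               NULL
                             })
    if (!is.null(correlations)) {
      readr::write_csv(correlations,
                       file.path(out_dir, "correlations.csv"),
                       progress = FALSE)
    }
  }
  invisible(list(cohort = cohort, correlations = correlations))
}
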