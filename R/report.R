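#' Run the full analysis and write a report bundle
#'
#' Executes the deterministic base case, the one-way sensitivity analysis,
#' the probabilistic sensitivity analysis (with CEAC and per-person EVPI)
#' and the value-of-implementation analysis, and writes machine-readable
#' outputs to `out_dir`: `summary.json`, `trace_<strategy>.csv`,
#' `tornado.csv`, `psa_draws.csv`, `ceac.csv` and `voi.csv`. The summary
#' records every accrual/structural flag in effect plus the package
#' version, so a run can be reproduced from its outputs. If any stage
#' fails, partial outputs are removed and the error is re-thrown with the
#' failing stage named.
#'
#' @param params A [parameter_set()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds GBP-per-QALY thresholds.
#' @param psa_iterations Number of PSA iterations; 0 disables the PSA (no
#'   `psa_draws.csv`/`ceac.csv` written).
#' @param seed Seed for the PSA.
#' @param owsa Run the one-way sensitivity analysis?
#' @param uptake,annual_incidence,voi_horizon_years Implementation scenario
#'   (see [value_of_implementation()]).
#' @return The report bundle (named list), invisibly.
#' @export
run_full_analysis <- function(params = default_parameters(),
                              out_dir,
                              thresholds = c(20000, 30000),
                              psa_iterations = 0,
                              seed = 1,
                              owsa = TRUE,
                              uptake = c(surgery_et = 0.76, pet = 0.24),
                              annual_incidence = 9356,
                              voi_horizon_years = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    written <<- c(written, path)
    path
  }
  stage <- "base case"
  bundle <- tryCatch({
    base <- run_base_case(params, thresholds)
    for (s in c("surgery_et", "pet")) {
      emit(build_partition_trace(params, s), paste0("trace_", s, ".csv"))
    }
    tornado <- NULL
    if (owsa) {
      stage <- "one-way sensitivity"
      tornado <- one_way_sensitivity(params, threshold = thresholds[1])
      emit(tornado, "tornado.csv")
    }
    psa <- ceac_tbl <- evpi <- NULL
    if (psa_iterations > 0) {
      stage <- "probabilistic sensitivity analysis"
      psa <- run_psa(params, n_iter = psa_iterations, seed = seed)
      emit(psa$draws, "psa_draws.csv")
      ceac_tbl <- ceac(psa, thresholds = sort(unique(
        c(seq(0, 50000, by = 1000), thresholds))))
      emit(ceac_tbl, "ceac.csv")
      evpi <- stats::setNames(
        vapply(thresholds, function(th) evpi_per_person(psa, th), 0),
        thresholds)
    }
    stage <- "value of implementation"
    voi <- value_of_implementation(base, uptake = uptake,
                                   annual_incidence = annual_incidence,
                                   horizon_years = voi_horizon_years,
                                   discount_rate = params$discount_rate)
    emit(voi, "voi.csv")

    stage <- "summary"
    cmp <- base$comparison
    summary <- list(
      package_version = as.character(utils::packageVersion("petvoi")),
      settings = list(
        mode = params$mode,
        horizon_years = params$horizon_years,
        cycle_length = params$cycle_length,
        baseline_age = params$baseline_age,
        discount_rate = params$discount_rate,
        discount_per_cycle = params$discount_per_cycle,
        progressed_utility = params$progressed_utility,
        progression_cost_mode = params$progression_cost_mode,
        include_hospital_stay = params$include_hospital_stay,
        cost_surgery_oneoff_effective = surgery_cost(params),
        os_pet = c(family = params$os_pet$family,
                   as.list(params$os_pet$params)),
        pfs_pet = c(family = params$pfs_pet$family,
                    as.list(params$pfs_pet$params)),
        seed = seed,
        psa_iterations = psa_iterations
      ),
      strategies = base$strategies,
      comparison = list(
        incremental_cost = cmp$incremental_cost,
        incremental_qaly = cmp$incremental_qaly,
        icer = cmp$icer,
        label = cmp$label,
        nmb = cmp$nmb,
        inmb = as.list(cmp$inmb)
      ),
      psa = if (!is.null(psa)) list(
        n_iter = psa$n_iter, seed = psa$seed,
        means = summary(psa),
        probability_cost_effective = if (!is.null(ceac_tbl)) {
          ce <- dplyr::filter(ceac_tbl, .data$strategy == "surgery_et",
                              .data$threshold %in% thresholds)
          stats::setNames(as.list(ce$probability), ce$threshold)
        },
        evpi_per_person = as.list(evpi)
      ),
      voi = voi
    )
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
    list(base = base, tornado = tornado, psa = psa, ceac = ceac_tbl,
         evpi = evpi, voi = voi, summary = summary, files = written)
  }, error = function(e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(bundle)
}
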