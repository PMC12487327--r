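#' Per-person expected value of perfect implementation
#'
#' The net benefit forgone per patient because uptake of the net-benefit
#' maximizing strategy is below 100%:
#' `EVPImp = max_j E[NB(j)] - sum_j rho_j E[NB(j)]`,
#' where `rho_j` are the current implementation shares. With two
#' strategies and the better one taken up at share `rho*`, this equals
#' `(1 - rho*) * INMB`.
#'
#' @param nb Named numeric vector of expected net (monetary) benefit per
#'   strategy at one threshold.
#' @param uptake Named numeric vector of implementation shares for the same
#'   strategies; must be in `[0, 1]` and sum to 1.
#' @return EVPImp in the units of `nb` (non-negative scalar).
#' @examples
#' evpimp_per_person(c(surgery_et = 80877.96, pet = 71288.45),
#'                   c(surgery_et = 0.76, pet = 0.24))
#' @export
evpimp_per_person <- function(nb, uptake) {
  stopifnot(is.numeric(nb), is.numeric(uptake))
  if (is.null(names(nb)) || is.null(names(uptake)) ||
      !setequal(names(nb), names(uptake))) {
    stop("nb and uptake must be named for the same strategies", call. = FALSE)
  }
  uptake <- uptake[names(nb)]
  if (any(uptake < 0 | uptake > 1) || abs(sum(uptake) - 1) > 1e-9) {
    stop("scenario error: uptake shares must lie in [0, 1] and sum to 1",
         call. = FALSE)
  }
  max(nb) - sum(uptake * nb)
}

#' Discounted cumulative incident population
#'
#' Sums annual incident cohorts over the scale-up horizon, discounting each
#' cohort to present value. By default the first cohort arrives at t = 0
#' (undiscounted) and cohorts 2..H at t = 1..H-1.
#'
#' @param annual_incidence New eligible patients per year.
#' @param horizon_years Number of annual cohorts.
#' @param discount_rate Annual discount rate.
#' @param first_cohort_at 0 (default) or 1; timing of the first cohort.
#' @return Discounted population size, rounded to the nearest integer.
#' @examples
#' discounted_incident_population(9356, 10, 0.035)
#' @export
discounted_incident_population <- function(annual_incidence = 9356,
                                           horizon_years = 10,
                                           discount_rate = 0.035,
                                           first_cohort_at = 0) {
  stopifnot(horizon_years >= 1, annual_incidence >= 0,
            first_cohort_at %in% c(0, 1))
  t <- first_cohort_at + seq_len(horizon_years) - 1
  round(sum(annual_incidence * (1 + discount_rate)^(-t)))
}

#' Population-level expected value of perfect implementation
#'
#' Scales a per-person EVPImp up to the discounted future incident
#' population, reported both in monetary units and in QALYs (monetary value
#' divided by the threshold).
#'
#' @param per_person Per-person EVPImp in GBP.
#' @param population Population size (see
#'   [discounted_incident_population()]).
#' @param threshold GBP-per-QALY threshold used to express the result in
#'   QALYs.
#' @return A one-row tibble: `threshold`, `evpimp_per_person_gbp`,
#'   `evpimp_per_person_qaly`, `population`, `evpimp_population_gbp`,
#'   `evpimp_population_qaly`.
#' @export
population_evpimp <- function(per_person, population, threshold) {
  stopifnot(per_person >= 0, population >= 0, threshold > 0)
  tibble::tibble(
    threshold = threshold,
    evpimp_per_person_gbp = per_person,
    evpimp_per_person_qaly = per_person / threshold,
    population = population,
    evpimp_population_gbp = per_person * population,
    evpimp_population_qaly = per_person * population / threshold
  )
}

#' Value-of-implementation analysis for a base-case result
#'
#' Convenience wrapper: takes a deterministic [run_base_case()] result,
#' applies the implementation shares to each threshold's net monetary
#' benefits, and scales to the discounted incident population.
#'
#' @param cea A `petvoi_cea` object.
#' @param uptake Named implementation shares (default: published audit
#'   shares, 76% surgery + ET / 24% PET).
#' @param annual_incidence,horizon_years,discount_rate,first_cohort_at
#'   Population scale-up settings (see
#'   [discounted_incident_population()]).
#' @return A tibble with one row per threshold (columns as in
#'   [population_evpimp()]).
#' @examples
#' voi <- value_of_implementation(run_base_case())
#' voi$evpimp_per_person_gbp
#' @export
value_of_implementation <- function(cea,
                                    uptake = c(surgery_et = 0.76, pet = 0.24),
                                    annual_incidence = 9356,
                                    horizon_years = 10,
                                    discount_rate = 0.035,
                                    first_cohort_at = 0) {
  stopifnot(inherits(cea, "petvoi_cea"))
  pop <- discounted_incident_population(annual_incidence, horizon_years,
                                        discount_rate, first_cohort_at)
  purrr::map_dfr(unique(cea$comparison$nmb$threshold), function(th) {
    nmb_th <- dplyr::filter(cea$comparison$nmb, .data$threshold == th)
    nb <- stats::setNames(nmb_th$nmb, nmb_th$strategy)
    population_evpimp(evpimp_per_person(nb, uptake), pop, th)
  })
}
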