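#' Simulate right-censored individual participant data
#'
#' Event times are drawn from one of the five candidate families; observed
#' time is the minimum of the event time, an optional exponential
#' random-censoring time and the administrative censoring time. Emulates
#' the long-follow-up trial setting behind the model's survival inputs.
#'
#' @param family Family name as in [survival_model()].
#' @param params Named parameter vector for the family.
#' @param n Number of subjects.
#' @param admin_censor_time Administrative censoring time (years).
#' @param censor_rate Rate (per year) of exponential random censoring;
#'   0 disables it.
#' @param seed Optional integer seed (draws are deterministic given it).
#' @param arm Strategy label attached to the records.
#' @return A tibble of IPD records: `time`, `event`, `arm`.
#' @examples
#' ipd <- simulate_ipd("lognormal", c(meanlog = 1.40, sdlog = 0.98),
#'                     n = 100, admin_censor_time = 20, seed = 1)
#' @export
simulate_ipd <- function(family, params, n, admin_censor_time = 20,
                         censor_rate = 0, seed = NULL, arm = NA_character_) {
  model <- survival_model(family, params)  # validates family + parameters
  stopifnot(n >= 1, admin_censor_time >= 0, censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- model$params
  tev <- switch(family,
    exponential = stats::rexp(n, p[["rate"]]),
    weibull     = stats::rweibull(n, p[["shape"]], p[["scale"]]),
    gompertz    = flexsurv::rgompertz(n, p[["shape"]], p[["rate"]]),
    lognormal   = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = flexsurv::rllogis(n, shape = p[["shape"]],
                                    scale = 1 / p[["rate"]]))
  tcen <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  tcen <- pmin(tcen, admin_censor_time)
  tibble::tibble(time = pmin(tev, tcen),
                 event = as.integer(tev <= tcen),
                 arm = arm)
}

#' Emulate curve digitization and a numbers-at-risk table
#'
#' Reads the Kaplan-Meier estimate of a set of IPD records at a grid of
#' time points (right-continuous step convention) and counts subjects still
#' at risk at each risk-table interval start — the two artefacts a published
#' figure provides to the reconstruction stage.
#'
#' @param records IPD data frame (`time`, `event`).
#' @param grid Time points at which the curve is read.
#' @param intervals Risk-table interval start times.
#' @return A list with `curve` (tibble `time`, `survival`) and `risk`
#'   (tibble `interval_start`, `n_at_risk`).
#' @export
digitize_fixture <- function(records, grid, intervals = grid[1]) {
  stopifnot(length(grid) >= 1)
  if (max(grid) > max(records$time) + 1e-9) {
    stop("grid extends beyond the observed time span", call. = FALSE)
  }
  km <- kaplan_meier(records)
  curve <- tibble::tibble(time = sort(unique(grid)),
                          survival = km_survival_at(km, sort(unique(grid))))
  risk <- tibble::tibble(
    interval_start = sort(unique(intervals)),
    n_at_risk = vapply(sort(unique(intervals)),
                       function(s) sum(records$time >= s - 1e-12), 0L))
  list(curve = curve, risk = risk)
}

#' Write IPD / curve / risk-table fixtures as CSV
#'
#' Same dialects the reconstruction and fitting stages read back.
#'
#' @param x A data frame.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
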