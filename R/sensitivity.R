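#' Default one-way sensitivity ranges
#'
#' Low/high values for every uncertain input, taken from the published 95%
#' confidence intervals where printed and otherwise from the 2.5th/97.5th
#' percentiles of the probabilistic distribution. Survival-curve parameters
#' are varied by the published relative interval widths (the shipped curve
#' is calibrated, so the printed absolute intervals are applied
#' proportionally).
#'
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
default_sensitivity_ranges <- function() {
  fx <- .fixture_raw()
  p <- parameter_set()
  sv <- fx$pet_survival
  rel <- function(base, lit, lo, hi) c(base * lo / lit, base * hi / lit)
  os_shape <- rel(p$os_pet$params[["shape"]], sv$os$shape,
                  sv$os$shape_low, sv$os$shape_high)
  os_rate <- rel(p$os_pet$params[["rate"]], sv$os$location,
                 sv$os$scale_low, sv$os$scale_high)
  tb <- fx$transition_probabilities
  tibble::tribble(
    ~parameter, ~low, ~high,
    "hr_os",  fx$hazard_ratios$hr_os$low,  fx$hazard_ratios$hr_os$high,
    "hr_pfs", fx$hazard_ratios$hr_pfs$low, fx$hazard_ratios$hr_pfs$high,
    "os_shape", os_shape[1], os_shape[2],
    "os_rate",  os_rate[1],  os_rate[2],
    "pfs_meanlog", sv$pfs$location_low, sv$pfs$location_high,
    "pfs_sdlog",   sv$pfs$scale_low,    sv$pfs$scale_high,
    "p_met_surgery", stats::qbeta(0.025, tb$p_met_surgery$alpha, tb$p_met_surgery$beta),
                     stats::qbeta(0.975, tb$p_met_surgery$alpha, tb$p_met_surgery$beta),
    "p_met_pet", stats::qbeta(0.025, tb$p_met_pet$alpha, tb$p_met_pet$beta),
                 stats::qbeta(0.975, tb$p_met_pet$alpha, tb$p_met_pet$beta),
    "u_stable", fx$utilities$u_stable$low, fx$utilities$u_stable$high,
    "du_progressed", fx$utilities$du_progressed$low, fx$utilities$du_progressed$high,
    "du_metastatic", fx$utilities$du_metastatic$low, fx$utilities$du_metastatic$high,
    "du_age_annual", fx$utilities$du_age_annual$low, fx$utilities$du_age_annual$high,
    "p_mastectomy", fx$costs$p_mastectomy$low, fx$costs$p_mastectomy$high,
    "cost_progressed", fx$costs$cost_progressed$low, fx$costs$cost_progressed$high,
    "cost_metastatic", fx$costs$cost_metastatic$low, fx$costs$cost_metastatic$high
  )
}

#' Set a (possibly nested) parameter by name
#'
#' Understands the plain [parameter_set()] fields plus the survival-curve
#' shorthands `os_shape`, `os_rate`, `pfs_meanlog`, `pfs_sdlog`.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param value New value.
#' @return The modified parameter set.
#' @export
set_parameter <- function(params, name, value) {
  if (name %in% c("os_shape", "os_rate")) {
    tgt <- sub("os_", "", name)
    params$os_pet$params[[tgt]] <- value
  } else if (name %in% c("pfs_meanlog", "pfs_sdlog")) {
    tgt <- sub("pfs_", "", name)
    params$pfs_pet$params[[tgt]] <- value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  validate_parameter_set(params)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic comparison with each parameter set to its low
#' and high value in turn, reporting the incremental net monetary benefit of
#' surgery + ET at the chosen threshold and the swing (absolute difference
#' between the two ends).
#'
#' @param params Base-case [parameter_set()].
#' @param ranges Tibble of `parameter`, `low`, `high`
#'   (default [default_sensitivity_ranges()]). Inverted ranges are swapped
#'   with a warning.
#' @param threshold GBP-per-QALY threshold.
#' @return A tibble of class `petvoi_tornado`, sorted by decreasing swing,
#'   with columns `parameter`, `low`, `high`, `inmb_low`, `inmb_high`,
#'   `inmb_base`, `swing`.
#' @export
one_way_sensitivity <- function(params = default_parameters(),
                                ranges = default_sensitivity_ranges(),
                                threshold = 20000) {
  stopifnot(all(c("parameter", "low", "high") %in% names(ranges)))
  inv <- ranges$low > ranges$high
  if (any(inv)) {
    warning("inverted range(s) swapped: ",
            paste(ranges$parameter[inv], collapse = ", "), call. = FALSE)
    tmp <- ranges$low[inv]
    ranges$low[inv] <- ranges$high[inv]
    ranges$high[inv] <- tmp
  }
  inmb_at <- function(p) {
    res <- run_base_case(p, thresholds = threshold)
    unname(res$comparison$inmb[1])
  }
  base_inmb <- inmb_at(params)
  out <- purrr::pmap_dfr(ranges, function(parameter, low, high) {
    tibble::tibble(
      parameter = parameter, low = low, high = high,
      inmb_low = inmb_at(set_parameter(params, parameter, low)),
      inmb_high = inmb_at(set_parameter(params, parameter, high)))
  })
  out <- dplyr::mutate(out, inmb_base = base_inmb,
                       swing = abs(.data$inmb_high - .data$inmb_low))
  out <- dplyr::arrange(out, dplyr::desc(.data$swing))
  class(out) <- c("petvoi_tornado", class(out))
  attr(out, "threshold") <- threshold
  out
}
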