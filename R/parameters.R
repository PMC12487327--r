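#' Model parameter set
#'
#' Builds the complete set of inputs for one deterministic model run. All
#' defaults come from the shipped parameter fixture (see
#' [default_parameter_fixture()]); any field can be overridden by name.
#' Times are in years and monetary values in GBP throughout.
#'
#' The survival inputs describe the primary endocrine therapy (PET) arm;
#' the surgery + ET arm is derived by proportional-hazards adjustment with
#' `hr_os` and `hr_pfs`.
#'
#' @param ... Named overrides of any field listed below.
#' @param survival `"calibrated"` (default) uses the overall-survival
#'   log-logistic curve calibrated so the model reproduces the published
#'   life expectancy and median survival; `"literal"` maps the published
#'   Stata-style parameters directly (shape as the ancillary parameter, the
#'   location exponentiated to a rate).
#'
#' @section Fields:
#' `os_pet`, `pfs_pet` ([survival_model()] objects); `hr_os`, `hr_pfs`;
#' `p_met_surgery`, `p_met_pet` (metastatic share of the progressed state);
#' `u_stable`, `du_progressed`, `du_metastatic`, `du_age_annual`,
#' `progressed_utility` (`"uniform"`: the whole progressed state carries the
#' metastatic decrement; `"split"`: substate-specific decrements);
#' `cost_surgery_oneoff` (`NULL` = mastectomy/BCS tariff mix),
#' `cost_mastectomy`, `cost_bcs`, `p_mastectomy`, `cost_hospital_stay`,
#' `include_hospital_stay`, `cost_tamoxifen_daily`, `cost_letrozole_daily`,
#' `tamoxifen_years`, `letrozole_years`, `cost_followup`, `followup_years`,
#' `cost_progressed`, `cost_metastatic` (annual state costs),
#' `progression_cost_mode` (`"entry_episode"` or `"per_year"`),
#' `tp_prog_death`, `tp_met_death` (used only in `mode = "markov"`),
#' `discount_rate`, `discount_per_cycle`, `baseline_age`, `horizon_years`,
#' `cycle_length`, `mode` (`"psm"` or `"markov"`).
#'
#' @return An object of class `parameter_set` (a validated named list).
#' @examples
#' p <- parameter_set(horizon_years = 20)
#' p$horizon_years
#' @export
parameter_set <- function(..., survival = c("calibrated", "literal")) {
  survival <- match.arg(survival)
  fx <- .fixture_raw()
  os <- if (survival == "calibrated") {
    survival_model("loglogistic",
                   shape = fx$pet_survival$os_calibrated$shape,
                   rate  = fx$pet_survival$os_calibrated$rate)
  } else {
    survival_model("loglogistic",
                   shape = fx$pet_survival$os$shape,
                   rate  = exp(-fx$pet_survival$os$location))
  }
  defaults <- list(
    os_pet = os,
    pfs_pet = survival_model("lognormal",
                             meanlog = fx$pet_survival$pfs$location,
                             sdlog   = fx$pet_survival$pfs$scale),
    hr_os  = fx$hazard_ratios$hr_os$value,
    hr_pfs = fx$hazard_ratios$hr_pfs$value,
    p_met_surgery = fx$transition_probabilities$p_met_surgery$value,
    p_met_pet     = fx$transition_probabilities$p_met_pet$value,
    u_stable      = fx$utilities$u_stable$value,
    du_progressed = fx$utilities$du_progressed$value,
    du_metastatic = fx$utilities$du_metastatic$value,
    du_age_annual = fx$utilities$du_age_annual$value,
    progressed_utility = "uniform",
    cost_surgery_oneoff = NULL,
    cost_surgery_aggregate = fx$costs$cost_surgery_aggregate$value,
    cost_mastectomy = fx$costs$cost_mastectomy$value,
    cost_bcs        = fx$costs$cost_bcs$value,
    p_mastectomy    = fx$costs$p_mastectomy$value,
    cost_hospital_stay = fx$costs$cost_hospital_stay$value,
    include_hospital_stay = FALSE,
    cost_tamoxifen_daily = fx$costs$cost_tamoxifen_daily$value,
    cost_letrozole_daily = fx$costs$cost_letrozole_daily$value,
    tamoxifen_years = 5,
    letrozole_years = 5,
    cost_followup   = fx$costs$cost_followup$value,
    followup_years  = 10,
    cost_progressed = fx$costs$cost_progressed$value,
    cost_metastatic = fx$costs$cost_metastatic$value,
    progression_cost_mode = "entry_episode",
    tp_prog_death = fx$transition_probabilities$tp_prog_death$value,
    tp_met_death  = fx$transition_probabilities$tp_met_death$value,
    discount_rate = fx$settings$discount_rate,
    discount_per_cycle = TRUE,
    baseline_age  = fx$settings$baseline_age,
    horizon_years = fx$settings$horizon_years,
    cycle_length  = fx$settings$cycle_length,
    mode = "psm"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  validate_parameter_set(structure(defaults, class = "parameter_set"))
}

#' @rdname parameter_set
#' @export
default_parameters <- function(..., survival = "calibrated") {
  parameter_set(..., survival = survival)
}

validate_parameter_set <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  probs <- c("p_met_surgery", "p_met_pet", "p_mastectomy",
             "tp_prog_death", "tp_met_death")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  costs <- c("cost_surgery_aggregate", "cost_mastectomy", "cost_bcs",
             "cost_hospital_stay", "cost_tamoxifen_daily",
             "cost_letrozole_daily", "cost_followup", "cost_progressed",
             "cost_metastatic")
  for (nm in costs) {
    if (p[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (p$hr_os <= 0 || p$hr_pfs <= 0) stop("hazard ratios must be positive",
                                          call. = FALSE)
  if (p$cycle_length <= 0) stop("cycle_length must be positive", call. = FALSE)
  ncyc <- p$horizon_years / p$cycle_length
  if (abs(ncyc - round(ncyc)) > 1e-9) {
    stop("horizon_years must be a whole number of cycles", call. = FALSE)
  }
  if (!p$mode %in% c("psm", "markov")) stop("mode must be 'psm' or 'markov'",
                                            call. = FALSE)
  if (!p$progressed_utility %in% c("uniform", "split")) {
    stop("progressed_utility must be 'uniform' or 'split'", call. = FALSE)
  }
  if (!p$progression_cost_mode %in% c("entry_episode", "per_year")) {
    stop("progression_cost_mode must be 'entry_episode' or 'per_year'",
         call. = FALSE)
  }
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  PET OS:  "); print(x$os_pet)
  cat("  PET PFS: "); print(x$pfs_pet)
  cat(sprintf("  HR (OS) %.2f, HR (PFS) %.2f; horizon %g y, cycle %g y, %s mode\n",
              x$hr_os, x$hr_pfs, x$horizon_years, x$cycle_length, x$mode))
  cat(sprintf("  discount %.1f%% %s\n", 100 * x$discount_rate,
              if (x$discount_per_cycle) "per cycle" else "per year"))
  invisible(x)
}

#' The shipped parameter fixture
#'
#' Loads the model's input-parameter fixture: every point value together
#' with its probabilistic-analysis distribution, plus the calibrated
#' overall-survival curve. The fixture ships as a YAML file under
#' `inst/extdata` and round-trips losslessly through [write_parameter_fixture()].
#'
#' @param path Optional path to an alternative fixture file.
#' @return A list with elements `parameters` (a [parameter_set()]),
#'   `distributions` (a tibble of distribution specifications, see
#'   [default_distributions()]) and `raw` (the parsed fixture).
#' @export
default_parameter_fixture <- function(path = NULL) {
  raw <- .fixture_raw(path)
  structure(list(parameters = parameter_set(),
                 distributions = .distributions_from_raw(raw),
                 raw = raw),
            class = "petvoi_fixture")
}

.fixture_raw <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.petvoi_cache$raw)) return(.petvoi_cache$raw)
    path <- system.file("extdata", "model_parameters.yaml", package = "petvoi")
    .petvoi_cache$raw <- yaml::read_yaml(path)
    return(.petvoi_cache$raw)
  }
  yaml::read_yaml(path)
}

.petvoi_cache <- new.env(parent = emptyenv())

#' @export
print.petvoi_fixture <- function(x, ...) {
  cat("<petvoi_fixture> model parameter fixture;",
      nrow(x$distributions), "distribution specs\n")
  invisible(x)
}

#' Write a parameter fixture back to YAML
#'
#' @param fixture Output of [default_parameter_fixture()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_parameter_fixture <- function(fixture, path) {
  yaml::write_yaml(fixture$raw, path, precision = 15)
  invisible(path)
}

#' Probabilistic distribution specifications
#'
#' One row per uncertain model parameter: the distribution family and its
#' parameters as published. Gamma-distributed costs carry a `rescale`
#' factor applied to each draw so that the sampled mean equals the
#' deterministic annual cost (the published gamma means are exactly twice
#' the point values). Correlated survival-curve parameters are drawn via
#' the published Cholesky factors (`dist = "mvnorm_chol"`, columns
#' `par1`-`par3` holding L11, L21, L22).
#'
#' @return A tibble with columns `parameter`, `dist`, `par1`, `par2`,
#'   `par3`, `rescale`.
#' @export
default_distributions <- function() {
  default_parameter_fixture()$distributions
}

.distributions_from_raw <- function(raw) {
  row <- function(parameter, dist, par1, par2 = NA_real_, par3 = NA_real_,
                  rescale = 1) {
    tibble::tibble(parameter = parameter, dist = dist, par1 = par1,
                   par2 = par2, par3 = par3, rescale = rescale)
  }
  hr <- raw$hazard_ratios; tp <- raw$transition_probabilities
  ut <- raw$utilities; co <- raw$costs; sv <- raw$pet_survival
  dplyr::bind_rows(
    row("hr_os",  "lognormal", hr$hr_os$mean,  hr$hr_os$sd),
    row("hr_pfs", "lognormal", hr$hr_pfs$mean, hr$hr_pfs$sd),
    row("os_pet",  "mvnorm_chol", sv$os$cholesky[1],  sv$os$cholesky[2],
        sv$os$cholesky[3]),
    row("pfs_pet", "mvnorm_chol", sv$pfs$cholesky[1], sv$pfs$cholesky[2],
        sv$pfs$cholesky[3]),
    row("tp_prog_death", "beta", tp$tp_prog_death$alpha, tp$tp_prog_death$beta),
    row("tp_met_death",  "beta", tp$tp_met_death$alpha,  tp$tp_met_death$beta),
    row("p_met_surgery", "beta", tp$p_met_surgery$alpha, tp$p_met_surgery$beta),
    row("p_met_pet",     "beta", tp$p_met_pet$alpha,     tp$p_met_pet$beta),
    row("u_stable",      "beta", ut$u_stable$alpha,      ut$u_stable$beta),
    row("du_progressed", "normal", ut$du_progressed$mean, ut$du_progressed$se),
    row("du_metastatic", "normal", ut$du_metastatic$mean, ut$du_metastatic$se),
    row("du_age_annual", "normal", ut$du_age_annual$mean, ut$du_age_annual$se),
    row("p_mastectomy",  "beta", co$p_mastectomy$alpha, co$p_mastectomy$beta),
    row("cost_progressed", "gamma", co$cost_progressed$shape,
        co$cost_progressed$scale, rescale = 0.5),
    row("cost_metastatic", "gamma", co$cost_metastatic$shape,
        co$cost_metastatic$scale, rescale = 0.5)
  )
}

#' Effective one-off surgery cost
#'
#' The default surgical one-off is the tariff mix
#' `p_mastectomy * cost_mastectomy + (1 - p_mastectomy) * cost_bcs`;
#' setting `cost_surgery_oneoff` (e.g. to the published aggregate
#' `cost_surgery_aggregate`, which also covers delayed reconstruction)
#' overrides it. The hospital-stay tariff is added when
#' `include_hospital_stay` is `TRUE`.
#'
#' @param params A [parameter_set()].
#' @return One-off cost in GBP charged at model start in the surgery arm.
#' @export
surgery_cost <- function(params) {
  base <- if (!is.null(params$cost_surgery_oneoff)) {
    params$cost_surgery_oneoff
  } else {
    params$p_mastectomy * params$cost_mastectomy +
      (1 - params$p_mastectomy) * params$cost_bcs
  }
  base + if (isTRUE(params$include_hospital_stay)) params$cost_hospital_stay else 0
}
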