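#' Construct a parametric survival model
#'
#' A lightweight container for a named parametric time-to-event
#' distribution evaluated on a time axis in years. Five families are
#' supported, each with an explicitly declared parametrization:
#'
#' * `exponential`: `rate` (events per year), S(t) = exp(-rate * t)
#' * `weibull`: `shape`, `scale` (as [stats::pweibull()])
#' * `gompertz`: `shape`, `rate` (as [flexsurv::pgompertz()])
#' * `lognormal`: `meanlog` (location on log-time), `sdlog` (scale)
#' * `loglogistic`: `shape`, `rate`, S(t) = 1 / (1 + (rate * t)^shape)
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param ... Named numeric parameters for the family (see above).
#'
#' @return An object of class `survmodel`.
#' @examples
#' m <- survival_model("exponential", rate = 0.1)
#' survival_probability(m, 5)
#' @export
survival_model <- function(family, ...) {
  family <- match.arg(family, names(.sm_params))
  params <- c(...)
  expected <- .sm_params[[family]]
  if (!setequal(names(params), expected)) {
    stop("family '", family, "' needs parameters: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  params <- params[expected]
  if (any(!is.finite(params))) stop("parameters must be finite", call. = FALSE)
  positive <- setdiff(expected, "meanlog")
  if (any(params[positive] <= 0)) {
    stop("parameters ", paste(positive, collapse = ", "),
         " must be positive for family '", family, "'", call. = FALSE)
  }
  structure(list(family = family, params = params), class = "survmodel")
}

.sm_params <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  lognormal   = c("meanlog", "sdlog"),
  loglogistic = c("shape", "rate")
)

#' @export
print.survmodel <- function(x, ...) {
  cat("<survmodel> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 5), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Survival probability S(t)
#'
#' @param model A [survival_model()] or a hazard-ratio adjusted model from
#'   [apply_hazard_ratio()].
#' @param t Non-negative time(s) in years.
#' @return Numeric vector of survival probabilities.
#' @export
survival_probability <- function(model, t) {
  UseMethod("survival_probability")
}

#' @export
survival_probability.survmodel <- function(model, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  p <- model$params
  switch(model$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = 1 / (1 + (p[["rate"]] * t)^p[["shape"]])
  )
}

#' @export
survival_probability.survmodel_ph <- function(model, t) {
  survival_probability(model$base, t)^model$hr
}

#' Apply a proportional-hazards adjustment
#'
#' Returns a model whose survival function is `S(t)^hr`, i.e. the hazard of
#' the base model scaled by the hazard ratio `hr`. Used to derive the
#' surgery + endocrine therapy arm from the PET arm's fitted curves.
#'
#' @param model A [survival_model()].
#' @param hr Positive hazard ratio.
#' @return An object of class `survmodel_ph`; [survival_probability()] and
#'   [median_survival_time()] work on it as on the base model.
#' @export
apply_hazard_ratio <- function(model, hr) {
  stopifnot(inherits(model, c("survmodel", "survmodel_ph")))
  if (!is.numeric(hr) || length(hr) != 1 || !is.finite(hr) || hr <= 0) {
    stop("hr must be a positive number", call. = FALSE)
  }
  if (inherits(model, "survmodel_ph")) {
    return(structure(list(base = model$base, hr = model$hr * hr),
                     class = "survmodel_ph"))
  }
  structure(list(base = model, hr = hr), class = "survmodel_ph")
}

#' @export
print.survmodel_ph <- function(x, ...) {
  cat("<survmodel> hazard-ratio adjusted (hr = ", signif(x$hr, 5), ") of:\n  ",
      sep = "")
  print(x$base)
  invisible(x)
}

#' Median survival time
#'
#' Time t at which S(t) = 0.5, by closed form where the family admits one
#' and otherwise by bracketed root finding to 1e-6 years.
#'
#' @param model A [survival_model()] or hazard-ratio adjusted model.
#' @param upper Horizon (years) searched for the median before declaring it
#'   not reached.
#' @return Median in years, or `NA_real_` with a warning when survival never
#'   falls to 0.5 before `upper`.
#' @export
median_survival_time <- function(model, upper = 200) {
  if (inherits(model, "survmodel")) {
    p <- model$params
    closed <- switch(model$family,
      exponential = log(2) / p[["rate"]],
      lognormal   = exp(p[["meanlog"]]),
      loglogistic = 1 / p[["rate"]],
      weibull     = p[["scale"]] * log(2)^(1 / p[["shape"]]),
      NULL)
    if (!is.null(closed)) return(closed)
  }
  f <- function(t) survival_probability(model, t) - 0.5
  if (f(upper) > 0) {
    warning("median survival not reached within ", upper, " years")
    return(NA_real_)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-6)$root
}
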