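#' Fit a parametric survival model to right-censored data
#'
#' Maximum-likelihood fitting of one of the five candidate extrapolation
#' families to individual participant data (IPD). Estimation is delegated
#' to [flexsurv::flexsurvreg()]; the fitted coefficients are mapped onto the
#' parametrization declared in [survival_model()].
#'
#' @param data A data frame with columns `time` (years, non-negative) and
#'   `event` (1 = event, 0 = right-censored). Extra columns (e.g. `arm`)
#'   are ignored.
#' @param family Family name as in [survival_model()].
#' @return An object of class `petvoi_fit`: a list with elements `model`
#'   (a [survival_model()]), `family`, `loglik`, `aic`, `bic`, `n`,
#'   `n_events`, `vcov` (covariance of the estimates on the estimation
#'   scale) and `ci` (natural-scale estimates with 95% limits).
#' @examples
#' ipd <- simulate_ipd("exponential", c(rate = 0.2), n = 200, seed = 1)
#' fit <- fit_parametric_survival(ipd, "exponential")
#' glance(fit)
#' @export
fit_parametric_survival <- function(data, family) {
  family <- match.arg(family, names(.sm_params))
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  time <- data$time
  event <- data$event
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  if (sum(event) < 2) {
    stop("no-events error: need at least 2 events to identify the likelihood",
         call. = FALSE)
  }
  dist <- switch(family, exponential = "exp", weibull = "weibull",
                 gompertz = "gompertz", lognormal = "lnorm",
                 loglogistic = "llogis")
  # flexsurv chokes on t = 0; nudge to half the smallest positive time
  tpos <- time
  if (any(tpos == 0)) tpos[tpos == 0] <- min(tpos[tpos > 0], 1) / 2
  df <- data.frame(time = tpos, event = event)
  fs <- NULL
  for (attempt in 1:3) {
    inits <- if (attempt == 1) NULL else .fit_inits(df, dist, attempt)
    fs <- tryCatch(
      flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = df,
                            dist = dist, inits = inits),
      error = function(e) e)
    if (!inherits(fs, "error")) break
  }
  if (inherits(fs, "error")) {
    stop("convergence error after 3 starting points: ",
         conditionMessage(fs), call. = FALSE)
  }
  est <- stats::setNames(fs$res[, "est"], rownames(fs$res))
  params <- switch(family,
    exponential = c(rate = unname(est["rate"])),
    weibull     = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    gompertz    = c(shape = unname(est["shape"]), rate = unname(est["rate"])),
    lognormal   = c(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"])),
    loglogistic = c(shape = unname(est["shape"]), rate = 1 / unname(est["scale"])))
  k <- fs$npars
  n <- nrow(df)
  structure(list(
    model = survival_model(family,
                           stats::setNames(unname(params), names(params))),
    family = family,
    loglik = fs$loglik,
    aic = 2 * k - 2 * fs$loglik,
    bic = k * log(n) - 2 * fs$loglik,
    n = n,
    n_events = sum(event),
    k = k,
    vcov = fs$cov,
    ci = fs$res
  ), class = "petvoi_fit")
}

.fit_inits <- function(df, dist, attempt) {
  rate <- sum(df$event) / sum(df$time)
  scl <- if (attempt == 2) 1 else 4
  switch(dist,
    exp      = rate * scl,
    weibull  = c(1 * scl, 1 / rate),
    gompertz = c(0.001 * scl, rate),
    lnorm    = c(log(1 / rate), scl),
    llogis   = c(1 * scl, 1 / rate))
}

#' @export
print.petvoi_fit <- function(x, ...) {
  cat("<petvoi_fit> ", x$family, " fit, n = ", x$n, " (", x$n_events,
      " events)\n", sep = "")
  print(x$model)
  cat(sprintf("  loglik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$loglik, x$aic, x$bic))
  invisible(x)
}

#' @rdname fit_parametric_survival
#' @param x,.x A `petvoi_fit` object.
#' @exportS3Method generics::tidy
tidy.petvoi_fit <- function(x, ...) {
  ci <- x$ci
  tibble::tibble(term = rownames(ci),
                 estimate = ci[, "est"],
                 conf.low = ci[, "L95%"],
                 conf.high = ci[, "U95%"])
}

#' @rdname fit_parametric_survival
#' @exportS3Method generics::glance
glance.petvoi_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, nobs = x$n, n_events = x$n_events, df = x$k)
}

#' Fit all five candidate families
#'
#' @inheritParams fit_parametric_survival
#' @return A named list of `petvoi_fit` objects.
#' @export
fit_all_families <- function(data) {
  fams <- names(.sm_params)
  stats::setNames(lapply(fams, function(f) fit_parametric_survival(data, f)),
                  fams)
}

#' Rank fitted models by information criteria
#'
#' Orders candidate fits by ascending AIC, breaking ties by BIC. The full
#' table is returned so the visual-plausibility check can be made by the
#' caller; the top row is the selected family.
#'
#' @param fits A list of `petvoi_fit` objects fitted to the same data.
#' @return A tibble with one row per fit, ranked.
#' @export
select_best_fit <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "petvoi_fit")))
  ns <- vapply(fits, `[[`, 0, "n")
  if (length(unique(ns)) != 1) {
    stop("inconsistency error: fits were made on differing sample sizes (",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(fits, glance))
  out <- dplyr::arrange(out, .data$AIC, .data$BIC)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Write a fit report as JSON
#'
#' @param fit A `petvoi_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "petvoi_fit"))
  jsonlite::write_json(list(
    family = fit$family,
    params = as.list(fit$model$params),
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic, n = fit$n,
    vcov = unclass(fit$vcov)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
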