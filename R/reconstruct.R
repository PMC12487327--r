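#' Reconstruct individual participant data from a digitized survival curve
#'
#' Deterministic reconstruction of event and censoring times from digitized
#' Kaplan-Meier coordinates and a numbers-at-risk table, in the style of the
#' published curve-reconstruction algorithm used throughout health
#' technology assessment. Within each risk-table interval the number
#' censored is solved iteratively so that the implied number at risk at the
#' start of the next interval matches the published count, censoring times
#' being spread evenly across the interval (constant censoring rate). Event
#' counts at each digitized step are chosen so the product-limit estimate of
#' the output tracks the input curve.
#'
#' @param curve Data frame with columns `time` (years, strictly increasing)
#'   and `survival` (non-increasing, in `[0, 1]`).
#' @param risk Data frame with columns `interval_start` (years) and
#'   `n_at_risk` (non-increasing counts). Must cover the curve's time span.
#' @param total_events Optional total number of events; when supplied, event
#'   counts are rescaled so their sum matches it.
#' @param arm Optional strategy label attached to the output.
#' @return A tibble of IPD records with columns `time`, `event` and `arm`;
#'   one row per subject, `nrow` equal to the first at-risk count.
#' @examples
#' curve <- tibble::tibble(time = c(0, 1), survival = c(1, 0.5))
#' risk <- tibble::tibble(interval_start = 0, n_at_risk = 100)
#' ipd <- reconstruct_ipd(curve, risk)
#' sum(ipd$event)
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL, arm = NA_character_) {
  .check_curve(curve)
  .check_risk(risk)
  tk <- curve$time
  Sk <- curve$survival
  if (min(risk$interval_start) > min(tk) + 1e-9) {
    stop("coverage error: risk table starts after the curve does", call. = FALSE)
  }
  # drop risk intervals beyond the digitized span; they constrain nothing
  risk <- risk[risk$interval_start <= max(tk) + 1e-9, , drop = FALSE]
  nint <- nrow(risk)
  nrisk <- risk$n_at_risk
  bounds <- c(risk$interval_start, max(tk) + 1e-9)
  # click indices in [bounds_i, bounds_{i+1})
  lower <- vapply(seq_len(nint), function(i) {
    w <- which(tk >= bounds[i] - 1e-12 & tk < bounds[i + 1])
    if (length(w)) min(w) else NA_integer_
  }, 1L)
  upper <- vapply(seq_len(nint), function(i) {
    w <- which(tk >= bounds[i] - 1e-12 & tk < bounds[i + 1])
    if (length(w)) max(w) else NA_integer_
  }, 1L)
  last_click <- max(tk)

  ev_t <- numeric(0); cen_t <- numeric(0)
  n_hat <- nrisk[1]
  SKM <- 1
  for (i in seq_len(nint)) {
    if (is.na(lower[i])) next
    idx <- lower[i]:upper[i]
    is_last <- i == nint
    target <- if (!is_last) nrisk[i + 1] else NA_integer_
    # initial censoring guess from the survival drop across the interval
    if (!is_last) {
      Send <- Sk[lower[i + 1]]
      guess <- round(n_hat * (if (SKM > 0) Send / SKM else 0)) - target
      ncen <- max(0, min(n_hat, guess))
    } else {
      ncen <- 0  # within-interval censoring; survivors censored at end
    }
    span <- c(tk[idx[1]], if (!is_last) bounds[i + 1] else last_click)
    for (iter in 1:60) {
      cen_times <- if (ncen > 0)
        span[1] + (seq_len(ncen) - 0.5) / ncen * (span[2] - span[1]) else numeric(0)
      n_run <- n_hat; S_run <- SKM
      ev_i <- integer(length(idx)); cen_used <- 0
      for (j in seq_along(idx)) {
        k <- idx[j]
        d <- if (S_run > 0 && n_run > 0) round(n_run * (1 - Sk[k] / S_run)) else 0
        d <- max(0, min(n_run, d))
        if (d > 0) S_run <- S_run * (1 - d / n_run)
        ev_i[j] <- d
        n_run <- n_run - d
        t_next <- if (j < length(idx)) tk[idx[j + 1]] else span[2] + 1e-12
        c_here <- sum(cen_times >= tk[k] & cen_times < t_next)
        c_here <- min(c_here, n_run)
        cen_used <- cen_used + c_here
        n_run <- n_run - c_here
      }
      if (is_last || n_run == target || iter == 60) {
        # commit this interval
        ev_t <- c(ev_t, rep(tk[idx], ev_i))
        cen_t <- c(cen_t, cen_times[seq_len(cen_used)])
        n_hat <- n_run; SKM <- S_run
        break
      }
      ncen <- max(0, min(n_hat, ncen + (n_run - target)))
    }
  }
  # survivors at the end of follow-up are administratively censored
  if (n_hat > 0) cen_t <- c(cen_t, rep(last_click, n_hat))

  if (!is.null(total_events) && length(ev_t) > 0 && total_events != length(ev_t)) {
    # rescale event counts per step to match the published total
    tab <- table(ev_t)
    scaled <- round(as.numeric(tab) * total_events / length(ev_t))
    ev_t2 <- rep(as.numeric(names(tab)), scaled)
    delta <- length(ev_t) - length(ev_t2)
    ev_t <- ev_t2
    cen_t <- c(cen_t, rep(last_click, delta))  # keep n constant
  }
  out <- tibble::tibble(
    time = c(ev_t, cen_t),
    event = c(rep(1, length(ev_t)), rep(0, length(cen_t))),
    arm = arm
  )
  dplyr::arrange(out, .data$time, dplyr::desc(.data$event))
}

.check_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("time", "survival") %in% names(curve)))
  if (nrow(curve) < 1) stop("curve is empty", call. = FALSE)
  if (is.unsorted(curve$time, strictly = TRUE)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(curve$survival) > 1e-9)) {
    stop("monotonicity error: survival must be non-increasing", call. = FALSE)
  }
  if (any(curve$survival < -1e-12 | curve$survival > 1 + 1e-12)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  invisible(curve)
}

.check_risk <- function(risk) {
  stopifnot(is.data.frame(risk),
            all(c("interval_start", "n_at_risk") %in% names(risk)))
  if (nrow(risk) < 1) stop("risk table is empty", call. = FALSE)
  if (any(diff(risk$n_at_risk) > 0)) {
    stop("n_at_risk must be non-increasing", call. = FALSE)
  }
  if (any(risk$n_at_risk < 0)) stop("counts must be non-negative", call. = FALSE)
  invisible(risk)
}

#' Kaplan-Meier estimate of reconstructed or simulated IPD
#'
#' Product-limit estimator, used to validate reconstruction round trips.
#' Wraps [survival::survfit()].
#'
#' @param data Data frame with columns `time` and `event`.
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`
#'   and `survival` (one row per distinct observed time).
#' @export
kaplan_meier <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (nrow(data) == 0) stop("empty input", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  tibble::tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, survival = sf$surv)
}

#' Evaluate a Kaplan-Meier step curve at arbitrary times
#'
#' Right-continuous step convention: the estimate holds from each event
#' time until the next.
#'
#' @param km Output of [kaplan_meier()] (or any data frame with `time` and
#'   `survival` defining a step function).
#' @param times Times at which to read the curve.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(all(c("time", "survival") %in% names(km)))
  vapply(times, function(t) {
    w <- which(km$time <= t + 1e-12)
    if (length(w) == 0) 1 else km$survival[max(w)]
  }, 1)
}

#' Read digitized curve / risk-table CSV files
#'
#' @param path CSV file. Curves have columns `time,survival`; risk tables
#'   `interval_start,n_at_risk`.
#' @return A tibble.
#' @export
read_curve_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  .check_curve(out)
  out
}

#' @rdname read_curve_csv
#' @export
read_risk_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  .check_risk(out)
  out
}

#' Read an IPD CSV (columns time, event, arm; times in years)
#'
#' @param path CSV file path.
#' @return A tibble with columns `time`, `event`, `arm`.
#' @export
read_ipd_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time", "event") %in% names(out)))
  if (!"arm" %in% names(out)) out$arm <- NA_character_
  out
}
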