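#' Survival curves for a strategy
#'
#' The PET arm uses the fitted/calibrated curves directly; the surgery + ET
#' arm applies the overall-survival and progression-free-survival hazard
#' ratios to them.
#'
#' @param params A [parameter_set()].
#' @param strategy `"surgery_et"` or `"pet"`.
#' @return A list with `os` and `pfs` models (evaluable with
#'   [survival_probability()]).
#' @export
strategy_survival <- function(params, strategy = c("surgery_et", "pet")) {
  strategy <- match.arg(strategy)
  if (strategy == "pet") {
    list(os = params$os_pet, pfs = params$pfs_pet)
  } else {
    list(os = apply_hazard_ratio(params$os_pet, params$hr_os),
         pfs = apply_hazard_ratio(params$pfs_pet, params$hr_pfs))
  }
}

#' Build the partitioned survival state trace
#'
#' Evaluates the strategy's overall-survival (OS) and progression-free
#' survival (PFS) curves at every cycle boundary and partitions the cohort
#' into stable (= PFS, clipped to OS), progressed (= OS - PFS, split into a
#' local and a metastatic substate by the arm-specific metastatic share) and
#' dead (= 1 - OS). Each row also carries the half-cycle-corrected
#' occupancy of the cycle *ending* at that boundary (the mean of the two
#' adjacent boundary values; `NA` on the row for cycle 0).
#'
#' In `mode = "markov"` the stable state still follows the PFS curve but
#' death from the progressed substates is governed by the per-cycle death
#' probabilities `tp_prog_death` and `tp_met_death` instead of the OS curve.
#'
#' @param params A [parameter_set()].
#' @param strategy `"surgery_et"` or `"pet"`.
#' @param os,pfs Optional survival functions or models overriding the ones
#'   implied by `params` (used when tracing reconstructed/fitted curves).
#' @return A tibble of class `petvoi_trace`, one row per cycle boundary,
#'   with columns `cycle`, `time`, `age`, `stable`, `progressed_local`,
#'   `metastatic`, `dead`, `entrants` (exits from stable during the cycle)
#'   and `hcc_*` half-cycle-corrected occupancies.
#' @examples
#' tr <- build_partition_trace(default_parameters(), "pet")
#' head(tr)
#' @export
build_partition_trace <- function(params, strategy = c("surgery_et", "pet"),
                                  os = NULL, pfs = NULL) {
  strategy <- match.arg(strategy)
  curves <- strategy_survival(params, strategy)
  if (!is.null(os)) curves$os <- os
  if (!is.null(pfs)) curves$pfs <- pfs
  ev <- function(m, t) {
    if (is.function(m)) m(t) else survival_probability(m, t)
  }
  n_cycles <- round(params$horizon_years / params$cycle_length)
  tt <- seq(0, params$horizon_years, length.out = n_cycles + 1)
  S_os <- ev(curves$os, tt)
  S_pfs <- ev(curves$pfs, tt)
  if (abs(S_os[1] - 1) > 1e-6 || abs(S_pfs[1] - 1) > 1e-6) {
    stop("curve error: survival at time 0 must equal 1", call. = FALSE)
  }
  S_pfs <- pmin(S_pfs, S_os)  # partitioned-survival consistency clip
  p_met <- if (strategy == "surgery_et") params$p_met_surgery else params$p_met_pet

  if (params$mode == "psm") {
    stable <- S_pfs
    prog <- pmax(0, S_os - S_pfs)
    dead <- 1 - S_os
  } else {
    # state-transition variant: progressed substates drain at the
    # published per-cycle death probabilities, OS curve unused
    stable <- S_pfs
    loc <- met <- dead <- numeric(length(tt))
    for (k in seq_len(length(tt) - 1)) {
      entr <- max(0, stable[k] - stable[k + 1])
      d_loc <- loc[k] * params$tp_prog_death
      d_met <- met[k] * params$tp_met_death
      loc[k + 1] <- loc[k] - d_loc + entr * (1 - p_met)
      met[k + 1] <- met[k] - d_met + entr * p_met
      dead[k + 1] <- dead[k] + d_loc + d_met
    }
    prog <- loc + met
  }
  if (any(prog < -1e-9)) stop("internal invariant error: negative occupancy",
                              call. = FALSE)
  if (params$mode == "psm") {
    loc <- prog * (1 - p_met)
    met <- prog * p_met
  }
  entrants <- c(NA, pmax(0, stable[-length(stable)] - stable[-1]))
  hcc <- function(x) c(NA, (x[-length(x)] + x[-1]) / 2)
  out <- tibble::tibble(
    cycle = 0:n_cycles,
    time = tt,
    age = params$baseline_age + tt,
    stable = stable,
    progressed_local = loc,
    metastatic = met,
    dead = if (params$mode == "psm") dead else 1 - stable - loc - met,
    entrants = entrants,
    hcc_stable = hcc(stable),
    hcc_progressed_local = hcc(loc),
    hcc_metastatic = hcc(met),
    hcc_dead = hcc(if (params$mode == "psm") dead else 1 - stable - loc - met)
  )
  class(out) <- c("petvoi_trace", class(out))
  attr(out, "strategy") <- strategy
  out
}

#' State utility values
#'
#' Utility of each living state at a given age, before any flooring. The
#' stable-state utility declines linearly with age; progressed-state
#' utilities are decrements from it. Under the default
#' `progressed_utility = "uniform"` both progressed substates carry the
#' metastatic decrement; under `"split"` the local substate carries
#' `du_progressed` and the metastatic substate `du_metastatic`.
#'
#' @param params A [parameter_set()].
#' @param state One of `"stable"`, `"progressed_local"`, `"metastatic"`.
#' @param age Attained age (years); defaults to the baseline age.
#' @return Utility value(s).
#' @examples
#' p <- default_parameters(progressed_utility = "split")
#' state_utility(p, "progressed_local")  # 0.75 - 0.126
#' state_utility(p, "metastatic")        # 0.75 - 0.352
#' @export
state_utility <- function(params, state, age = params$baseline_age) {
  state <- match.arg(state, c("stable", "progressed_local", "metastatic"))
  u <- params$u_stable + params$du_age_annual * (age - params$baseline_age)
  du <- switch(state,
    stable = 0,
    progressed_local = if (params$progressed_utility == "uniform")
      params$du_metastatic else params$du_progressed,
    metastatic = params$du_metastatic)
  u + du
}

.discount_factors <- function(params, n_cycles) {
  mid <- seq_len(n_cycles) - 0.5
  if (isTRUE(params$discount_per_cycle)) {
    (1 + params$discount_rate)^(-mid)
  } else {
    (1 + params$discount_rate)^(-(mid * params$cycle_length))
  }
}

#' Accrue life years, QALYs and costs over a state trace
#'
#' Per-cycle accrual at the half-cycle-corrected occupancy, discounted at
#' the midpoint of each cycle. Life years are reported undiscounted; QALYs
#' and costs discounted. Cost components follow the shipped accrual
#' schedule: a one-off surgical cost (surgery arm, cycle 0); endocrine
#' therapy per cycle in the stable state (tamoxifen for the first
#' `tamoxifen_years`, then letrozole for `letrozole_years`); follow-up per
#' year in the stable state during the endocrine-therapy period; and a
#' progression episode (half a year of the annual progressed/metastatic
#' state cost, mixed by the arm's metastatic share) charged on each exit
#' from the stable state. `progression_cost_mode = "per_year"` instead
#' accrues the full annual state costs for the whole time spent progressed.
#'
#' @param trace A [build_partition_trace()] result.
#' @param params The same [parameter_set()].
#' @param strategy Strategy label; defaults to the trace's own.
#' @return A one-row tibble: `strategy`, `cost`, `ly` (undiscounted),
#'   `qaly` (discounted), `ly_discounted`, and `cost_*` components.
#' @export
accrue_outcomes <- function(trace, params, strategy = NULL) {
  strategy <- strategy %||% attr(trace, "strategy")
  n_cycles <- nrow(trace) - 1
  cyc <- params$cycle_length
  stable <- trace$hcc_stable[-1]
  loc <- trace$hcc_progressed_local[-1]
  met <- trace$hcc_metastatic[-1]
  entrants <- trace$entrants[-1]
  tmid <- (seq_len(n_cycles) - 0.5) * cyc
  disc <- .discount_factors(params, n_cycles)

  alive <- stable + loc + met
  ly <- sum(alive) * cyc
  ly_disc <- sum(alive * disc) * cyc

  u_st <- params$u_stable + params$du_age_annual * tmid
  du_loc <- if (params$progressed_utility == "uniform")
    params$du_metastatic else params$du_progressed
  u_loc <- u_st + du_loc
  u_met <- u_st + params$du_metastatic
  floored <- any(c(u_st, u_loc, u_met) < 0)
  if (floored) warning("state utility below 0 was floored", call. = FALSE)
  u_st <- pmax(u_st, 0); u_loc <- pmax(u_loc, 0); u_met <- pmax(u_met, 0)
  qaly <- sum((stable * u_st + loc * u_loc + met * u_met) * disc) * cyc

  days_per_cycle <- 365.25 * cyc
  on_tam <- tmid <= params$tamoxifen_years
  on_let <- tmid > params$tamoxifen_years &
    tmid <= params$tamoxifen_years + params$letrozole_years
  cost_et <- sum(stable[on_tam] * disc[on_tam]) * params$cost_tamoxifen_daily *
    days_per_cycle +
    sum(stable[on_let] * disc[on_let]) * params$cost_letrozole_daily *
    days_per_cycle
  on_fu <- tmid <= params$followup_years
  cost_fu <- sum(stable[on_fu] * disc[on_fu]) * params$cost_followup * cyc

  p_met <- if (strategy == "surgery_et") params$p_met_surgery else params$p_met_pet
  if (params$progression_cost_mode == "entry_episode") {
    episode <- ((1 - p_met) * params$cost_progressed +
                  p_met * params$cost_metastatic) * cyc
    cost_prog <- sum(entrants * disc) * episode
  } else {
    cost_prog <- sum((loc * params$cost_progressed +
                        met * params$cost_metastatic) * disc) * cyc
  }
  cost_surg <- if (strategy == "surgery_et") surgery_cost(params) else 0

  tibble::tibble(
    strategy = strategy,
    cost = cost_surg + cost_et + cost_fu + cost_prog,
    ly = ly,
    qaly = qaly,
    ly_discounted = ly_disc,
    cost_surgery = cost_surg,
    cost_endocrine = cost_et,
    cost_followup = cost_fu,
    cost_progression = cost_prog
  )
}

#' Run the deterministic base case
#'
#' Traces both strategies, accrues outcomes and compares them.
#'
#' @param params A [parameter_set()].
#' @param thresholds Willingness-to-pay thresholds (GBP per QALY).
#' @return An object of class `petvoi_cea`: list with `strategies` (tibble,
#'   one row per arm), `comparison` (see [compare_strategies()]) and
#'   `params`.
#' @examples
#' res <- run_base_case(default_parameters())
#' glance(res)
#' @export
run_base_case <- function(params = default_parameters(),
                          thresholds = c(20000, 30000)) {
  strategies <- dplyr::bind_rows(lapply(c("surgery_et", "pet"), function(s) {
    accrue_outcomes(build_partition_trace(params, s), params, s)
  }))
  comparison <- compare_strategies(strategies[1, ], strategies[2, ],
                                   thresholds = thresholds)
  structure(list(strategies = strategies, comparison = comparison,
                 params = params, thresholds = thresholds),
            class = "petvoi_cea")
}

#' Compare two strategies
#'
#' Incremental cost, incremental QALYs, the ICER (with dominance handling
#' when the QALY difference is negligible), and net monetary benefit per
#' threshold.
#'
#' @param a Intervention [accrue_outcomes()] row.
#' @param b Comparator row. May be omitted if `a` has two rows
#'   (intervention first).
#' @param thresholds GBP-per-QALY thresholds for NMB/INMB.
#' @return A list of class `petvoi_comparison`: `incremental_cost`,
#'   `incremental_qaly`, `icer`, `label`, and `nmb` (tibble with one row per
#'   strategy and threshold, plus `inmb` on the intervention rows).
#' @export
compare_strategies <- function(a, b = NULL, thresholds = c(20000, 30000)) {
  if (is.null(b)) {
    stopifnot(nrow(a) == 2)
    b <- a[2, ]; a <- a[1, ]
  }
  stopifnot(all(thresholds > 0))
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  if (abs(d_qaly) < 1e-9) {
    icer <- NA_real_
    label <- if (abs(d_cost) < 1e-9) "equivalent"
             else if (d_cost < 0) "dominant" else "dominated"
  } else {
    icer <- d_cost / d_qaly
    label <- if (d_qaly > 0 && d_cost <= 0) "dominant"
             else if (d_qaly < 0 && d_cost >= 0) "dominated"
             else "trade-off"
  }
  nmb <- tidyr::expand_grid(
    threshold = thresholds,
    tibble::tibble(strategy = c(a$strategy, b$strategy),
                   cost = c(a$cost, b$cost), qaly = c(a$qaly, b$qaly)))
  nmb <- dplyr::mutate(nmb, nmb = .data$threshold * .data$qaly - .data$cost)
  inmb <- stats::setNames(thresholds * d_qaly - d_cost, thresholds)
  structure(list(incremental_cost = d_cost, incremental_qaly = d_qaly,
                 icer = icer, label = label, nmb = nmb, inmb = inmb,
                 intervention = a$strategy, comparator = b$strategy),
            class = "petvoi_comparison")
}

#' @export
print.petvoi_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost  GBP %.2f\n", x$incremental_cost))
  cat(sprintf("  incremental QALY  %.4f\n", x$incremental_qaly))
  if (is.na(x$icer)) {
    cat("  ICER: ", x$label, "\n")
  } else {
    cat(sprintf("  ICER  GBP %.2f per QALY (%s)\n", x$icer, x$label))
  }
  for (th in names(x$inmb)) {
    cat(sprintf("  INMB @ GBP %s: %.2f\n", th, x$inmb[[th]]))
  }
  invisible(x)
}

#' @export
print.petvoi_cea <- function(x, ...) {
  cat("<petvoi_cea> deterministic base case\n")
  print(as.data.frame(x$strategies[, c("strategy", "cost", "ly", "qaly")]),
        row.names = FALSE)
  print(x$comparison)
  invisible(x)
}

#' @rdname run_base_case
#' @param x A `petvoi_cea` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.petvoi_cea <- function(x, ...) x$strategies

#' @rdname run_base_case
#' @exportS3Method generics::glance
glance.petvoi_cea <- function(x, ...) {
  cmp <- x$comparison
  out <- tibble::tibble(
    incremental_cost = cmp$incremental_cost,
    incremental_qaly = cmp$incremental_qaly,
    icer = cmp$icer,
    label = cmp$label
  )
  for (th in names(cmp$inmb)) out[[paste0("inmb_", th)]] <- cmp$inmb[[th]]
  out
}
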