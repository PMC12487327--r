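#' Draw one probabilistic parameter set
#'
#' Samples every uncertain parameter from its specification (see
#' [default_distributions()]) and returns a coherent [parameter_set()].
#' Hazard ratios are drawn lognormally (normal on the log scale around the
#' log of the published mean); beta for proportions and the stable-state
#' utility; normal for utility decrements (truncated so that no state
#' utility can fall below the EQ-5D-3L floor of -0.594 or exceed 1); gamma
#' for state costs, rescaled so the sampled mean equals the deterministic
#' annual cost; and the survival-curve parameter pairs via the published
#' Cholesky factors, applied on the log-parameter scale for
#' positivity-constrained parameters.
#'
#' Draws use the current RNG state; seed management is the caller's
#' responsibility (see [run_psa()]).
#'
#' @param specs Distribution specifications ([default_distributions()]).
#' @param base Base [parameter_set()] supplying fixed values and the means
#'   of the survival-parameter draws.
#' @return A [parameter_set()].
#' @export
sample_parameter_set <- function(specs = default_distributions(),
                                 base = default_parameters()) {
  .check_specs(specs)
  p <- base
  for (i in seq_len(nrow(specs))) {
    nm <- specs$parameter[i]
    dist <- specs$dist[i]
    par1 <- specs$par1[i]; par2 <- specs$par2[i]
    if (dist == "fixed") next
    if (dist == "mvnorm_chol") {
      z <- stats::rnorm(2)
      shift <- c(par1 * z[1], par2 * z[1] + specs$par3[i] * z[2])
      if (nm == "os_pet") {
        p$os_pet$params[["shape"]] <- exp(log(p$os_pet$params[["shape"]]) + shift[1])
        p$os_pet$params[["rate"]]  <- exp(log(p$os_pet$params[["rate"]]) + shift[2])
      } else if (nm == "pfs_pet") {
        p$pfs_pet$params[["meanlog"]] <- p$pfs_pet$params[["meanlog"]] + shift[1]
        p$pfs_pet$params[["sdlog"]]   <- exp(log(p$pfs_pet$params[["sdlog"]]) + shift[2])
      } else {
        stop("mvnorm_chol spec for unknown target: ", nm, call. = FALSE)
      }
      next
    }
    value <- switch(dist,
      beta      = stats::rbeta(1, par1, par2),
      gamma     = stats::rgamma(1, shape = par1, scale = par2) * specs$rescale[i],
      normal    = stats::rnorm(1, par1, par2),
      lognormal = exp(stats::rnorm(1, log(par1), par2)),
      stop("unknown distribution: ", dist, call. = FALSE))
    p[[nm]] <- value
  }
  # EQ-5D-3L bounds: utilities live in [-0.594, 1]
  p$u_stable <- min(p$u_stable, 1)
  p$du_progressed <- max(p$du_progressed, -0.594 - p$u_stable)
  p$du_metastatic <- max(p$du_metastatic, -0.594 - p$u_stable)
  validate_parameter_set(p)
}

.check_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("parameter", "dist", "par1", "par2") %in% names(specs)))
  bad <- specs$dist %in% c("beta", "gamma") &
    (specs$par1 <= 0 | specs$par2 <= 0)
  bad <- bad | (specs$dist %in% c("normal", "lognormal") & specs$par2 < 0)
  if (any(bad)) {
    stop("spec error: invalid distribution parameters for ",
         paste(specs$parameter[bad], collapse = ", "), call. = FALSE)
  }
  invisible(specs)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws
#' one parameter set (shared by both strategies — common random numbers)
#' and runs the deterministic engine for each arm. Reproducible given
#' `seed`: iteration `i` uses its own substream seeded by `seed + i`, so
#' results do not depend on the number of iterations run before inspection.
#'
#' @param params Base [parameter_set()].
#' @param specs Distribution specifications.
#' @param n_iter Number of iterations (the analysis default is 10,000;
#'   2,000 gives stable acceptability estimates at desk scale).
#' @param seed Integer seed.
#' @return An object of class `petvoi_psa`: list with `draws` (tibble of
#'   `iteration`, `strategy`, `cost`, `qaly`, `ly`), `n_iter`, `seed`,
#'   `rejections`.
#' @examples
#' psa <- run_psa(n_iter = 20, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(params = default_parameters(),
                    specs = default_distributions(),
                    n_iter = 2000, seed = 1) {
  stopifnot(n_iter >= 1)
  .check_specs(specs)
  rejections <- 0L
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    for (attempt in 0:5) {
      set.seed((seed + i + attempt * 1000003L) %% 2147483647L)
      res <- tryCatch({
        draw <- sample_parameter_set(specs, params)
        dplyr::bind_rows(lapply(c("surgery_et", "pet"), function(s) {
          accrue_outcomes(build_partition_trace(draw, s), draw, s)
        }))
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(res)) break
      rejections <- rejections + 1L
    }
    if (is.null(res)) stop("iteration ", i, " failed repeatedly", call. = FALSE)
    rows[[i]] <- dplyr::mutate(
      res[, c("strategy", "cost", "qaly", "ly")], iteration = i,
      .before = 1)
  }
  draws <- dplyr::bind_rows(rows)
  if (any(!is.finite(draws$cost)) || any(!is.finite(draws$qaly))) {
    stop("non-finite PSA results", call. = FALSE)
  }
  structure(list(draws = draws, n_iter = n_iter, seed = seed,
                 rejections = rejections),
            class = "petvoi_psa")
}

#' @export
print.petvoi_psa <- function(x, ...) {
  cat("<petvoi_psa> ", x$n_iter, " iterations (seed ", x$seed, ", ",
      x$rejections, " redraws)\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @rdname run_psa
#' @param object,x A `petvoi_psa` object.
#' @param ... Unused.
#' @export
summary.petvoi_psa <- function(object, ...) {
  dplyr::summarise(dplyr::group_by(object$draws, .data$strategy),
                   mean_cost = mean(.data$cost), mean_qaly = mean(.data$qaly),
                   mean_ly = mean(.data$ly), .groups = "drop")
}

#' @rdname run_psa
#' @exportS3Method generics::tidy
tidy.petvoi_psa <- function(x, ...) x$draws

#' Cost-effectiveness acceptability curve
#'
#' For each threshold, the fraction of PSA iterations in which each strategy
#' has the highest net monetary benefit. Fractions sum to one per threshold.
#'
#' @param psa A [run_psa()] result.
#' @param thresholds Grid of thresholds (GBP per QALY).
#' @return A tibble of class `petvoi_ceac`: `threshold`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "petvoi_psa"))
  wide <- tidyr::pivot_wider(psa$draws, id_cols = "iteration",
                             names_from = "strategy",
                             values_from = c("cost", "qaly"))
  strategies <- unique(psa$draws$strategy)
  out <- purrr::map_dfr(thresholds, function(th) {
    nb <- vapply(strategies, function(s) {
      th * wide[[paste0("qaly_", s)]] - wide[[paste0("cost_", s)]]
    }, numeric(nrow(wide)))
    win <- strategies[max.col(nb, ties.method = "first")]
    tibble::tibble(threshold = th, strategy = strategies,
                   probability = vapply(strategies,
                                        function(s) mean(win == s), 0,
                                        USE.NAMES = FALSE))
  })
  class(out) <- c("petvoi_ceac", class(out))
  out
}

#' Per-person expected value of perfect information
#'
#' `EVPI = E_theta[max_j NB(j, theta)] - max_j E_theta[NB(j, theta)]` at a
#' given willingness-to-pay threshold; non-negative by construction.
#'
#' @param psa A [run_psa()] result (at least 2 iterations).
#' @param threshold GBP per QALY.
#' @return EVPI in GBP per person.
#' @export
evpi_per_person <- function(psa, threshold) {
  stopifnot(inherits(psa, "petvoi_psa"), psa$n_iter >= 2)
  wide <- tidyr::pivot_wider(psa$draws, id_cols = "iteration",
                             names_from = "strategy",
                             values_from = c("cost", "qaly"))
  strategies <- unique(psa$draws$strategy)
  nb <- vapply(strategies, function(s) {
    threshold * wide[[paste0("qaly_", s)]] - wide[[paste0("cost_", s)]]
  }, numeric(nrow(wide)))
  mean(apply(nb, 1, max)) - max(colMeans(nb))
}
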