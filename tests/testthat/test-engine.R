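test_that("degenerate curves put the whole cohort in stable and LY = horizon", {
  p <- default_parameters(horizon_years = 10)
  one <- function(t) rep(1, length(t))
  tr <- build_partition_trace(p, "pet", os = one, pfs = one)
  expect_true(all(tr$stable == 1))
  out <- accrue_outcomes(tr, p, "pet")
  expect_equal(out$ly, 10)
})

test_that("a boundary partitions into the arm's metastatic share", {
  # os = 0.7, pfs = 0.4, surgery metastatic share 0.42
  p <- default_parameters(horizon_years = 1)
  os <- function(t) ifelse(t == 0, 1, 0.7)
  pfs <- function(t) ifelse(t == 0, 1, 0.4)
  tr <- build_partition_trace(p, "surgery_et", os = os, pfs = pfs)
  last <- tr[nrow(tr), ]
  expect_equal(last$progressed_local, 0.3 * (1 - 0.42))
  expect_equal(last$metastatic, 0.3 * 0.42)
  expect_equal(last$dead, 0.3)
})

test_that("traces conserve mass, keep occupancies in [0,1], and death is monotone", {
  for (mode in c("psm", "markov")) {
    for (s in c("surgery_et", "pet")) {
      tr <- build_partition_trace(default_parameters(mode = mode), s)
      occ <- tr[, c("stable", "progressed_local", "metastatic", "dead")]
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(occ >= -1e-12 & occ <= 1 + 1e-12))
      expect_true(all(diff(tr$dead) >= -1e-12))
    }
  }
})

test_that("curves must start at 1", {
  p <- default_parameters(horizon_years = 1)
  expect_error(build_partition_trace(p, "pet", os = function(t) rep(0.9, length(t))),
               "curve error")
})

test_that("half-cycle-corrected discounted LY matches the continuous integral", {
  # exponential OS at rate 0.1, pfs = os, annual discounting at 3.5%
  p <- default_parameters(horizon_years = 30, discount_per_cycle = FALSE)
  expo <- survival_model("exponential", rate = 0.1)
  f <- function(t) survival_probability(expo, t)
  tr <- build_partition_trace(p, "pet", os = f, pfs = f)
  out <- accrue_outcomes(tr, p, "pet")
  oracle <- stats::integrate(function(t) exp(-0.1 * t) * 1.035^(-t),
                             0, 30, rel.tol = 1e-10)$value
  expect_lt(abs(out$ly_discounted - oracle) / oracle, 0.005)
})

test_that("state utilities reproduce the published decrements in split mode", {
  p <- default_parameters(progressed_utility = "split")
  expect_equal(state_utility(p, "stable"), 0.75)
  expect_equal(state_utility(p, "progressed_local"), 0.75 - 0.126)
  expect_equal(state_utility(p, "metastatic"), 0.75 - 0.352)
  # age decrement moves the stable utility linearly
  expect_equal(state_utility(p, "stable", age = 80), 0.75 - 0.0013 * 10)
  # default mode applies the metastatic decrement across the progressed state
  expect_equal(state_utility(default_parameters(), "progressed_local"),
               0.75 - 0.352)
})

test_that("with zero discounting and utility one, QALYs equal life years", {
  p <- default_parameters(discount_rate = 0, u_stable = 1, du_age_annual = 0,
                          du_metastatic = 0, du_progressed = 0)
  tr <- build_partition_trace(p, "pet")
  out <- accrue_outcomes(tr, p, "pet")
  expect_equal(out$qaly, out$ly, tolerance = 1e-12)
})

test_that("discounted quantities never exceed undiscounted ones", {
  for (s in c("surgery_et", "pet")) {
    p <- default_parameters()
    out <- accrue_outcomes(build_partition_trace(p, s), p, s)
    expect_lte(out$ly_discounted, out$ly)
    expect_lte(out$qaly, out$ly)  # utilities are at most 1
  }
})

test_that("halving the cycle length moves discounted QALYs by less than 1%", {
  base <- default_parameters(discount_per_cycle = FALSE)
  half <- default_parameters(discount_per_cycle = FALSE, cycle_length = 0.25)
  q <- function(p) accrue_outcomes(build_partition_trace(p, "pet"), p, "pet")$qaly
  expect_lt(abs(q(half) - q(base)) / q(base), 0.01)
})

test_that("ICER arithmetic and dominance handling", {
  a <- tibble::tibble(strategy = "surgery_et", cost = 10627.57,
                      qaly = 3.8695105 + 0.705766)
  b <- tibble::tibble(strategy = "pet", cost = 10627.57 - 4525.81,
                      qaly = 3.8695105)
  cmp <- compare_strategies(a, b)
  expect_equal(cmp$icer, 4525.81 / 0.705766, tolerance = 1e-9)
  expect_equal(round(cmp$icer, 2), 6412.62)
  # NMB at a threshold: lambda * Q - C
  one <- compare_strategies(tibble::tibble(strategy = "x", cost = 10000, qaly = 2),
                            tibble::tibble(strategy = "y", cost = 10000, qaly = 2),
                            thresholds = 20000)
  expect_equal(one$nmb$nmb[1], 20000 * 2 - 10000)
  expect_equal(one$label, "equivalent")
  # cheaper and more effective dominates
  dom <- compare_strategies(tibble::tibble(strategy = "x", cost = 1, qaly = 3),
                            tibble::tibble(strategy = "y", cost = 2, qaly = 2))
  expect_equal(dom$label, "dominant")
})

test_that("INMB sign agrees with ICER vs threshold whenever dQALY > 0", {
  set.seed(101)
  for (i in 1:25) {
    a <- tibble::tibble(strategy = "a", cost = runif(1, 0, 2e4),
                        qaly = runif(1, 2, 5))
    b <- tibble::tibble(strategy = "b", cost = runif(1, 0, 2e4),
                        qaly = a$qaly - runif(1, 0.01, 1))
    th <- runif(1, 1e3, 5e4)
    cmp <- compare_strategies(a, b, thresholds = th)
    expect_equal(sign(cmp$inmb[[1]]), sign(th - cmp$icer))
  }
})

test_that("deterministic base case reproduces the published outcome table", {
  res <- run_base_case()
  surg <- res$strategies[res$strategies$strategy == "surgery_et", ]
  pet <- res$strategies[res$strategies$strategy == "pet", ]
  expect_equal(surg$qaly, 4.57, tolerance = 0.10)
  expect_equal(pet$qaly, 3.87, tolerance = 0.10)
  expect_equal(surg$ly, 15.75, tolerance = 0.10)
  expect_equal(pet$ly, 13.94, tolerance = 0.10)
})

test_that("tornado: degenerate range gives zero swing, ranges sort by swing", {
  rng <- tibble::tibble(parameter = c("u_stable", "hr_os"),
                        low = c(0.75, 0.73), high = c(0.75, 1.00))
  tor <- one_way_sensitivity(ranges = rng)
  expect_equal(tor$swing[tor$parameter == "u_stable"], 0)
  expect_equal(tor$parameter[1], "hr_os")
  # inverted ranges are swapped with a warning
  expect_warning(
    one_way_sensitivity(ranges = tibble::tibble(parameter = "hr_os",
                                                low = 1.0, high = 0.73)),
    "swapped")
})

test_that("INMB stays positive over every published range; survival dominates", {
  tor <- one_way_sensitivity()
  expect_true(all(tor$inmb_low > 0))
  expect_true(all(tor$inmb_high > 0))
  # overall and progression-free survival effects are the key drivers
  du_rank <- match(c("du_metastatic", "du_progressed"), tor$parameter)
  hr_rank <- match(c("hr_os", "hr_pfs"), tor$parameter)
  expect_true(all(hr_rank < du_rank))
})
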