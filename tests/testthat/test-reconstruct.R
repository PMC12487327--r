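test_that("product-limit estimate matches a hand computation", {
  # events at 1 and 2; censored at 1.5 and 3
  ipd <- tibble::tibble(time = c(1, 1.5, 2, 3), event = c(1, 0, 1, 0))
  km <- kaplan_meier(ipd)
  expect_equal(km_survival_at(km, 1), 0.75)
  expect_equal(km_survival_at(km, 2), 0.75 * 0.5)
  expect_equal(km_survival_at(km, 0.5), 1)       # before the first event
  expect_equal(km_survival_at(km, 10), 0.375)    # carried forward
})

test_that("all-censored data give S identically 1", {
  km <- kaplan_meier(tibble::tibble(time = c(2, 4, 6), event = 0))
  expect_true(all(km$survival == 1))
  expect_error(kaplan_meier(tibble::tibble(time = numeric(), event = numeric())),
               "empty")
})

test_that("a flat curve reconstructs to censored-only records", {
  curve <- tibble::tibble(time = c(0, 2, 4, 6), survival = 1)
  risk <- tibble::tibble(interval_start = c(0, 3), n_at_risk = c(50, 50))
  rec <- reconstruct_ipd(curve, risk)
  expect_equal(nrow(rec), 50)
  expect_equal(sum(rec$event), 0)
})

test_that("single-interval drop to 0.5 yields ~half the cohort as events", {
  curve <- tibble::tibble(time = c(0, 1), survival = c(1, 0.5))
  risk <- tibble::tibble(interval_start = 0, n_at_risk = 100)
  rec <- reconstruct_ipd(curve, risk)
  expect_equal(nrow(rec), 100)
  expect_equal(sum(rec$event), 50)
})

test_that("invalid curves and tables are rejected", {
  expect_error(reconstruct_ipd(
    tibble::tibble(time = c(0, 1), survival = c(0.8, 0.9)),
    tibble::tibble(interval_start = 0, n_at_risk = 10)), "monotonicity")
  expect_error(reconstruct_ipd(
    tibble::tibble(time = c(1, 2), survival = c(1, 0.9)),
    tibble::tibble(interval_start = 1.5, n_at_risk = 10)), "coverage")
  expect_error(reconstruct_ipd(
    tibble::tibble(time = c(0, 2), survival = c(1, 0.9)),
    tibble::tibble(interval_start = c(0, 1), n_at_risk = c(10, 12))),
    "non-increasing")
})

test_that("digitize -> reconstruct round trip stays within 0.02 survival", {
  ipd <- simulate_ipd("lognormal", c(meanlog = 1.40, sdlog = 0.98), n = 500,
                      admin_censor_time = 20, seed = 42)
  fx <- digitize_fixture(ipd, grid = seq(0, 20, by = 0.5),
                         intervals = seq(0, 16, by = 4))
  rec <- reconstruct_ipd(fx$curve, fx$risk)
  expect_equal(nrow(rec), fx$risk$n_at_risk[1])
  km <- kaplan_meier(rec)
  dev <- abs(km_survival_at(km, fx$curve$time) - fx$curve$survival)
  expect_lt(max(dev), 0.02)
})

test_that("round trip holds across families and seeds", {
  cases <- list(
    list(family = "exponential", params = c(rate = 0.12)),
    list(family = "weibull", params = c(shape = 1.4, scale = 9)),
    list(family = "gompertz", params = c(shape = 0.08, rate = 0.05)),
    list(family = "loglogistic", params = c(shape = 1.72, rate = 0.2)))
  for (case in cases) {
    for (seed in c(1, 2)) {
      ipd <- simulate_ipd(case$family, case$params, n = 400,
                          admin_censor_time = 20, censor_rate = 0.02,
                          seed = seed)
      fx <- digitize_fixture(ipd, grid = seq(0, 18, by = 1),
                             intervals = seq(0, 15, by = 5))
      rec <- reconstruct_ipd(fx$curve, fx$risk)
      expect_equal(nrow(rec), fx$risk$n_at_risk[1])
      km <- kaplan_meier(rec)
      dev <- abs(km_survival_at(km, fx$curve$time) - fx$curve$survival)
      expect_lt(max(dev), 0.02)
    }
  }
})

test_that("a published total event count is honoured", {
  ipd <- simulate_ipd("exponential", c(rate = 0.15), n = 300,
                      admin_censor_time = 15, seed = 9)
  fx <- digitize_fixture(ipd, grid = seq(0, 15, by = 1),
                         intervals = c(0, 5, 10))
  rec0 <- reconstruct_ipd(fx$curve, fx$risk)
  target <- sum(rec0$event) - 10
  rec <- reconstruct_ipd(fx$curve, fx$risk, total_events = target)
  expect_equal(sum(rec$event), target, tolerance = 2)  # integer rounding
  expect_equal(nrow(rec), fx$risk$n_at_risk[1])
})

test_that("curve and risk CSVs round-trip through the readers", {
  curve <- tibble::tibble(time = c(0, 1, 2), survival = c(1, 0.8, 0.6))
  risk <- tibble::tibble(interval_start = c(0, 1), n_at_risk = c(100L, 70L))
  cpath <- withr::local_tempfile(fileext = ".csv")
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(curve, cpath); write_fixture_csv(risk, rpath)
  expect_equal(as.data.frame(read_curve_csv(cpath)), as.data.frame(curve))
  expect_equal(as.data.frame(read_risk_csv(rpath)),
               as.data.frame(dplyr::mutate(risk, n_at_risk = as.numeric(n_at_risk))))
})
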