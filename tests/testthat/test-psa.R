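test_that("sampled marginals match their analytic moments (3 MC SEs at 20k draws)", {
  specs <- default_distributions()
  base <- default_parameters()
  n <- 20000
  set.seed(123)
  draws <- vapply(seq_len(n), function(i) {
    p <- sample_parameter_set(specs, base)
    c(u_stable = p$u_stable, hr_os = p$hr_os,
      cost_progressed = p$cost_progressed,
      du_metastatic = p$du_metastatic,
      os_log_shape = log(p$os_pet$params[["shape"]]),
      os_log_rate = log(p$os_pet$params[["rate"]]))
  }, numeric(6))
  draws <- t(draws)
  check_mean <- function(x, mean, sd) {
    expect_lt(abs(mean(x) - mean), 3 * sd / sqrt(n))
  }
  # beta(7.13, 2.38): mean 0.7497
  a <- 7.13; b <- 2.38
  check_mean(draws[, "u_stable"], a / (a + b),
             sqrt(a * b / ((a + b)^2 * (a + b + 1))))
  expect_equal(mean(draws[, "u_stable"]), 0.7497, tolerance = 0.005 / 0.7497)
  # lognormal hazard ratio: median equals the published mean
  expect_gte(stats::median(draws[, "hr_os"]), 0.84)
  expect_lte(stats::median(draws[, "hr_os"]), 0.88)
  mu <- log(0.86); s <- 0.07
  check_mean(draws[, "hr_os"], exp(mu + s^2 / 2),
             sqrt((exp(s^2) - 1) * exp(2 * mu + s^2)))
  # rescaled gamma: mean is the deterministic annual cost
  shp <- 33.88; scl <- 487.09
  check_mean(draws[, "cost_progressed"], 0.5 * shp * scl,
             0.5 * sqrt(shp) * scl)
  expect_equal(mean(draws[, "cost_progressed"]), 8251.75,
               tolerance = 3 * 0.5 * sqrt(shp) * scl / sqrt(n) / 8251.75)
  # normal decrement (truncation never binds this far from the floor)
  check_mean(draws[, "du_metastatic"], -0.352, 0.072)
  # correlated survival draws reproduce the Cholesky covariance L L^T
  L <- matrix(c(0.0628, -0.0028, 0, 0.07385), 2, 2)
  target <- L %*% t(L)
  emp <- stats::cov(draws[, c("os_log_shape", "os_log_rate")])
  expect_equal(emp[1, 1], target[1, 1], tolerance = 0.1)
  expect_equal(emp[2, 2], target[2, 2], tolerance = 0.1)
  expect_equal(emp[1, 2], target[1, 2], tolerance = 3 *
                 sqrt((target[1, 1] * target[2, 2] + target[1, 2]^2) / n) /
                 abs(target[1, 2]))
})

test_that("fixed parameters pass through unchanged", {
  specs <- tibble::tibble(parameter = "u_stable", dist = "fixed",
                          par1 = NA_real_, par2 = NA_real_, par3 = NA_real_,
                          rescale = 1)
  base <- default_parameters()
  set.seed(1)
  p1 <- sample_parameter_set(specs, base)
  p2 <- sample_parameter_set(specs, base)
  expect_identical(p1, base)
  expect_identical(p2, base)
})

test_that("invalid distribution parameters fail at load, not at draw time", {
  bad <- tibble::tibble(parameter = "u_stable", dist = "beta",
                        par1 = -7, par2 = 2.38, par3 = NA_real_, rescale = 1)
  expect_error(sample_parameter_set(bad), "spec error")
  expect_error(run_psa(specs = bad, n_iter = 5, seed = 1), "spec error")
})

test_that("a one-iteration PSA with fixed specs equals the base case", {
  specs <- dplyr::mutate(default_distributions(), dist = "fixed")
  psa <- run_psa(specs = specs, n_iter = 1, seed = 7)
  det <- run_base_case()
  expect_equal(psa$draws$cost, det$strategies$cost, tolerance = 1e-12)
  expect_equal(psa$draws$qaly, det$strategies$qaly, tolerance = 1e-12)
})

test_that("the PSA is bitwise reproducible for a given seed", {
  a <- run_psa(n_iter = 25, seed = 11)
  b <- run_psa(n_iter = 25, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(summary(a), summary(b))
  c <- run_psa(n_iter = 25, seed = 12)
  expect_false(identical(a$draws, c$draws))
})

test_that("CEAC probabilities sum to one and favour the cheaper arm at lambda 0", {
  psa <- run_psa(n_iter = 100, seed = 3)
  cc <- ceac(psa, thresholds = c(0, 10000, 20000, 30000))
  sums <- tapply(cc$probability, cc$threshold, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  at0 <- cc[cc$threshold == 0, ]
  expect_equal(at0$probability[at0$strategy == "pet"], 1)  # PET is cheaper
})

test_that("EVPI: hand-computed toy value, and non-negativity", {
  # two iterations, NBs {(10, 0), (0, 10)} -> E[max] - max E = 10 - 5
  psa <- toy_psa(nb_a = c(10, 0), nb_b = c(0, 10))
  expect_equal(evpi_per_person(psa, threshold = 1), 5)
  # one strategy dominating everywhere gives zero
  dom <- toy_psa(nb_a = c(10, 12), nb_b = c(5, 7))
  expect_equal(evpi_per_person(dom, threshold = 1), 0)
  # real runs stay non-negative at any threshold
  psa <- run_psa(n_iter = 60, seed = 5)
  for (th in c(0, 13000, 20000, 30000)) {
    expect_gte(evpi_per_person(psa, th), 0)
  }
})
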