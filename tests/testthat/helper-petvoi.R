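# shared fixtures built in code

# a minimal petvoi_fit for ranking tests (no data behind it)
fake_fit <- function(family = "weibull", aic = 100, bic = 105, n = 500,
                     loglik = -(aic - 2 * 2) / 2) {
  structure(list(model = survival_model("weibull", shape = 1, scale = 1),
                 family = family, loglik = loglik, aic = aic, bic = bic,
                 n = n, n_events = n, k = 2, vcov = diag(2),
                 ci = matrix(1, 2, 3, dimnames = list(
                   c("shape", "scale"), c("est", "L95%", "U95%")))),
            class = "petvoi_fit")
}

# a hand-built PSA object with known per-iteration net benefits at lambda = 1
# (qaly holds the NB, cost = 0)
toy_psa <- function(nb_a, nb_b) {
  draws <- tibble::tibble(
    iteration = rep(seq_along(nb_a), each = 2),
    strategy = rep(c("a", "b"), length(nb_a)),
    cost = 0,
    qaly = as.vector(rbind(nb_a, nb_b)),
    ly = 1)
  structure(list(draws = draws, n_iter = length(nb_a), seed = 0,
                 rejections = 0L), class = "petvoi_psa")
}

# published base-case net monetary benefits (GBP), used as inputs to the
# implementation-value identities
NB_20K <- c(surgery_et = 80877.96, pet = 71288.45)
NB_30K <- c(surgery_et = 126630.72, pet = 109983.55)
UPTAKE <- c(surgery_et = 0.76, pet = 0.24)
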