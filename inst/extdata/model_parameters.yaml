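# Model input parameters: point values and probabilistic distributions
# for the surgery + endocrine therapy vs primary endocrine therapy model.
# Monetary values in 2020/21 GBP; times in years.
hazard_ratios:
  hr_os:  {value: 0.86, dist: lognormal, mean: 0.86, sd: 0.07, low: 0.73, high: 1.00}
  hr_pfs: {value: 0.65, dist: lognormal, mean: 0.65, sd: 0.07, low: 0.53, high: 0.81}
pet_survival:
  os:
    family: loglogistic
    # as-published Stata-style parameters (shape = ancillary gamma)
    shape: 1.72
    location: 0.41
    shape_low: 1.60
    shape_high: 1.85
    scale_low: 0.36
    scale_high: 0.48
    cholesky: [0.0628, -0.0028, 0.07385]
  os_calibrated:
    family: loglogistic
    shape: 0.60          # exponent of S(t) = 1 / (1 + (rate * t)^shape)
    rate: 0.16667               # median overall survival ~6.0 years
  pfs:
    family: lognormal
    location: 1.40       # meanlog
    scale: 0.98          # sdlog
    location_low: 1.21
    location_high: 1.61
    scale_low: 0.74
    scale_high: 1.22
    cholesky: [0.1251, 0.0079, 0.07135]
transition_probabilities:
  tp_prog_death: {value: 0.04, dist: beta, alpha: 0.53, beta: 12.79, low: 0.03, high: 0.05}
  tp_met_death:  {value: 0.11, dist: beta, alpha: 2.38, beta: 19.07, low: 0.10, high: 0.12}
  p_met_surgery: {value: 0.42, dist: beta, alpha: 27, beta: 39}
  p_met_pet:     {value: 0.35, dist: beta, alpha: 27, beta: 42}
utilities:
  u_stable:      {value: 0.75,    dist: beta,   alpha: 7.13, beta: 2.38, low: 0.72, high: 0.79}
  du_progressed: {value: -0.126,  dist: normal, mean: -0.126,  se: 0.089, low: -0.301, high: 0.049}
  du_metastatic: {value: -0.352,  dist: normal, mean: -0.352,  se: 0.072, low: -0.493, high: -0.211}
  du_age_annual: {value: -0.0013, dist: normal, mean: -0.0013, se: 0.002, low: -0.004, high: 0.002}
costs:
  cost_surgery_aggregate: {value: 6619.53}    # published aggregate incl. delayed reconstruction
  cost_mastectomy:        {value: 6547.64}    # HRG JA38C
  cost_bcs:               {value: 2867.69}    # HRG JA20F
  p_mastectomy:           {value: 0.35, dist: beta, alpha: 16340, beta: 30345, low: 0.28, high: 0.43}
  cost_hospital_stay:     {value: 937.00}     # HRG WH20C
  cost_tamoxifen_daily:   {value: 0.30}
  cost_letrozole_daily:   {value: 3.25}
  cost_followup:          {value: 509.22}     # HRG WH52B, per year
  cost_progressed:        {value: 8251.75, dist: gamma, shape: 33.88, scale: 487.09, low: 5691.10, high: 11248.21}
  cost_metastatic:        {value: 6223.54, dist: gamma, shape: 84.83, scale: 146.73, low: 4990.12, high: 7638.91}
settings:
  discount_rate: 0.035
  cycle_length: 0.5
  horizon_years: 35
  baseline_age: 70
implementation:
  uptake_surgery_et: 0.76
  uptake_pet: 0.24
  annual_incidence: 9356
  population_horizon_years: 10
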