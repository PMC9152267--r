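# Shared fixtures: default inputs and an independent closed-form oracle for
# the discounted life-years of the two-state cohort model.

base_params <- default_parameters()
base_settings <- default_settings()
base_draw <- base_case_draw(base_params)

# Geometric-series closed form for the half-cycle-corrected discounted
# life-years (in years): with q = (1 - p) * v and v the monthly discount
# factor, LY = (1/2 + q (1 - q^(T-1)) / (1 - q) + q^T / 2) / 12.
closed_form_ly <- function(monthly_p, annual_discount, horizon) {
  v <- (1 + annual_discount)^(-1 / 12)
  q <- (1 - monthly_p) * v
  if (q == 1) return((0.5 + (horizon - 1) + 0.5) / 12)
  (0.5 + q * (1 - q^(horizon - 1)) / (1 - q) + 0.5 * q^horizon) / 12
}

# A random valid parameter draw for property tests: probabilities and
# utilities uniform in (0, 1), costs/durations positive.
random_draw <- function(params = base_params) {
  vals <- purrr::map2_dbl(params$role, params$value, function(role, v) {
    switch(role,
      probability = stats::runif(1, 0.01, 0.99),
      utility = stats::runif(1, 0.1, 1),
      rate = stats::runif(1, 0, 0.08),
      cost = stats::runif(1, 0.1, 2) * max(v, 1),
      duration = stats::runif(1, 1, 40)
    )
  })
  stats::setNames(vals, params$name)
}
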