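test_that("default parameter table matches the published inputs", {
  p <- base_params
  expect_setequal(
    p$name,
    c("p_ifi_posaconazole", "p_ifi_first_gen", "p_death_ifi", "p_death_other",
      "surv5_aml", "surv5_mds", "cost_ifi_treatment",
      "daily_cost_posa_susp", "daily_cost_posa_tab",
      "daily_cost_fluconazole", "daily_cost_itraconazole",
      "duration_posa", "duration_fluconazole", "duration_itraconazole",
      "discount_rate", "utility_induction", "utility_remission")
  )
  val <- base_case_draw(p)
  # count-derived probabilities are stored unrounded but round to the
  # published three-decimal values
  expect_equal(round(val[["p_ifi_posaconazole"]], 3), 0.046)
  expect_equal(round(val[["p_ifi_first_gen"]], 3), 0.111)
  expect_equal(round(val[["p_death_ifi"]], 3), 0.447)
  expect_equal(val[["p_ifi_posaconazole"]], 14 / 304)
  u <- p[p$name == "utility_remission", ]
  expect_equal(c(u$low, u$high), c(0.623, 1.000))
  probs <- p[p$role %in% c("probability", "utility"), ]
  expect_true(all(probs$value >= 0 & probs$value <= 1))
  expect_true(all(p$low <= p$value & p$value <= p$high))
  # rounded variant swaps in the three-decimal values
  pr <- default_parameters(use_trial_fractions = FALSE)
  expect_equal(pr$value[pr$name == "p_ifi_posaconazole"], 0.046)
})

test_that("configuration round-trips and overrides apply on top of defaults", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(path)
  cfg <- load_config(path)
  expect_equal(cfg$parameters, base_params)
  expect_equal(cfg$settings, base_settings)

  # empty document reproduces the defaults
  empty <- withr::local_tempfile(fileext = ".yml")
  writeLines("", empty)
  cfg0 <- load_config(empty)
  expect_equal(cfg0$parameters, base_params)

  # single-field override leaves everything else untouched
  over <- withr::local_tempfile(fileext = ".yml")
  writeLines("parameters:\n  daily_cost_posa_susp: {base: 30.0, low: 22.5, high: 37.5}", over)
  cfgo <- load_config(over)
  expect_equal(cfgo$parameters$value[cfgo$parameters$name == "daily_cost_posa_susp"], 30)
  other <- cfgo$parameters$name != "daily_cost_posa_susp"
  expect_equal(cfgo$parameters[other, ], base_params[other, ])
})

test_that("invalid configuration is rejected with a named failure", {
  bad_range <- withr::local_tempfile(fileext = ".yml")
  writeLines("parameters:\n  daily_cost_fluconazole: {low: 0.9, high: 0.1, base: 0.5}", bad_range)
  expect_error(load_config(bad_range), "low <= base <= high.*daily_cost_fluconazole")

  bad_family <- withr::local_tempfile(fileext = ".yml")
  writeLines("parameters:\n  daily_cost_fluconazole: {family: lognormal}", bad_family)
  expect_error(load_config(bad_family), "unknown distribution family")

  bad_param <- withr::local_tempfile(fileext = ".yml")
  writeLines("parameters:\n  not_a_parameter: {base: 1}", bad_param)
  expect_error(load_config(bad_param), "unknown parameter")

  bad_setting <- withr::local_tempfile(fileext = ".yml")
  writeLines("settings:\n  cycle_years: 2", bad_setting)
  expect_error(load_config(bad_setting), "unknown setting")

  expect_error(load_config(file.path(tempdir(), "absent.yml")), "not found")
  expect_error(
    validate_parameters(base_params[base_params$name != "discount_rate", ]),
    "missing required parameter.*discount_rate"
  )
})

test_that("sensitivity bounds use stated ranges, else base +/- 25% with utility cap", {
  b <- dsa_bounds(base_params)
  rem <- b[b$name == "utility_remission", ]
  expect_equal(c(rem$dsa_low, rem$dsa_high), c(0.623, 1.000))
  susp <- b[b$name == "daily_cost_posa_susp", ]
  expect_equal(c(susp$dsa_low, susp$dsa_high), c(34.17, 56.95))

  # no stated range: +/- 25%, utilities truncated at 1, zero base stays zero
  p <- base_params
  p$low[p$name == "daily_cost_fluconazole"] <- NA
  p$high[p$name == "daily_cost_fluconazole"] <- NA
  p$value[p$name == "daily_cost_fluconazole"] <- 0
  p$low[p$name == "utility_remission"] <- NA
  p$high[p$name == "utility_remission"] <- NA
  b2 <- dsa_bounds(p)
  z <- b2[b2$name == "daily_cost_fluconazole", ]
  expect_equal(c(z$dsa_low, z$dsa_high), c(0, 0))
  r2 <- b2[b2$name == "utility_remission", ]
  expect_equal(c(r2$dsa_low, r2$dsa_high), c(0.830 * 0.75, 1))

  # fixed parameters are not varied
  p$family[p$name == "duration_posa"] <- "fixed"
  b3 <- dsa_bounds(p)
  expect_equal(b3$dsa_low[b3$name == "duration_posa"], 29)
  expect_equal(b3$dsa_high[b3$name == "duration_posa"], 29)
})

test_that("beta and gamma distributions are moment-matched to base and range/3.92", {
  for (nm in base_params$name[base_params$family %in% c("beta", "gamma")]) {
    row <- base_params[base_params$name == nm, ]
    d <- fit_sampling_distribution(base_params, nm)
    target_sd <- (row$high - row$low) / 3.92
    # analytic moments of the fitted distribution, computed independently
    if (d$family == "beta") {
      m <- d$shape1 / (d$shape1 + d$shape2)
      v <- d$shape1 * d$shape2 /
        ((d$shape1 + d$shape2)^2 * (d$shape1 + d$shape2 + 1))
    } else {
      m <- d$shape * d$scale
      v <- d$shape * d$scale^2
    }
    expect_equal(m, row$value, tolerance = 1e-9)
    expect_equal(sqrt(v), target_sd, tolerance = 1e-9)
  }

  # method-of-moments formulas, checked against direct computation at the
  # published rounded base value
  p <- default_parameters(use_trial_fractions = FALSE)
  d <- fit_sampling_distribution(p, "p_ifi_posaconazole")
  m <- 0.046
  v <- ((0.058 - 0.034) / 3.92)^2
  k <- m * (1 - m) / v - 1
  expect_equal(d$shape1, m * k)
  expect_equal(d$shape2, (1 - m) * k)

  dg <- fit_sampling_distribution(p, "duration_posa")
  vg <- ((36.25 - 21.75) / 3.92)^2
  expect_equal(dg$shape, 29^2 / vg)
  expect_equal(dg$scale, vg / 29)

  # beta moment matching requires base strictly inside (0, 1)
  p2 <- base_params
  p2$value[p2$name == "p_death_other"] <- 0
  p2$low[p2$name == "p_death_other"] <- 0
  expect_error(fit_sampling_distribution(p2, "p_death_other"), "\\(0, 1\\)")

  # degenerate family: every draw equals the base
  p3 <- base_params
  p3$family[p3$name == "duration_posa"] <- "fixed"
  d3 <- fit_sampling_distribution(p3, "duration_posa")
  expect_equal(sample_dist(d3, 5), rep(29, 5))
})

test_that("parameter sampling is seed-deterministic, clipped, and centred", {
  a <- sample_parameter_set(base_params, n = 20, seed = 11)
  b <- sample_parameter_set(base_params, n = 20, seed = 11)
  expect_identical(a, b)
  c <- sample_parameter_set(base_params, n = 20, seed = 12)
  expect_false(identical(a, c))

  big <- sample_parameter_set(base_params, n = 10000, seed = 5)
  for (nm in base_params$name[base_params$role %in% c("probability", "utility")]) {
    expect_true(all(big[[nm]] >= 0 & big[[nm]] <= 1))
  }
  # Monte-Carlo mean converges to the moment-matched mean
  d <- fit_sampling_distribution(base_params, "p_ifi_posaconazole")
  se <- d$sd / sqrt(nrow(big))
  expect_lt(abs(mean(big$p_ifi_posaconazole) - d$mean), 3 * se)
})
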