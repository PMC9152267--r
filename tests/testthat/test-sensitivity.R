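test_that("tornado is sorted, contains the base ICER, and zeroes fixed bars", {
  dsa <- one_way_dsa(base_params, base_settings)
  expect_equal(nrow(dsa), nrow(base_params))
  expect_true(all(dsa$width >= 0))
  expect_equal(dsa$width, sort(dsa$width, decreasing = TRUE))

  base_icer <- glance(run_base_case())$icer_per_qaly_suspension
  # for cost and probability parameters the ICER is monotone over the bar,
  # so the base-case ICER lies inside it
  mono <- base_params$name[base_params$role %in% c("cost", "probability")]
  for (nm in setdiff(mono, c("daily_cost_posa_tab"))) {
    row <- dsa[dsa$parameter == nm, ]
    if (row$width == 0) next
    expect_gte(base_icer, min(row$icer_low, row$icer_high) - 1e-9)
    expect_lte(base_icer, max(row$icer_low, row$icer_high) + 1e-9)
  }

  # a parameter declared fixed is not varied: zero-width bar
  p <- base_params
  p$family[p$name == "duration_posa"] <- "fixed"
  dsa_f <- one_way_dsa(p, base_settings)
  expect_equal(dsa_f$width[dsa_f$parameter == "duration_posa"], 0)

  # the tablet daily cost is irrelevant to the suspension comparison
  expect_equal(dsa$width[dsa$parameter == "daily_cost_posa_tab"], 0)
})

test_that("PSA is reproducible and honours the configured iteration count", {
  a <- run_psa(base_params, base_settings, n = 60, seed = 7)
  b <- run_psa(base_params, base_settings, n = 60, seed = 7)
  expect_identical(a$iterations, b$iterations)
  expect_equal(nrow(a$iterations), 60)
  expect_equal(a$seed, 7L)
  c <- run_psa(base_params, base_settings, n = 60, seed = 8)
  expect_false(identical(a$iterations, c$iterations))

  # default n comes from settings (published analysis: 1,000 iterations)
  expect_equal(default_settings()$psa_iterations, 1000L)
  s <- base_settings
  s$psa_iterations <- 25L
  expect_equal(run_psa(base_params, s)$n, 25L)

  gl <- glance(a)
  expect_equal(gl$n, 60L)
  expect_true(gl$prob_cost_effective >= 0 && gl$prob_cost_effective <= 1)
  expect_equal(nrow(tidy(a)), 60)
})

test_that("probability of cost-effectiveness has the right limits", {
  psa <- run_psa(base_params, base_settings, n = 200, seed = 3)
  it <- psa$iterations
  # zero WTP: count of strictly cost-saving iterations
  expect_equal(probability_cost_effective(psa, 0), mean(it$delta_cost < 0))
  # enormous WTP: fraction of iterations with any QALY gain
  expect_equal(probability_cost_effective(psa, 1e12), mean(it$delta_qaly > 0))
})

test_that("the acceptability curve is a bounded curve over the WTP grid", {
  psa <- run_psa(base_params, base_settings, n = 200, seed = 3)
  cc <- ceac(psa)
  expect_equal(nrow(cc), length(seq(0, 60000, by = 250)))
  expect_true(all(cc$probability_cost_effective >= 0 &
                  cc$probability_cost_effective <= 1))
  expect_equal(cc$probability_cost_effective[1],
               probability_cost_effective(psa, 0))
  # empty grid gives an empty curve
  empty <- ceac(psa, numeric(0))
  expect_equal(nrow(empty), 0)
  # crossing: smallest grid WTP with probability above one half
  cross <- ceac_crossing(cc)
  expect_true(is.na(cross) || cross %in% cc$wtp)

  flat <- tibble::tibble(wtp = c(0, 100), probability_cost_effective = c(0.1, 0.2))
  expect_true(is.na(ceac_crossing(flat)))
})

test_that("plots build without evaluation errors", {
  psa <- run_psa(base_params, base_settings, n = 50, seed = 9)
  expect_s3_class(plot_psa_scatter(psa), "ggplot")
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(plot_ceac(ceac(psa, seq(0, 50000, 1000)), wtp = 31315), "ggplot")
  dsa <- one_way_dsa(base_params, base_settings)
  expect_s3_class(plot_tornado(dsa, base_icer = 12000, wtp = 31315), "ggplot")
})
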