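test_that("per-strategy totals reproduce the published base-case costs", {
  susp <- evaluate_strategy(posaconazole_suspension(), base_draw, base_settings)
  fgt <- evaluate_strategy(first_generation_triazoles(), base_draw, base_settings)
  expect_equal(susp$total_cost, 1571.0, tolerance = 0.005)
  expect_equal(fgt$total_cost, 616.3, tolerance = 0.005)
  cmp <- compare_strategies(fgt, susp)
  expect_equal(cmp$delta_cost, 954.7, tolerance = 0.005)

  # accounting identity, and strict ordering of the two regimens
  expect_equal(susp$total_cost, susp$drug_cost + susp$ifi_cost)
  expect_gt(susp$qaly, fgt$qaly)
  expect_gt(susp$total_cost, fgt$total_cost)
  expect_gte(susp$ly, susp$qaly)
})

test_that("cost accounting and LY >= QALY hold for arbitrary draws", {
  withr::local_seed(7)
  for (i in 1:50) {
    draw <- random_draw()
    res <- evaluate_strategy(posaconazole_suspension(), draw, base_settings)
    expect_equal(res$total_cost, res$drug_cost + res$ifi_cost)
    expect_gte(res$ly, res$qaly)
    expect_gte(res$qaly, 0)
  }
  # unit utilities collapse QALYs onto LYs
  d1 <- base_draw
  d1[c("utility_induction", "utility_remission")] <- 1
  res1 <- evaluate_strategy(posaconazole_suspension(), d1, base_settings)
  expect_equal(res1$qaly, res1$ly)
})

test_that("comparisons classify dominance, quadrants, and undefined ICERs", {
  mk <- function(cost, qaly, ly = qaly, name = "s") {
    tibble::tibble(strategy = name, drug_cost = cost, ifi_cost = 0,
                   total_cost = cost, ly = ly, qaly = qaly)
  }
  # cheaper and more effective: alternative dominates, no ICER
  cmp <- compare_strategies(mk(1000, 2), mk(800, 3))
  expect_equal(cmp$dominance, "alt_dominant")
  expect_true(is.na(cmp$icer_per_qaly))
  # dearer and less effective: reference dominates
  cmp2 <- compare_strategies(mk(800, 3), mk(1000, 2))
  expect_equal(cmp2$dominance, "ref_dominant")
  expect_true(is.na(cmp2$icer_per_qaly))
  # self-comparison: zero deltas, no dominance
  cmp3 <- compare_strategies(mk(1000, 2), mk(1000, 2))
  expect_equal(cmp3$delta_cost, 0)
  expect_equal(cmp3$delta_qaly, 0)
  expect_equal(cmp3$dominance, "none")
  expect_true(is.na(cmp3$icer_per_qaly))
  # south-west quadrant: ratio computed but flagged
  cmp4 <- compare_strategies(mk(1000, 3), mk(800, 2))
  expect_equal(cmp4$quadrant, "SW")
  expect_equal(cmp4$icer_per_qaly, (800 - 1000) / (2 - 3))
  # zero effect increment with a cost difference: ICER absent
  cmp5 <- compare_strategies(mk(800, 2), mk(1000, 2))
  expect_true(is.na(cmp5$icer_per_qaly))
  expect_equal(cmp5$dominance, "none")
})

test_that("net monetary benefit is consistent with the ICER threshold rule", {
  res <- tibble::tibble(strategy = "x", drug_cost = 1571, ifi_cost = 0,
                        total_cost = 1571.0, ly = 4, qaly = 3.683)
  expect_equal(net_monetary_benefit(res, 31315), 31315 * 3.683 - 1571.0,
               tolerance = 0.1 / 113762)
  expect_equal(net_monetary_benefit(res, 0), -1571.0)
  expect_error(net_monetary_benefit(res, -5), ">= 0")

  # delta NMB > 0 <=> ICER < WTP whenever delta_qaly > 0
  withr::local_seed(21)
  for (i in 1:30) {
    draw <- random_draw()
    fgt <- evaluate_strategy(first_generation_triazoles(), draw, base_settings)
    susp <- evaluate_strategy(posaconazole_suspension(), draw, base_settings)
    cmp <- compare_strategies(fgt, susp)
    if (is.na(cmp$icer_per_qaly) || cmp$delta_qaly <= 0) next
    for (wtp in c(5000, 31315, 60000)) {
      dnmb <- net_monetary_benefit(susp, wtp) - net_monetary_benefit(fgt, wtp)
      expect_equal(dnmb > 0, cmp$icer_per_qaly < wtp)
    }
  }
})

test_that("base-case object prints, tidies, and summarises", {
  bc <- run_base_case()
  expect_s3_class(bc, "cea_basecase")
  expect_output(print(bc), "Incremental results")
  td <- tidy(bc)
  expect_equal(nrow(td), 3)
  gl <- glance(bc)
  expect_equal(nrow(gl), 1)
  expect_true(gl$suspension_cost_effective)
  expect_equal(
    gl$icer_per_qaly_suspension,
    bc$comparisons$icer_per_qaly[bc$comparisons$alternative == "posaconazole_suspension"]
  )
})
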