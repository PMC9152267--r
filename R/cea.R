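#' Evaluate a strategy end to end
#'
#' Runs the 100-day decision tree and, for the surviving fraction, the
#' lifetime Markov phase, and combines them into per-patient expected
#' totals: `ly = initial_ly + survivor_fraction * per_survivor_ly`, and
#' analogously for QALYs with the respective utilities. Costs arise only
#' in the initial period (drug acquisition plus IFI management) and are
#' not discounted.
#'
#' @param strategy A `cea_strategy`.
#' @param draw Named numeric vector (or one-row data frame) of parameters.
#' @param settings Settings list.
#' @return A one-row tibble: `strategy`, `drug_cost`, `ifi_cost`,
#'   `total_cost`, `ly`, `qaly`.
#' @examples
#' evaluate_strategy(posaconazole_suspension(),
#'                   base_case_draw(default_parameters()))
#' @export
evaluate_strategy <- function(strategy, draw, settings = default_settings()) {
  draw <- .as_draw(draw)
  settings <- .validate_settings(settings)
  tree <- evaluate_tree(strategy, draw, settings)
  surv <- per_survivor_expectation(draw, settings)
  tibble::tibble(
    strategy = strategy$name,
    drug_cost = tree$prophylaxis_cost,
    ifi_cost = tree$ifi_management_cost,
    total_cost = tree$prophylaxis_cost + tree$ifi_management_cost,
    ly = tree$initial_ly + tree$survivor_fraction * surv$ly,
    qaly = tree$initial_qaly + tree$survivor_fraction * surv$qaly
  )
}

#' Compare two strategies
#'
#' Computes incremental cost, life-years and QALYs of `alternative` minus
#' `reference`, the corresponding ICERs, the incremental cost-effectiveness
#' plane quadrant, and dominance. An ICER is reported only when the
#' increment in the denominator is non-zero and cost and effect increments
#' share a sign (north-east or south-west quadrant); in the south-west
#' quadrant (cheaper and less effective) the ratio is still computed but
#' flagged by `quadrant = "SW"`. A strategy that is strictly cheaper and
#' strictly more effective dominates, and no ICER is reported.
#'
#' @param reference,alternative One-row strategy results from
#'   [evaluate_strategy()].
#' @return A one-row tibble: `reference`, `alternative`, `delta_cost`,
#'   `delta_ly`, `delta_qaly`, `icer_per_ly`, `icer_per_qaly`, `quadrant`
#'   (`"NE"`, `"SE"`, `"SW"`, `"NW"`, or `NA` on an axis), `dominance`
#'   (`"none"`, `"alt_dominant"`, `"ref_dominant"`).
#' @export
compare_strategies <- function(reference, alternative) {
  stopifnot(nrow(reference) == 1, nrow(alternative) == 1)
  dc <- alternative$total_cost - reference$total_cost
  dly <- alternative$ly - reference$ly
  dq <- alternative$qaly - reference$qaly

  dominance <- if (dc < 0 && dq > 0) {
    "alt_dominant"
  } else if (dc > 0 && dq < 0) {
    "ref_dominant"
  } else {
    "none"
  }
  quadrant <- if (dc == 0 || dq == 0) {
    NA_character_
  } else if (dc > 0 && dq > 0) "NE" else if (dc > 0 && dq < 0) {
    "NW"
  } else if (dc < 0 && dq < 0) "SW" else "SE"

  icer_ok <- function(d_eff) {
    d_eff != 0 && dominance == "none" && sign(dc) == sign(d_eff)
  }
  tibble::tibble(
    reference = reference$strategy,
    alternative = alternative$strategy,
    delta_cost = dc,
    delta_ly = dly,
    delta_qaly = dq,
    icer_per_ly = if (icer_ok(dly)) dc / dly else NA_real_,
    icer_per_qaly = if (icer_ok(dq)) dc / dq else NA_real_,
    quadrant = quadrant,
    dominance = dominance
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp x QALY - total cost`. At a given willingness-to-pay (WTP)
#' threshold, the strategy with the larger NMB is preferred; for two
#' strategies with a positive QALY increment, a positive incremental NMB
#' is equivalent to the ICER lying below the threshold.
#'
#' @param result A strategy result from [evaluate_strategy()] (one or more
#'   rows).
#' @param wtp Willingness to pay per QALY (USD), `>= 0`.
#' @return Numeric vector of net monetary benefits (USD).
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qaly - result$total_cost
}

#' Run the base-case cost-effectiveness analysis
#'
#' Evaluates the first-generation triazole arm (reference) and the
#' posaconazole oral suspension and tablet formulations at the base-case
#' parameter values, and compares each posaconazole formulation against
#' the reference.
#'
#' @param params Parameter table.
#' @param settings Settings list.
#' @return An object of class `cea_basecase` with elements `results`
#'   (three-row tibble of strategy results), `comparisons` (two-row tibble
#'   of incremental results vs. the reference), and `wtp`.
#' @examples
#' run_base_case()
#' @export
run_base_case <- function(params = default_parameters(),
                          settings = default_settings()) {
  validate_parameters(params)
  settings <- .validate_settings(settings)
  draw <- base_case_draw(params)
  ref <- evaluate_strategy(first_generation_triazoles(settings$fluconazole_share),
                           draw, settings)
  susp <- evaluate_strategy(posaconazole_suspension(), draw, settings)
  tab <- evaluate_strategy(posaconazole_tablet(), draw, settings)
  structure(
    list(
      results = dplyr::bind_rows(ref, susp, tab),
      comparisons = dplyr::bind_rows(
        compare_strategies(ref, susp),
        compare_strategies(ref, tab)
      ),
      wtp = settings$wtp_per_qaly
    ),
    class = "cea_basecase"
  )
}

#' @export
print.cea_basecase <- function(x, ...) {
  cat("Base-case cost-effectiveness analysis\n")
  cat("Per-strategy results (USD, years):\n")
  res <- dplyr::mutate(
    x$results,
    dplyr::across(dplyr::ends_with("cost"), ~ round(.x, 1)),
    dplyr::across(c("ly", "qaly"), ~ round(.x, 3))
  )
  print(as.data.frame(res), row.names = FALSE)
  cat("\nIncremental results vs.", x$comparisons$reference[1], ":\n")
  cmp <- dplyr::mutate(
    x$comparisons,
    delta_cost = round(.data$delta_cost, 1),
    dplyr::across(c("delta_ly", "delta_qaly"), ~ round(.x, 3)),
    dplyr::across(dplyr::starts_with("icer"), ~ round(.x, 1))
  )
  print(as.data.frame(cmp), row.names = FALSE)
  cat("\nWTP threshold: $", format(x$wtp, big.mark = ","), "/QALY\n", sep = "")
  invisible(x)
}

#' Tidy a base-case analysis
#'
#' @param x A `cea_basecase`.
#' @param ... Unused.
#' @return The per-strategy results tibble.
#' @export
tidy.cea_basecase <- function(x, ...) {
  x$results
}

#' One-row summary of a base-case analysis
#'
#' @param x A `cea_basecase`.
#' @param ... Unused.
#' @return A one-row tibble with the suspension and tablet ICERs per QALY,
#'   the incremental cost and QALYs of the suspension, the WTP threshold,
#'   and whether each formulation is cost-effective at that threshold.
#' @export
glance.cea_basecase <- function(x, ...) {
  cmp <- x$comparisons
  susp <- cmp[cmp$alternative == "posaconazole_suspension", ]
  tab <- cmp[cmp$alternative == "posaconazole_tablet", ]
  tibble::tibble(
    delta_cost_suspension = susp$delta_cost,
    delta_qaly_suspension = susp$delta_qaly,
    icer_per_qaly_suspension = susp$icer_per_qaly,
    icer_per_qaly_tablet = tab$icer_per_qaly,
    wtp_per_qaly = x$wtp,
    suspension_cost_effective = susp$icer_per_qaly <= x$wtp,
    tablet_cost_effective = tab$icer_per_qaly <= x$wtp
  )
}

# Vectorised strategy evaluation across many parameter draws (used by the
# probabilistic sensitivity analysis). `draws` is a tibble with one column
# per parameter. Returns a tibble of per-draw results.
.evaluate_strategy_draws <- function(strategy, draws, settings) {
  comp <- strategy$components
  drug_cost <- rep(0, nrow(draws))
  for (i in seq_len(nrow(comp))) {
    drug_cost <- drug_cost +
      comp$weight[i] * draws[[comp$cost_param[i]]] * draws[[comp$duration_param[i]]]
  }
  p_ifi <- draws[[strategy$p_ifi_param]]
  d_ifi <- draws[["p_death_ifi"]]
  d_oth <- draws[["p_death_other"]]
  sf <- p_ifi * (1 - d_ifi) + (1 - p_ifi) * (1 - d_oth)
  period_ly <- settings$initial_period_days / 365.25
  initial_ly <- if (settings$initial_accrual == "full") {
    rep(period_ly, nrow(draws))
  } else {
    period_ly * (sf + 0.5 * (1 - sf))
  }
  surv_ly <- .per_survivor_ly_vec(
    surv_aml = draws[["surv5_aml"]],
    surv_mds = draws[["surv5_mds"]],
    discount = draws[["discount_rate"]],
    aml_share = settings$aml_share,
    horizon = settings$horizon_cycles
  )
  ifi_cost <- p_ifi * draws[["cost_ifi_treatment"]]
  tibble::tibble(
    strategy = strategy$name,
    drug_cost = drug_cost,
    ifi_cost = ifi_cost,
    total_cost = drug_cost + ifi_cost,
    ly = initial_ly + sf * surv_ly,
    qaly = initial_ly * draws[["utility_induction"]] +
      sf * surv_ly * draws[["utility_remission"]]
  )
}
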