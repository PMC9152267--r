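#' The initial 100-day decision tree
#'
#' Over the first 100 days after starting prophylaxis, a patient either
#' develops an invasive fungal infection (IFI) and then dies of it or
#' survives it, or remains IFI-free and either dies of other causes or
#' survives. The four terminal states are mutually exclusive and
#' exhaustive. All prophylaxis drug costs and IFI-management costs fall in
#' this period and are therefore not discounted.
#'
#' @name posacea-tree
#' @keywords internal
NULL

#' Expected prophylaxis drug cost of a strategy
#'
#' Sum over drug components of weight x daily cost x duration, with costs
#' and durations taken from the supplied parameter draw.
#'
#' @param strategy A `cea_strategy`.
#' @param draw Named numeric vector (or one-row data frame) of parameter
#'   values, e.g. [base_case_draw()].
#' @return Expected drug cost in USD (scalar).
#' @examples
#' prophylaxis_cost(posaconazole_suspension(), base_case_draw(default_parameters()))
#' @export
prophylaxis_cost <- function(strategy, draw) {
  stopifnot(inherits(strategy, "cea_strategy"))
  draw <- .as_draw(draw)
  comp <- strategy$components
  sum(comp$weight * unname(draw[comp$cost_param]) * unname(draw[comp$duration_param]))
}

#' Evaluate the 100-day decision tree for one strategy
#'
#' Computes the terminal-state probabilities, the expected prophylaxis and
#' IFI-management costs, and the life-years/QALYs accrued during the
#' initial period. With `p` the IFI probability of the regimen, `d_ifi` the
#' IFI-related mortality and `d_o` the other-cause mortality:
#' `p_die_ifi = p * d_ifi`, `p_survive_post_ifi = p * (1 - d_ifi)`,
#' `p_die_other = (1 - p) * d_o`, `p_survive_no_ifi = (1 - p) * (1 - d_o)`.
#' The IFI-management cost attaches to IFI occurrence regardless of
#' subsequent death: `p * cost_ifi_treatment`.
#'
#' By default the full 100-day life-year accrual (weighted by the induction
#' utility for QALYs) is credited to every patient, including within-period
#' decedents; set `settings$initial_accrual = "half_for_decedents"` to
#' credit decedents half the period instead.
#'
#' @param strategy A `cea_strategy`.
#' @param draw Named numeric vector (or one-row data frame) of parameters.
#' @param settings Settings list ([default_settings()]).
#' @return A one-row tibble: `strategy`, the four terminal probabilities,
#'   `survivor_fraction`, `prophylaxis_cost`, `ifi_management_cost`,
#'   `initial_ly`, `initial_qaly`.
#' @examples
#' evaluate_tree(posaconazole_suspension(),
#'               base_case_draw(default_parameters()),
#'               default_settings())
#' @export
evaluate_tree <- function(strategy, draw, settings = default_settings()) {
  stopifnot(inherits(strategy, "cea_strategy"))
  draw <- .as_draw(draw)
  settings <- .validate_settings(settings)

  p_ifi <- unname(draw[strategy$p_ifi_param])
  d_ifi <- unname(draw["p_death_ifi"])
  d_oth <- unname(draw["p_death_other"])
  stopifnot(p_ifi >= 0, p_ifi <= 1, d_ifi >= 0, d_ifi <= 1, d_oth >= 0, d_oth <= 1)

  p_die_ifi <- p_ifi * d_ifi
  p_survive_post_ifi <- p_ifi * (1 - d_ifi)
  p_die_other <- (1 - p_ifi) * d_oth
  p_survive_no_ifi <- (1 - p_ifi) * (1 - d_oth)
  survivor_fraction <- p_survive_post_ifi + p_survive_no_ifi

  period_ly <- settings$initial_period_days / 365.25
  initial_ly <- if (settings$initial_accrual == "full") {
    period_ly
  } else {
    period_ly * (survivor_fraction + 0.5 * (1 - survivor_fraction))
  }

  drug_cost <- prophylaxis_cost(strategy, draw)
  tibble::tibble(
    strategy = strategy$name,
    p_die_ifi = p_die_ifi,
    p_die_other = p_die_other,
    p_survive_post_ifi = p_survive_post_ifi,
    p_survive_no_ifi = p_survive_no_ifi,
    survivor_fraction = survivor_fraction,
    prophylaxis_cost = drug_cost,
    ifi_management_cost = p_ifi * unname(draw["cost_ifi_treatment"]),
    initial_ly = initial_ly,
    initial_qaly = initial_ly * unname(draw["utility_induction"])
  )
}
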