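#' Define a prophylaxis strategy
#'
#' A strategy is one or more drug components (each with a daily-cost
#' parameter, a duration parameter and a mixing weight) plus the parameter
#' giving the probability of invasive fungal infection under that regimen.
#' Weights must sum to 1; a blend represents a treatment arm in which
#' patients receive different drugs (e.g. fluconazole or itraconazole).
#'
#' @param name Strategy label.
#' @param components A data frame with columns `drug`, `cost_param`,
#'   `duration_param`, `weight`.
#' @param p_ifi_param Name of the parameter holding the IFI probability for
#'   this regimen.
#' @return An object of class `cea_strategy`.
#' @examples
#' first_generation_triazoles()
#' @export
strategy <- function(name, components, p_ifi_param) {
  components <- tibble::as_tibble(components)
  stopifnot(
    all(c("drug", "cost_param", "duration_param", "weight") %in% names(components)),
    nrow(components) >= 1,
    all(components$weight >= 0)
  )
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("component weights must sum to 1")
  }
  structure(
    list(name = name, components = components, p_ifi_param = p_ifi_param),
    class = "cea_strategy"
  )
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat("<cea_strategy> ", x$name, " (p_ifi: ", x$p_ifi_param, ")\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Built-in prophylaxis strategies
#'
#' `posaconazole_suspension()`: oral suspension, 200 mg three times daily
#' for 29 days. `posaconazole_tablet()`: tablet formulation for the same 29
#' days, assumed equally effective (same IFI probability parameter).
#' `first_generation_triazoles()`: a blend of fluconazole (400 mg once
#' daily, 24 days) and itraconazole (200 mg twice daily, 29 days), mixed by
#' the share of patients receiving fluconazole.
#'
#' @param fluconazole_share Fraction of the first-generation arm receiving
#'   fluconazole (remainder itraconazole).
#' @return A `cea_strategy`.
#' @name builtin_strategies
NULL

#' @rdname builtin_strategies
#' @export
posaconazole_suspension <- function() {
  strategy(
    "posaconazole_suspension",
    tibble::tibble(
      drug = "posaconazole (oral suspension)",
      cost_param = "daily_cost_posa_susp",
      duration_param = "duration_posa",
      weight = 1
    ),
    p_ifi_param = "p_ifi_posaconazole"
  )
}

#' @rdname builtin_strategies
#' @export
posaconazole_tablet <- function() {
  strategy(
    "posaconazole_tablet",
    tibble::tibble(
      drug = "posaconazole (tablets)",
      cost_param = "daily_cost_posa_tab",
      duration_param = "duration_posa",
      weight = 1
    ),
    p_ifi_param = "p_ifi_posaconazole"
  )
}

#' @rdname builtin_strategies
#' @export
first_generation_triazoles <- function(fluconazole_share = 0.81) {
  stopifnot(fluconazole_share >= 0, fluconazole_share <= 1)
  strategy(
    "first_generation_triazoles",
    tibble::tibble(
      drug = c("fluconazole", "itraconazole"),
      cost_param = c("daily_cost_fluconazole", "daily_cost_itraconazole"),
      duration_param = c("duration_fluconazole", "duration_itraconazole"),
      weight = c(fluconazole_share, 1 - fluconazole_share)
    ),
    p_ifi_param = "p_ifi_first_gen"
  )
}

#' Look up a built-in strategy by name
#'
#' @param name One of `"posaconazole_suspension"`, `"posaconazole_tablet"`,
#'   `"first_generation_triazoles"`.
#' @param fluconazole_share Passed to [first_generation_triazoles()].
#' @return A `cea_strategy`.
#' @export
get_strategy <- function(name, fluconazole_share = 0.81) {
  switch(
    name,
    posaconazole_suspension = posaconazole_suspension(),
    posaconazole_tablet = posaconazole_tablet(),
    first_generation_triazoles = first_generation_triazoles(fluconazole_share),
    stop("unknown strategy: ", name)
  )
}
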