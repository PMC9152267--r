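#' Scenario analyses
#'
#' Two scenario analyses are supported: substituting the posaconazole
#' tablet formulation for the oral suspension (same efficacy and duration,
#' higher daily cost), and sweeping the willingness-to-pay threshold over
#' province-level values (three times each province's GDP per capita) to
#' reflect China's regional economic imbalance.
#'
#' @name posacea-scenarios
#' @keywords internal
NULL

#' The tablet-substitution strategy
#'
#' Returns the posaconazole tablet strategy used in the formulation
#' scenario: identical IFI probability and 29-day duration to the oral
#' suspension, with the tablet daily cost. The tablet daily cost is
#' applied flat over the full duration.
#'
#' @return A `cea_strategy`.
#' @export
tablet_strategy <- function() {
  posaconazole_tablet()
}

#' Read a province GDP-per-capita table
#'
#' Reads a CSV with columns `province`, `gdp_per_capita`, and optionally
#' `currency` (`"USD"` or `"CNY"`; default USD). CNY values are converted
#' to USD once at load using the fixed exchange rate in `settings`
#' (`cny_per_100usd`).
#'
#' @param path CSV file path.
#' @param settings Settings list (for the exchange rate).
#' @return A tibble with columns `province`, `gdp_per_capita` (USD).
#' @export
read_province_table <- function(path, settings = default_settings()) {
  settings <- .validate_settings(settings)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("province", "gdp_per_capita") %in% names(tbl)))
  if ("currency" %in% names(tbl)) {
    bad <- setdiff(unique(tbl$currency), c("USD", "CNY"))
    if (length(bad) > 0) stop("unknown currency: ", paste(bad, collapse = ", "))
    tbl$gdp_per_capita <- ifelse(
      tbl$currency == "CNY",
      tbl$gdp_per_capita / settings$cny_per_100usd * 100,
      tbl$gdp_per_capita
    )
    tbl$currency <- NULL
  }
  if (any(tbl$gdp_per_capita <= 0)) stop("gdp_per_capita must be positive")
  tibble::as_tibble(tbl[c("province", "gdp_per_capita")])
}

#' Province-level willingness-to-pay analysis
#'
#' For each province, sets the WTP threshold to three times its GDP per
#' capita and reports whether the base-case ICER falls below it and the
#' PSA probability of cost-effectiveness at that threshold.
#'
#' @param provinces Tibble with `province`, `gdp_per_capita` (USD), e.g.
#'   from [read_province_table()] or [make_province_table()].
#' @param comparison One-row comparison from [compare_strategies()] (or a
#'   `cea_basecase` comparisons row) holding the base-case ICER.
#' @param psa A `cea_psa` for the same strategy pair.
#' @return A tibble: `province`, `gdp_per_capita`, `wtp`,
#'   `icer_below_wtp`, `psa_probability`. Empty input gives an empty
#'   report.
#' @export
province_analysis <- function(provinces, comparison, psa) {
  stopifnot(is.data.frame(provinces))
  if (nrow(provinces) == 0) {
    return(tibble::tibble(
      province = character(), gdp_per_capita = numeric(), wtp = numeric(),
      icer_below_wtp = logical(), psa_probability = numeric()
    ))
  }
  stopifnot(all(provinces$gdp_per_capita > 0))
  icer <- comparison$icer_per_qaly[1]
  wtp <- 3 * provinces$gdp_per_capita
  tibble::tibble(
    province = provinces$province,
    gdp_per_capita = provinces$gdp_per_capita,
    wtp = wtp,
    icer_below_wtp = !is.na(icer) & icer <= wtp,
    psa_probability = probability_cost_effective(psa, wtp)
  )
}
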