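#' Synthetic data generation
#'
#' Generators for inputs with the statistical structure the analysis
#' assumes: RCT-like binomial outcome counts at the trial arm sizes
#' (posaconazole n = 304, first-generation triazoles n = 298), and
#' province-level GDP-per-capita tables for willingness-to-pay sweeps.
#' These enable end-to-end and parameter-recovery testing without any
#' external data.
#'
#' @name posacea-synthetic
#' @keywords internal
NULL

#' Simulate trial outcome counts
#'
#' Draws, per arm, the number of invasive fungal infections
#' `Binomial(n, p_ifi_arm)`, then IFI deaths among the infected
#' `Binomial(ifi_events, p_death_ifi)` and other-cause deaths among the
#' uninfected `Binomial(n - ifi_events, p_death_other)`. Deaths are
#' conditioned hierarchically on simulated IFI events, mirroring how the
#' source probabilities nest.
#'
#' @param truth Parameter table providing the generating probabilities.
#' @param n_posa,n_fgt Arm sizes (default the trial sizes 304 and 298).
#' @param seed Optional integer seed.
#' @return A tibble with one row per arm: `arm`, `n`, `ifi_events`,
#'   `deaths_ifi`, `deaths_other`.
#' @examples
#' simulate_trial(default_parameters(), seed = 1)
#' @export
simulate_trial <- function(truth = default_parameters(),
                           n_posa = 304, n_fgt = 298, seed = NULL) {
  validate_parameters(truth)
  stopifnot(n_posa >= 0, n_fgt >= 0)
  val <- base_case_draw(truth)
  sim <- function() {
    n <- c(posaconazole = n_posa, first_generation = n_fgt)
    p_ifi <- c(val["p_ifi_posaconazole"], val["p_ifi_first_gen"])
    ifi <- stats::rbinom(2, n, p_ifi)
    d_ifi <- stats::rbinom(2, ifi, val["p_death_ifi"])
    d_oth <- stats::rbinom(2, n - ifi, val["p_death_other"])
    tibble::tibble(
      arm = names(n),
      n = as.integer(n),
      ifi_events = as.integer(ifi),
      deaths_ifi = as.integer(d_ifi),
      deaths_other = as.integer(d_oth)
    )
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Estimate model probabilities from trial counts
#'
#' Recovers the decision-tree probabilities from (possibly simulated)
#' outcome counts: per-arm IFI probability `events / n`, IFI-related
#' mortality pooled across arms, and other-cause mortality pooled across
#' arms, each with a range of plus/minus 25% of the estimate (capped at 1
#' for probabilities). Quantities with a zero denominator are returned as
#' `NA` with `estimable = FALSE`.
#'
#' @param counts Trial-count tibble as from [simulate_trial()].
#' @return A tibble: `name`, `value`, `low`, `high`, `events`, `trials`,
#'   `estimable`.
#' @examples
#' estimate_parameters(simulate_trial(seed = 1))
#' @export
estimate_parameters <- function(counts) {
  stopifnot(
    is.data.frame(counts),
    all(c("arm", "n", "ifi_events", "deaths_ifi", "deaths_other") %in% names(counts)),
    nrow(counts) == 2
  )
  stopifnot(
    all(counts$ifi_events >= 0), all(counts$ifi_events <= counts$n),
    all(counts$deaths_ifi <= counts$ifi_events),
    all(counts$deaths_other <= counts$n - counts$ifi_events)
  )
  posa <- counts[counts$arm == "posaconazole", ]
  fgt <- counts[counts$arm == "first_generation", ]
  entry <- function(name, events, trials) {
    est <- if (trials > 0) events / trials else NA_real_
    tibble::tibble(
      name = name,
      value = est,
      low = if (is.na(est)) NA_real_ else est * 0.75,
      high = if (is.na(est)) NA_real_ else min(est * 1.25, 1),
      events = as.integer(events),
      trials = as.integer(trials),
      estimable = trials > 0
    )
  }
  dplyr::bind_rows(
    entry("p_ifi_posaconazole", posa$ifi_events, posa$n),
    entry("p_ifi_first_gen", fgt$ifi_events, fgt$n),
    entry("p_death_ifi", sum(counts$deaths_ifi), sum(counts$ifi_events)),
    entry("p_death_other", sum(counts$deaths_other), sum(counts$n - counts$ifi_events))
  )
}

#' Apply estimated probabilities to a parameter table
#'
#' Overwrites the estimable entries of `params` with the estimates (value
#' and range) from [estimate_parameters()], enabling an end-to-end
#' estimate-then-model pipeline on simulated trials.
#'
#' @param params Parameter table to update.
#' @param estimates Output of [estimate_parameters()].
#' @return The updated parameter table.
#' @export
apply_estimates <- function(params, estimates) {
  validate_parameters(params)
  est <- estimates[estimates$estimable, ]
  i <- match(est$name, params$name)
  stopifnot(!anyNA(i))
  params$value[i] <- est$value
  params$low[i] <- est$low
  params$high[i] <- est$high
  params$events[i] <- est$events
  params$trials[i] <- est$trials
  validate_parameters(params)
  params
}

#' Generate a synthetic province GDP table
#'
#' Draws `n` provinces with GDP per capita uniform on `gdp_range` (USD).
#' The real province-level figures are deliberately not bundled; this
#' synthetic table stands in for a user-supplied CSV.
#'
#' @param n Number of provinces.
#' @param gdp_range Length-2 numeric `(low, high)` in USD.
#' @param seed Optional integer seed.
#' @return A tibble: `province` (`"province_01"`, ...), `gdp_per_capita`.
#' @examples
#' make_province_table(31, seed = 1)
#' @export
make_province_table <- function(n = 31, gdp_range = c(5000, 25000), seed = NULL) {
  stopifnot(n >= 0, length(gdp_range) == 2, gdp_range[1] <= gdp_range[2],
            gdp_range[1] > 0)
  gen <- function() {
    tibble::tibble(
      province = sprintf("province_%02d", seq_len(n)),
      gdp_per_capita = stats::runif(n, gdp_range[1], gdp_range[2])
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
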