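#' Lifetime Markov phase for 100-day survivors
#'
#' Patients alive at day 100 enter a two-state (alive/dead) cohort model
#' run in monthly cycles with half-cycle correction. The death hazard is
#' constant, derived from the 5-year relative survival of the underlying
#' disease (AML or MDS) and extrapolated unchanged beyond five years.
#' Benefits (life-years and QALYs) are discounted annually; no costs
#' accrue in this phase.
#'
#' @name posacea-markov
#' @keywords internal
NULL

#' Convert a 5-year survival probability to a monthly death probability
#'
#' Assumes a constant hazard over the 60 months: the monthly probability
#' `p` satisfies `(1 - p)^60 = S5`, i.e. `p = 1 - S5^(1/60)`.
#'
#' @param five_year_survival Probability of surviving 5 years, in `(0, 1]`.
#' @return Monthly death probability.
#' @examples
#' monthly_death_probability(0.44)
#' @export
monthly_death_probability <- function(five_year_survival) {
  stopifnot(all(five_year_survival <= 1))
  if (any(five_year_survival <= 0)) {
    stop("five-year survival must be positive (zero implies infinite hazard)")
  }
  1 - five_year_survival^(1 / 60)
}

# Monthly discount factor from an annual rate.
.monthly_discount_factor <- function(annual_discount) {
  (1 + annual_discount)^(-1 / 12)
}

#' Run the two-state cohort model
#'
#' Tracks the surviving proportion `alive[t] = (1 - monthly_p)^t` over
#' `horizon_cycles` monthly cycles and accumulates discounted life-years
#' with the trapezoidal half-cycle correction: cycle 0 and the final cycle
#' contribute half weight. With `v = (1 + annual_discount)^(-1/12)`,
#' `discounted_ly = (1/12) * (alive[0] v^0 / 2 + sum_{t=1}^{T-1} alive[t] v^t
#' + alive[T] v^T / 2)`. QALYs apply the (constant) utility weight.
#'
#' @param monthly_p Monthly death probability in `[0, 1]`.
#' @param horizon_cycles Number of monthly cycles (`T >= 1`).
#' @param annual_discount Annual discount rate for benefits.
#' @param utility Utility weight applied to each alive cycle.
#' @return A list of class `markov_trace`: `trace` (tibble with columns
#'   `cycle`, `alive_proportion`, `discount_factor`, `cycle_ly`,
#'   `cycle_qaly`), `discounted_ly`, `discounted_qaly`.
#' @examples
#' run_cohort(monthly_death_probability(0.44), 600, 0.05, 0.830)
#' @export
run_cohort <- function(monthly_p, horizon_cycles, annual_discount, utility = 1) {
  stopifnot(
    length(monthly_p) == 1, monthly_p >= 0, monthly_p <= 1,
    horizon_cycles >= 1, annual_discount >= 0,
    utility >= 0, utility <= 1
  )
  t <- 0:horizon_cycles
  alive <- (1 - monthly_p)^t
  v <- .monthly_discount_factor(annual_discount)^t
  w <- c(0.5, rep(1, horizon_cycles - 1), 0.5)
  cycle_ly <- w * alive * v / 12
  trace <- tibble::tibble(
    cycle = t,
    alive_proportion = alive,
    discount_factor = v,
    cycle_ly = cycle_ly,
    cycle_qaly = cycle_ly * utility
  )
  structure(
    list(
      trace = trace,
      discounted_ly = sum(cycle_ly),
      discounted_qaly = sum(cycle_ly) * utility
    ),
    class = "markov_trace"
  )
}

#' @export
print.markov_trace <- function(x, ...) {
  cat("<markov_trace> ", nrow(x$trace) - 1, " cycles; discounted LY = ",
      signif(x$discounted_ly, 6), ", QALY = ", signif(x$discounted_qaly, 6),
      "\n", sep = "")
  invisible(x)
}

#' Export a Markov trace to CSV
#'
#' @param trace A `markov_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "markov_trace"))
  readr::write_csv(trace$trace, path)
  invisible(path)
}

#' Expected lifetime outcomes per 100-day survivor
#'
#' Mixes the AML and MDS cohort traces by the AML share of the study
#' population; both traces use the remission utility and the drawn
#' discount rate.
#'
#' @param draw Named numeric vector (or one-row data frame) of parameters.
#' @param settings Settings list.
#' @return A one-row tibble with columns `ly` and `qaly` (discounted, per
#'   entering survivor).
#' @examples
#' per_survivor_expectation(base_case_draw(default_parameters()))
#' @export
per_survivor_expectation <- function(draw, settings = default_settings()) {
  draw <- .as_draw(draw)
  settings <- .validate_settings(settings)
  ly <- .per_survivor_ly_vec(
    surv_aml = unname(draw["surv5_aml"]),
    surv_mds = unname(draw["surv5_mds"]),
    discount = unname(draw["discount_rate"]),
    aml_share = settings$aml_share,
    horizon = settings$horizon_cycles
  )
  tibble::tibble(ly = ly, qaly = ly * unname(draw["utility_remission"]))
}

# Vectorised (over draws) discounted per-survivor life-years: mixes the AML
# and MDS traces at the cohort AML share. Chunked so the cycle-by-draw
# matrices stay small.
.per_survivor_ly_vec <- function(surv_aml, surv_mds, discount, aml_share,
                                 horizon, chunk = 2000L) {
  n <- max(length(surv_aml), length(surv_mds), length(discount))
  surv_aml <- rep_len(surv_aml, n)
  surv_mds <- rep_len(surv_mds, n)
  discount <- rep_len(discount, n)
  t <- 0:horizon
  w <- c(0.5, rep(1, horizon - 1), 0.5)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    v <- outer(t, .monthly_discount_factor(discount[idx]), function(tt, vv) vv^tt)
    a_aml <- outer(t, 1 - monthly_death_probability(surv_aml[idx]), function(tt, ss) ss^tt)
    a_mds <- outer(t, 1 - monthly_death_probability(surv_mds[idx]), function(tt, ss) ss^tt)
    ly_aml <- colSums(w * a_aml * v) / 12
    ly_mds <- colSums(w * a_mds * v) / 12
    out[idx] <- aml_share * ly_aml + (1 - aml_share) * ly_mds
  }
  out
}
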