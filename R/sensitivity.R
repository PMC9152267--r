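#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the incremental cost-effectiveness ratio (per QALY) of
#' `alternative` vs. `reference` with each model parameter set in turn to
#' the low and high end of its sensitivity range ([dsa_bounds()]) while
#' all other parameters stay at base. Structural constants (cohort shares,
#' horizon) are not varied. Entries are sorted by bar width
#' `|icer_high - icer_low|`, widest first, ties broken alphabetically.
#'
#' @param params Parameter table.
#' @param settings Settings list.
#' @param reference,alternative `cea_strategy` objects; defaults are the
#'   first-generation triazole arm and the posaconazole oral suspension.
#' @return A tibble: `parameter`, `low`, `high` (parameter values),
#'   `icer_low`, `icer_high` (ICER per QALY at each bound), `width`,
#'   sorted by decreasing `width`.
#' @examples
#' one_way_dsa(default_parameters())
#' @export
one_way_dsa <- function(params = default_parameters(),
                        settings = default_settings(),
                        reference = NULL,
                        alternative = posaconazole_suspension()) {
  validate_parameters(params)
  settings <- .validate_settings(settings)
  if (is.null(reference)) {
    reference <- first_generation_triazoles(settings$fluconazole_share)
  }
  bounds <- dsa_bounds(params)
  base <- base_case_draw(params)
  icer_at <- function(name, value) {
    draw <- base
    draw[name] <- value
    cmp <- compare_strategies(
      evaluate_strategy(reference, draw, settings),
      evaluate_strategy(alternative, draw, settings)
    )
    cmp$icer_per_qaly
  }
  out <- purrr::pmap_dfr(bounds, function(name, dsa_low, dsa_high) {
    tibble::tibble(
      parameter = name,
      low = dsa_low,
      high = dsa_high,
      icer_low = icer_at(name, dsa_low),
      icer_high = icer_at(name, dsa_high)
    )
  })
  out$width <- abs(out$icer_high - out$icer_low)
  dplyr::arrange(out, dplyr::desc(.data$width), .data$parameter)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation drawing every parameter from its fitted sampling
#' distribution and evaluating both strategies through the full
#' tree-plus-Markov model for each draw. The result records per-iteration
#' costs and effects and their increments (`alternative - reference`).
#'
#' @param params Parameter table.
#' @param settings Settings list; `psa_iterations` and `rng_seed` provide
#'   defaults for `n` and `seed`.
#' @param reference,alternative `cea_strategy` objects; defaults as in
#'   [one_way_dsa()].
#' @param n Number of iterations (default `settings$psa_iterations`).
#' @param seed Integer RNG seed (default `settings$rng_seed`).
#' @return An object of class `cea_psa`: `iterations` (tibble with columns
#'   `.draw`, `cost_ref`, `qaly_ref`, `ly_ref`, `cost_alt`, `qaly_alt`,
#'   `ly_alt`, `delta_cost`, `delta_ly`, `delta_qaly`), `draws` (the
#'   sampled parameter sets), `n`, `seed`, `reference`, `alternative`,
#'   `wtp`.
#' @examples
#' psa <- run_psa(n = 50, seed = 7)
#' @export
run_psa <- function(params = default_parameters(),
                    settings = default_settings(),
                    reference = NULL,
                    alternative = posaconazole_suspension(),
                    n = NULL, seed = NULL) {
  validate_parameters(params)
  settings <- .validate_settings(settings)
  if (is.null(reference)) {
    reference <- first_generation_triazoles(settings$fluconazole_share)
  }
  if (is.null(n)) n <- settings$psa_iterations
  if (is.null(seed)) seed <- settings$rng_seed
  stopifnot(n >= 1)
  draws <- sample_parameter_set(params, n = n, seed = seed)
  res_ref <- .evaluate_strategy_draws(reference, draws, settings)
  res_alt <- .evaluate_strategy_draws(alternative, draws, settings)
  iterations <- tibble::tibble(
    .draw = draws$.draw,
    cost_ref = res_ref$total_cost,
    ly_ref = res_ref$ly,
    qaly_ref = res_ref$qaly,
    cost_alt = res_alt$total_cost,
    ly_alt = res_alt$ly,
    qaly_alt = res_alt$qaly,
    delta_cost = res_alt$total_cost - res_ref$total_cost,
    delta_ly = res_alt$ly - res_ref$ly,
    delta_qaly = res_alt$qaly - res_ref$qaly
  )
  structure(
    list(
      iterations = iterations,
      draws = draws,
      n = as.integer(n),
      seed = as.integer(seed),
      reference = reference$name,
      alternative = alternative$name,
      wtp = settings$wtp_per_qaly
    ),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa> ", x$n, " iterations (seed ", x$seed, "): ",
      x$alternative, " vs. ", x$reference, "\n", sep = "")
  cat("mean delta cost = ", round(mean(x$iterations$delta_cost), 1),
      ", mean delta QALY = ", round(mean(x$iterations$delta_qaly), 4), "\n", sep = "")
  cat("P(cost-effective at $", format(x$wtp, big.mark = ","), "/QALY) = ",
      round(probability_cost_effective(x, x$wtp), 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return The per-iteration results tibble.
#' @export
tidy.cea_psa <- function(x, ...) {
  x$iterations
}

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return A one-row tibble: iteration count, seed, mean increments, and
#'   the probability of cost-effectiveness at the stored WTP threshold.
#' @export
glance.cea_psa <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    seed = x$seed,
    mean_delta_cost = mean(x$iterations$delta_cost),
    mean_delta_qaly = mean(x$iterations$delta_qaly),
    wtp_per_qaly = x$wtp,
    prob_cost_effective = probability_cost_effective(x, x$wtp)
  )
}

#' Probability that the alternative is cost-effective
#'
#' The fraction of PSA iterations in which the incremental net monetary
#' benefit is positive: `wtp * delta_qaly - delta_cost > 0`. Using the NMB
#' criterion avoids the undefined-ratio pathology of per-iteration ICERs
#' when `delta_qaly <= 0`.
#'
#' @param psa A `cea_psa` (or a data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp Willingness to pay per QALY (USD); may be a vector.
#' @return Fraction(s) in `[0, 1]`, one per `wtp` value.
#' @export
probability_cost_effective <- function(psa, wtp) {
  it <- if (inherits(psa, "cea_psa")) psa$iterations else psa
  stopifnot(all(wtp >= 0))
  vapply(wtp, function(w) mean(w * it$delta_qaly - it$delta_cost > 0), numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates [probability_cost_effective()] over a grid of
#' willingness-to-pay values.
#'
#' @param psa A `cea_psa`.
#' @param wtp_grid Ascending numeric vector of WTP values (USD/QALY);
#'   default 0 to 60,000 in steps of 250.
#' @return A tibble with columns `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 250)) {
  if (length(wtp_grid) == 0) {
    return(tibble::tibble(wtp = numeric(), probability_cost_effective = numeric()))
  }
  stopifnot(!is.unsorted(wtp_grid))
  tibble::tibble(
    wtp = wtp_grid,
    probability_cost_effective = probability_cost_effective(psa, wtp_grid)
  )
}

#' Smallest WTP at which the alternative is favoured
#'
#' The smallest grid value at which the CEAC exceeds 0.5 — the point
#' beyond which the alternative is more likely than not to be
#' cost-effective.
#'
#' @param ceac_tbl A CEAC tibble from [ceac()].
#' @return A scalar WTP (USD/QALY), or `NA` if the curve never crosses 0.5.
#' @export
ceac_crossing <- function(ceac_tbl) {
  above <- ceac_tbl$wtp[ceac_tbl$probability_cost_effective > 0.5]
  if (length(above) == 0) NA_real_ else min(above)
}
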