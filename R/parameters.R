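#' Model input parameters
#'
#' The model is driven by a parameter table (one row per input: base value,
#' plausible range, and the distribution family used in probabilistic
#' sensitivity analysis) together with a list of structural settings
#' (cohort composition, cycle structure, willingness-to-pay threshold).
#'
#' @name posacea-parameters
#' @keywords internal
NULL

# Required parameter names: the table is rejected when any of these is absent.
.required_parameters <- c(
  "p_ifi_posaconazole", "p_ifi_first_gen", "p_death_ifi", "p_death_other",
  "surv5_aml", "surv5_mds", "cost_ifi_treatment",
  "daily_cost_posa_susp", "daily_cost_posa_tab",
  "daily_cost_fluconazole", "daily_cost_itraconazole",
  "duration_posa", "duration_fluconazole", "duration_itraconazole",
  "discount_rate", "utility_induction", "utility_remission"
)

.dist_families <- c("beta", "uniform", "gamma", "fixed")

#' Default model parameters
#'
#' Returns the full input-parameter table for the prophylaxis model: IFI and
#' mortality probabilities over the initial 100 days, 5-year relative
#' survivals for AML and MDS, drug and IFI-management costs (2020 USD),
#' prophylaxis durations, the annual discount rate, and health-state
#' utilities. Each row carries the base value, the range used in one-way
#' sensitivity analysis, and the distribution family used in probabilistic
#' sensitivity analysis.
#'
#' Probabilities whose base values derive from trial counts (IFI occurrence
#' per arm and pooled IFI-related mortality) are stored as the unrounded
#' event fractions (e.g. 14/304 rather than 0.046), with the counts kept in
#' the `events`/`trials` columns; set `use_trial_fractions = FALSE` to use
#' the rounded three-decimal values instead.
#'
#' @param use_trial_fractions Logical; store count-derived probabilities as
#'   exact fractions (default) or as their rounded three-decimal values.
#' @return A tibble with columns `name`, `value`, `low`, `high`, `family`
#'   (one of `"beta"`, `"uniform"`, `"gamma"`, `"fixed"`), `role` (one of
#'   `"probability"`, `"cost"`, `"duration"`, `"utility"`, `"rate"`),
#'   `events` and `trials` (integer counts, `NA` where not count-derived).
#' @examples
#' default_parameters()
#' @export
default_parameters <- function(use_trial_fractions = TRUE) {
  p <- tibble::tribble(
    ~name,                      ~value,   ~low,    ~high,    ~family,   ~role,        ~events, ~trials,
    "p_ifi_posaconazole",       14 / 304, 0.034,   0.058,    "beta",    "probability", 14L,    304L,
    "p_ifi_first_gen",          33 / 298, 0.083,   0.139,    "beta",    "probability", 33L,    298L,
    "p_death_ifi",              21 / 47,  0.335,   0.559,    "beta",    "probability", 21L,    47L,
    "p_death_other",            0.158,    0.119,   0.198,    "beta",    "probability", NA_integer_, NA_integer_,
    "surv5_aml",                0.44,     0.33,    0.55,     "uniform", "probability", NA_integer_, NA_integer_,
    "surv5_mds",                0.52,     0.39,    0.65,     "uniform", "probability", NA_integer_, NA_integer_,
    "cost_ifi_treatment",       5423.3,   4067.5,  6779.1,   "uniform", "cost",        NA_integer_, NA_integer_,
    "daily_cost_posa_susp",     45.56,    34.17,   56.95,    "uniform", "cost",        NA_integer_, NA_integer_,
    "daily_cost_posa_tab",      119.98,   89.99,   149.98,   "uniform", "cost",        NA_integer_, NA_integer_,
    "daily_cost_fluconazole",   0.26,     0.20,    0.33,     "uniform", "cost",        NA_integer_, NA_integer_,
    "daily_cost_itraconazole",  1.89,     1.42,    2.36,     "uniform", "cost",        NA_integer_, NA_integer_,
    "duration_posa",            29,       21.75,   36.25,    "gamma",   "duration",    NA_integer_, NA_integer_,
    "duration_fluconazole",     24,       18.00,   30.00,    "gamma",   "duration",    NA_integer_, NA_integer_,
    "duration_itraconazole",    29,       21.75,   36.25,    "gamma",   "duration",    NA_integer_, NA_integer_,
    "discount_rate",            0.05,     0.00,    0.08,     "uniform", "rate",        NA_integer_, NA_integer_,
    "utility_induction",        0.648,    0.486,   0.810,    "uniform", "utility",     NA_integer_, NA_integer_,
    "utility_remission",        0.830,    0.623,   1.000,    "uniform", "utility",     NA_integer_, NA_integer_
  )
  if (!use_trial_fractions) {
    rounded <- c(p_ifi_posaconazole = 0.046, p_ifi_first_gen = 0.111, p_death_ifi = 0.447)
    p$value[match(names(rounded), p$name)] <- unname(rounded)
  }
  validate_parameters(p)
  p
}

#' Default structural settings
#'
#' Structural constants of the model that are not sampled in probabilistic
#' sensitivity analysis: the 100-day initial (decision-tree) period, the
#' one-month Markov cycle and its 600-cycle (50-year) horizon, the cohort
#' composition (86% AML / 14% MDS), the fluconazole share of the
#' first-generation triazole arm (81%), the national willingness-to-pay
#' threshold (three times 2020 GDP per capita, $31,315/QALY), the CNY/USD
#' conversion, and defaults for the probabilistic analysis.
#'
#' @return A named list of settings; see Details in the package vignette.
#' @examples
#' default_settings()$wtp_per_qaly
#' @export
default_settings <- function() {
  list(
    initial_period_days = 100,
    cycle_length_months = 1,
    horizon_cycles = 600L,
    aml_share = 0.86,
    fluconazole_share = 0.81,
    wtp_per_qaly = 31315,
    cny_per_100usd = 689.76,
    psa_iterations = 1000L,
    rng_seed = 1L,
    initial_accrual = "full"
  )
}

#' Validate a parameter table
#'
#' Checks completeness (every required model input present), distribution
#' families, range ordering (`low <= value <= high`), and unit constraints
#' (probabilities and utilities in `[0, 1]`; costs and durations
#' non-negative). Called internally by every entry point that accepts a
#' parameter table.
#'
#' @param params A parameter table as returned by [default_parameters()].
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.data.frame(params))
  needed <- c("name", "value", "low", "high", "family", "role")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  missing_par <- setdiff(.required_parameters, params$name)
  if (length(missing_par) > 0) {
    stop("parameter table is missing required parameter(s): ",
         paste(missing_par, collapse = ", "))
  }
  if (anyDuplicated(params$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(params$name[duplicated(params$name)]), collapse = ", "))
  }
  bad_fam <- setdiff(unique(params$family), .dist_families)
  if (length(bad_fam) > 0) {
    stop("unknown distribution family: ", paste(bad_fam, collapse = ", "))
  }
  with_range <- !is.na(params$low) & !is.na(params$high)
  bad_rng <- with_range & (params$low > params$high | params$value < params$low |
                             params$value > params$high)
  if (any(bad_rng)) {
    stop("range must satisfy low <= base <= high for: ",
         paste(params$name[bad_rng], collapse = ", "))
  }
  unit01 <- params$role %in% c("probability", "utility")
  bad01 <- unit01 & (params$value < 0 | params$value > 1)
  if (any(bad01)) {
    stop("probabilities/utilities must lie in [0, 1]: ",
         paste(params$name[bad01], collapse = ", "))
  }
  nonneg <- params$role %in% c("cost", "duration")
  badn <- nonneg & params$value < 0
  if (any(badn)) {
    stop("costs and durations must be non-negative: ",
         paste(params$name[badn], collapse = ", "))
  }
  beta_bad <- params$family == "beta" & with_range & (params$low < 0 | params$high > 1)
  if (any(beta_bad)) {
    stop("beta ranges must lie within [0, 1]: ",
         paste(params$name[beta_bad], collapse = ", "))
  }
  gamma_bad <- params$family == "gamma" & with_range & params$low <= 0
  if (any(gamma_bad)) {
    stop("gamma ranges require low > 0: ",
         paste(params$name[gamma_bad], collapse = ", "))
  }
  invisible(params)
}

.validate_settings <- function(settings) {
  defaults <- default_settings()
  unknown <- setdiff(names(settings), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown setting(s): ", paste(unknown, collapse = ", "))
  }
  s <- utils::modifyList(defaults, settings)
  stopifnot(
    s$initial_period_days > 0,
    s$horizon_cycles >= 1,
    s$aml_share >= 0, s$aml_share <= 1,
    s$fluconazole_share >= 0, s$fluconazole_share <= 1,
    s$wtp_per_qaly >= 0,
    s$psa_iterations >= 1
  )
  if (!s$initial_accrual %in% c("full", "half_for_decedents")) {
    stop("initial_accrual must be 'full' or 'half_for_decedents'")
  }
  s
}

#' Load model configuration from a YAML file
#'
#' Reads a YAML document with optional `parameters:` and `settings:`
#' sections and applies it as overrides on top of the package defaults.
#' Each entry under `parameters:` may set any of `base`, `low`, `high`,
#' `family`; unknown parameter names, unknown fields, unknown settings and
#' invalid ranges are rejected with an informative error. An empty document
#' reproduces the defaults exactly, and `write_config()` followed by
#' `load_config()` round-trips.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `parameters` (tibble) and `settings` (list).
#' @seealso [write_config()], [default_parameters()], [default_settings()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), c("parameters", "settings"))
  if (length(unknown) > 0) {
    stop("unknown top-level config section(s): ", paste(unknown, collapse = ", "))
  }
  params <- default_parameters()
  for (nm in names(doc$parameters)) {
    i <- match(nm, params$name)
    if (is.na(i)) stop("unknown parameter in config: ", nm)
    entry <- doc$parameters[[nm]]
    bad <- setdiff(names(entry), c("base", "low", "high", "family"))
    if (length(bad) > 0) {
      stop("unknown field(s) for parameter ", nm, ": ", paste(bad, collapse = ", "))
    }
    if (!is.null(entry$base)) params$value[i] <- as.numeric(entry$base)
    if (!is.null(entry$low)) params$low[i] <- as.numeric(entry$low)
    if (!is.null(entry$high)) params$high[i] <- as.numeric(entry$high)
    if (!is.null(entry$family)) {
      fam <- as.character(entry$family)
      if (!fam %in% .dist_families) stop("unknown distribution family: ", fam)
      params$family[i] <- fam
    }
  }
  validate_parameters(params)
  settings <- .validate_settings(as.list(doc$settings))
  list(parameters = params, settings = settings)
}

#' Write model configuration to a YAML file
#'
#' Serializes a parameter table and settings list to the YAML schema read
#' by [load_config()]. Writing the defaults gives users an editable
#' template.
#'
#' @param params Parameter table ([default_parameters()] by default).
#' @param settings Settings list ([default_settings()] by default).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, params = default_parameters(),
                         settings = default_settings()) {
  validate_parameters(params)
  plist <- stats::setNames(
    purrr::pmap(params, function(name, value, low, high, family, ...) {
      list(base = value, low = low, high = high, family = family)
    }),
    params$name
  )
  yaml::write_yaml(list(parameters = plist, settings = settings), path,
                   precision = 15)
  invisible(path)
}

#' Bounds used in one-way deterministic sensitivity analysis
#'
#' For each parameter, returns the range over which it is varied one at a
#' time: the stated range when one is given, otherwise the base value plus
#' and minus 25%, with utilities truncated at 1. Parameters with the
#' `fixed` family are not varied (degenerate range at base).
#'
#' @param params Parameter table.
#' @return A tibble with columns `name`, `dsa_low`, `dsa_high`.
#' @examples
#' dsa_bounds(default_parameters())
#' @export
dsa_bounds <- function(params) {
  validate_parameters(params)
  dplyr::mutate(
    dplyr::select(params, "name", "value", "low", "high", "family", "role"),
    dsa_low = dplyr::if_else(is.na(.data$low), .data$value * 0.75, .data$low),
    dsa_high = dplyr::if_else(is.na(.data$high), .data$value * 1.25, .data$high),
    dsa_high = dplyr::if_else(.data$role == "utility", pmin(.data$dsa_high, 1), .data$dsa_high),
    dsa_low = dplyr::if_else(.data$family == "fixed", .data$value, .data$dsa_low),
    dsa_high = dplyr::if_else(.data$family == "fixed", .data$value, .data$dsa_high)
  ) |>
    dplyr::select("name", "dsa_low", "dsa_high")
}

#' Construct the sampling distribution for one parameter
#'
#' Builds the distribution from which a parameter is drawn in probabilistic
#' sensitivity analysis. `uniform` is taken directly on `[low, high]`.
#' `beta` and `gamma` are moment-matched so that the analytic mean equals
#' the base value and the standard deviation equals `(high - low) / 3.92`
#' (the stated range treated as a 95% interval): beta via
#' `alpha = m (m(1-m)/v - 1)`, `beta = (1-m)(m(1-m)/v - 1)`; gamma via
#' `shape = m^2/v`, `scale = v/m`. `fixed` (and any parameter with a
#' degenerate range) is a point mass at the base value.
#'
#' @param params Parameter table.
#' @param name Name of the parameter to fit.
#' @return An object of class `cea_dist` with elements `family`, `mean`,
#'   `sd` and the family-specific parameters.
#' @examples
#' fit_sampling_distribution(default_parameters(), "duration_posa")
#' @export
fit_sampling_distribution <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  row <- params[i, ]
  m <- row$value
  sdv <- if (is.na(row$low) || is.na(row$high)) 0 else (row$high - row$low) / 3.92
  v <- sdv^2
  fam <- row$family
  if (fam != "fixed" && v == 0) fam <- "fixed"
  d <- switch(
    fam,
    fixed = list(family = "fixed", mean = m, sd = 0),
    uniform = list(
      family = "uniform", min = row$low, max = row$high,
      mean = (row$low + row$high) / 2,
      sd = (row$high - row$low) / sqrt(12)
    ),
    beta = {
      if (m <= 0 || m >= 1) {
        stop("beta moment matching requires base in (0, 1) for ", name)
      }
      k <- m * (1 - m) / v - 1
      if (k <= 0) stop("beta variance too large for base value of ", name)
      list(family = "beta", shape1 = m * k, shape2 = (1 - m) * k, mean = m, sd = sdv)
    },
    gamma = {
      if (m <= 0) stop("gamma moment matching requires base > 0 for ", name)
      list(family = "gamma", shape = m^2 / v, scale = v / m, mean = m, sd = sdv)
    }
  )
  structure(c(d, list(name = row$name)), class = "cea_dist")
}

#' @export
print.cea_dist <- function(x, ...) {
  pars <- setdiff(names(x), c("family", "mean", "sd", "name"))
  cat("<cea_dist> ", x$name, ": ", x$family, "(",
      paste(sprintf("%s = %.4g", pars, unlist(x[pars])), collapse = ", "),
      "), mean = ", signif(x$mean, 4), ", sd = ", signif(x$sd, 4), "\n", sep = "")
  invisible(x)
}

#' Draw random variates from a fitted sampling distribution
#'
#' @param dist A `cea_dist` from [fit_sampling_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(dist, n) {
  stopifnot(inherits(dist, "cea_dist"), n >= 0)
  switch(
    dist$family,
    fixed = rep(dist$mean, n),
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale)
  )
}

#' Sample complete parameter sets for probabilistic sensitivity analysis
#'
#' Draws each parameter independently from its fitted sampling
#' distribution. Draws are reproducible given `seed`; probabilities and
#' utilities are clipped to `[0, 1]` after sampling.
#'
#' @param params Parameter table.
#' @param n Number of complete draws (rows).
#' @param seed Optional integer seed; when given, the current RNG state is
#'   preserved and restored.
#' @return A tibble with `n` rows, one column per parameter, plus `.draw`.
#' @examples
#' sample_parameter_set(default_parameters(), n = 3, seed = 42)
#' @export
sample_parameter_set <- function(params, n = 1, seed = NULL) {
  validate_parameters(params)
  draw_all <- function() {
    cols <- lapply(params$name, function(nm) {
      d <- fit_sampling_distribution(params, nm)
      x <- sample_dist(d, n)
      role <- params$role[match(nm, params$name)]
      if (role %in% c("probability", "utility")) x <- pmin(pmax(x, 0), 1)
      x
    })
    names(cols) <- params$name
    tibble::as_tibble(c(list(.draw = seq_len(n)), cols))
  }
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}

#' Base-case parameter draw
#'
#' The deterministic "draw" in which every parameter sits at its base
#' value; used by the base-case analysis and as the centre of the one-way
#' sensitivity analysis.
#'
#' @param params Parameter table.
#' @return A named numeric vector.
#' @export
base_case_draw <- function(params) {
  validate_parameters(params)
  stats::setNames(params$value, params$name)
}

# Coerce a draw (named vector or one-row data frame) to a named vector.
.as_draw <- function(draw) {
  if (is.data.frame(draw)) {
    stopifnot(nrow(draw) == 1)
    draw <- draw[setdiff(names(draw), ".draw")]
    return(unlist(draw))
  }
  stopifnot(is.numeric(draw), !is.null(names(draw)))
  draw
}
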