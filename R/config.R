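#' Configuration of the simulated multi-region population
#'
#' Parameterizes the synthetic world that the cohort generator draws from:
#' region structure, study years, sex-specific outcome rate schedules, the
#' true individual-level logistic model, the event processes behind the
#' lookback-window predictors, and the case-control sampling design.
#'
#' The defaults describe the study conditions the package targets: 18 health
#' regions with strong between-region rate variation, yearly suicide rates of
#' roughly 27 declining to 20 per 100,000 in males over 2002--2019 and a
#' stable 6.5 per 100,000 in females, binary lookback predictors at 3--60
#' month windows, and a 1% control sampling fraction.
#'
#' @param n_persons Number of simulated persons (closed cohort).
#' @param n_regions Number of health regions (default 18).
#' @param years Inclusive vector of study years (default 2002:2019).
#' @param sex_mix Proportion of males, in \[0, 1\].
#' @param baseline_rate_by_sex_year Data frame with columns `year`, `male`,
#'   `female`: target yearly suicide rates per 100,000 by sex. Defaults to a
#'   linear male decline from 27 to 20 per 100,000 across `years` and a
#'   constant 6.5 per 100,000 in females.
#' @param true_coefficients Named list with elements `male` and `female`,
#'   each a named numeric vector of population-scale coefficients including
#'   an `"(Intercept)"` entry. Names follow the canonical predictor naming
#'   convention (`<event_type>_<window>m` for lookback indicators).
#' @param calibrate_intercept If `TRUE` (default) the per-sex-year intercept
#'   is solved so that the population marginal outcome rate matches
#'   `baseline_rate_by_sex_year`; if `FALSE` the supplied `"(Intercept)"` is
#'   used as-is for every year.
#' @param event_process_params Data frame with columns `event_type`,
#'   `base_logit`, `severity_loading`: the yearly occurrence probability of
#'   an event of each type for person *i* is
#'   `inv_logit(base_logit + severity_loading * z_i)` where `z_i` is the
#'   person's latent severity.
#' @param region_effects List with per-region vectors (each length
#'   `n_regions`): `severity_shift` (mean latent severity, the
#'   covariate-mediated region effect), `intercept_offset` (additive logit
#'   offset, default zeros), `population_share` (relative region sizes,
#'   normalized internally), `budget_base` (regional per-capita mental
#'   health budget in currency units).
#' @param missingness_rates Named numeric vector of per-variable missingness
#'   fractions injected at feature-building time; defaults lie in
#'   \[0.0087, 0.0412\].
#' @param control_fraction Fraction of living non-cases sampled as controls
#'   each year, in (0, 1\]; default 0.01.
#' @param seed Integer seed governing all generation randomness.
#'
#' @return An object of class `population_config` (a validated list).
#' @seealso [generate_population()]
#' @export
population_config <- function(n_persons = 200000L,
                              n_regions = 18L,
                              years = 2002:2019,
                              sex_mix = 0.49,
                              baseline_rate_by_sex_year = NULL,
                              true_coefficients = NULL,
                              calibrate_intercept = TRUE,
                              event_process_params = NULL,
                              region_effects = NULL,
                              missingness_rates = NULL,
                              control_fraction = 0.01,
                              seed = 1L) {
  n_persons <- as.integer(n_persons)
  n_regions <- as.integer(n_regions)
  years <- as.integer(years)
  if (length(years) < 1L || any(diff(years) != 1L)) {
    rr_stop("'years' must be a consecutive inclusive year range")
  }
  if (!is_scalar_number(sex_mix) || sex_mix < 0 || sex_mix > 1) {
    rr_stop("'sex_mix' must lie in [0, 1]")
  }
  if (!is_scalar_number(control_fraction) ||
      control_fraction <= 0 || control_fraction > 1) {
    rr_stop("'control_fraction' must lie in (0, 1]")
  }
  if (n_persons < 1L) rr_stop("'n_persons' must be positive")
  if (n_regions < 1L) rr_stop("'n_regions' must be positive")

  if (is.null(baseline_rate_by_sex_year)) {
    baseline_rate_by_sex_year <- data.frame(
      year = years,
      male = seq(27, 20, length.out = length(years)),
      female = rep(6.5, length(years))
    )
  }
  stopifnot(all(c("year", "male", "female") %in% names(baseline_rate_by_sex_year)))
  if (any(baseline_rate_by_sex_year$male < 0) ||
      any(baseline_rate_by_sex_year$female < 0)) {
    rr_stop("outcome rates must be nonnegative")
  }
  if (!all(years %in% baseline_rate_by_sex_year$year)) {
    rr_stop("baseline_rate_by_sex_year must cover every study year")
  }

  if (is.null(true_coefficients)) {
    true_coefficients <- list(
      male = c(
        "(Intercept)" = -4.85,
        age = 0.01,
        charlson = 0.11,
        regional_budget = -0.001,
        suicide_attempt_hosp_60m = 1.88,
        er_physical_3m = 1.00,
        psychiatrist_mh_60m = 0.67,
        gp_physical_60m = -0.15,
        mood_anxiety_60m = 0.99,
        substance_use_60m = 0.89
      ),
      female = c(
        "(Intercept)" = -6.47,
        age = 0.0,
        suicide_attempt_hosp_60m = 1.85,
        er_mental_60m = 1.13,
        psychiatrist_mh_60m = 0.66,
        mood_anxiety_12m = 1.05,
        substance_use_60m = 0.84
      )
    )
  }
  for (sx in c("male", "female")) {
    cf <- true_coefficients[[sx]]
    if (is.null(cf) || !"(Intercept)" %in% names(cf)) {
      rr_stop(sprintf("true_coefficients$%s must include an \"(Intercept)\" entry", sx))
    }
    if (anyDuplicated(names(cf))) rr_stop("duplicate coefficient names")
  }

  if (is.null(event_process_params)) {
    event_process_params <- data.frame(
      event_type = c("suicide_attempt_hosp", "er_physical", "er_mental",
                     "psychiatrist_mh", "gp_physical", "mood_anxiety",
                     "substance_use", "respiratory"),
      base_logit = c(-6.5, -1.1, -3.8, -3.6, 0.0, -2.5, -3.6, -2.6),
      severity_loading = c(1.2, 0.3, 1.0, 1.1, 0.1, 1.0, 0.9, 0.4)
    )
  }
  stopifnot(all(c("event_type", "base_logit", "severity_loading") %in%
                  names(event_process_params)))

  if (is.null(region_effects)) {
    region_effects <- default_region_effects(n_regions)
  }
  for (nm in c("severity_shift", "intercept_offset", "population_share",
               "budget_base")) {
    if (is.null(region_effects[[nm]])) {
      region_effects[[nm]] <- if (nm == "population_share") {
        rep(1 / n_regions, n_regions)
      } else if (nm == "budget_base") {
        rep(300, n_regions)
      } else {
        rep(0, n_regions)
      }
    }
    if (length(region_effects[[nm]]) != n_regions) {
      rr_stop(sprintf("region_effects$%s must have length n_regions", nm))
    }
  }
  region_effects$population_share <-
    region_effects$population_share / sum(region_effects$population_share)

  if (is.null(missingness_rates)) {
    missingness_rates <- c(
      deprivation_social = 0.0412,
      deprivation_material = 0.0412,
      charlson = 0.0087
    )
  }
  if (any(missingness_rates < 0 | missingness_rates >= 1)) {
    rr_stop("missingness rates must lie in [0, 1)")
  }

  cfg <- structure(list(
    n_persons = n_persons,
    n_regions = n_regions,
    years = years,
    sex_mix = sex_mix,
    baseline_rate_by_sex_year = baseline_rate_by_sex_year,
    true_coefficients = true_coefficients,
    calibrate_intercept = isTRUE(calibrate_intercept),
    event_process_params = event_process_params,
    region_effects = region_effects,
    missingness_rates = missingness_rates,
    control_fraction = control_fraction,
    seed = as.integer(seed)
  ), class = "population_config")
  cfg
}

# Default regional structure: two large urban regions, a pack of mid-sized
# regions with modest severity differences, and a tier of small remote
# regions with strongly elevated latent severity. The severity gradient is
# covariate-mediated (it shifts event-process intensities), which is what
# lets an individual-level model explain the regional rate variation.
default_region_effects <- function(n_regions) {
  if (n_regions == 18L) {
    severity <- c(seq(-0.40, 0.40, length.out = 13), 1.0, 1.4, 1.9, 2.5, 3.2)
    share <- c(0.22, 0.12, rep(0.0475, 11), 0.030, 0.025, 0.020, 0.015, 0.012)
    budget <- 300 + 25 * severity  # higher-need regions budget more
  } else {
    severity <- seq(-0.5, 1.5, length.out = n_regions)
    share <- rep(1 / n_regions, n_regions)
    budget <- 300 + 25 * severity
  }
  list(
    severity_shift = severity,
    intercept_offset = rep(0, n_regions),
    population_share = share / sum(share),
    budget_base = budget
  )
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config>\n")
  cat(sprintf("  persons: %d in %d regions, years %d-%d, %.0f%% male\n",
              x$n_persons, x$n_regions, min(x$years), max(x$years),
              100 * x$sex_mix))
  cat(sprintf("  control fraction: %.3f; seed: %d\n",
              x$control_fraction, x$seed))
  cat(sprintf("  true predictors: male %d, female %d (+ intercept)\n",
              length(x$true_coefficients$male) - 1L,
              length(x$true_coefficients$female) - 1L))
  invisible(x)
}
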