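# internal: map model coefficient names onto feature definitions.
# Canonical names: "<event_type>_<w>m" (lookback indicator), a continuous
# panel/budget column (age, charlson, regional_budget), or an ordinal dummy
# "<var>_<level>" over the deprivation quintiles.
resolve_predictors <- function(names, event_types) {
  windows <- list(); continuous <- character(); ordinal <- character()
  for (nm in names) {
    w <- parse_window_name(nm)
    if (!is.null(w) && w$event_type %in% event_types) {
      windows[[nm]] <- window_spec(w$event_type, w$window_months)
    } else if (nm %in% c("age", "charlson", "regional_budget")) {
      continuous <- c(continuous, nm)
    } else if (grepl("^(deprivation_social|deprivation_material)_[0-9]$", nm)) {
      ordinal <- c(ordinal, sub("_[0-9]$", "", nm))
    } else {
      rr_stop(sprintf("cannot resolve predictor '%s' against the panel", nm))
    }
  }
  list(windows = windows, continuous = unique(continuous),
       ordinal = unique(ordinal))
}

# internal: per-person feature matrix for the aggregation population of a
# given year and sex, evaluated at the common December 31 reference date.
population_features <- function(panel, model, year, sex) {
  keep <- panel$panel[["year"]] == year &
    as.character(panel$panel[["sex"]]) == sex
  rows <- panel$panel[keep]
  if (nrow(rows) == 0L) {
    rr_stop(sprintf("no eligible persons for sex '%s' in year %d", sex, year))
  }
  rows <- merge(rows, panel$budget, by = c("region_id", "year"), all.x = TRUE)
  rows[, index_date := year_end_date(year)]
  need <- resolve_predictors(names(model$coefficients),
                             levels(panel$events$event_type))
  fm <- build_feature_matrix(list(data = rows, events = panel$events),
                             window_specs = unname(need$windows),
                             continuous = need$continuous,
                             ordinal = need$ordinal)
  missing_cols <- setdiff(names(model$coefficients), names(fm))
  if (length(missing_cols)) {
    rr_stop(sprintf("predictors not derivable for the population: %s",
                    paste(missing_cols, collapse = ", ")))
  }
  list(rows = rows, features = fm)
}

#' Aggregate model predictors into region-level profiles
#'
#' The first stage of model-based synthetic estimation: for each health
#' region, each binary predictor of the model becomes the within-region
#' proportion of persons with the attribute, and each continuous predictor
#' becomes the within-region mean. Lookback windows are evaluated at a
#' common December 31 reference date for everyone in the aggregation
#' population (the full simulated population of that region-year, not the
#' case-control sample).
#'
#' @param panel A `person_panel`.
#' @param model A `model_spec` whose coefficient names are canonical
#'   predictor names.
#' @param year Calendar year to aggregate.
#' @param sex `"male"` or `"female"`.
#' @return A `region_profile` data frame: `region_id`, `year`, `sex`,
#'   `population_count`, then one column per model predictor.
#' @export
aggregate_region_profile <- function(panel, model, year, sex) {
  stopifnot(inherits(panel, "person_panel"), inherits(model, "model_spec"))
  pf <- population_features(panel, model, year, sex)
  preds <- names(model$coefficients)
  dt <- data.table::as.data.table(
    pf$features[, preds, drop = FALSE])
  dt[, region_id := pf$rows$region_id]
  agg <- dt[, c(list(population_count = .N), lapply(.SD, mean)),
            by = region_id, .SDcols = preds]
  all_regions <- seq_len(panel$config$n_regions)
  absent <- setdiff(all_regions, agg$region_id)
  if (length(absent)) {
    rr_stop(sprintf("regions with zero eligible persons: %s",
                    paste(absent, collapse = ", ")))
  }
  data.table::setorder(agg, region_id)
  out <- data.frame(region_id = agg$region_id, year = year, sex = sex,
                    population_count = agg$population_count,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(agg[, ..preds], check.names = FALSE))
  class(out) <- c("region_profile", "data.frame")
  out
}

#' Correct a case-control intercept to the population scale
#'
#' A design including all cases and a fraction f of non-cases inflates the
#' logistic intercept by ln(1/f) while leaving slopes unbiased; this shifts
#' the intercept by ln(f) so that predicted probabilities live on the
#' population scale, as required before synthetic estimation of per-100,000
#' rates. With f = 1 the model is returned unchanged; a model already on
#' the population scale is not corrected twice.
#'
#' @param model A `model_spec` with its `control_fraction` recorded.
#' @return The corrected `model_spec` (`scale = "population"`, the applied
#'   offset stored in `correction_log`).
#' @export
intercept_correction <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  f <- model$control_fraction
  if (!is_scalar_number(f) || f <= 0 || f > 1) {
    rr_stop("control sampling fraction must lie in (0, 1]")
  }
  if (identical(model$scale, "population")) return(model)
  model$intercept <- model$intercept + log(f)
  model$scale <- "population"
  model$correction_log <- sprintf(
    "intercept shifted by ln(%g) = %.4f (case-control -> population scale)",
    f, log(f))
  model
}

#' Predict the regional risk from an aggregated profile
#'
#' The second stage of synthetic estimation: applies the model coefficients
#' to the region-level proportions and means, yielding a logit per region,
#' converts it to a probability, and scales to a rate per 100,000.
#'
#' @param profile A `region_profile` from [aggregate_region_profile()].
#' @param model A `model_spec`; its coefficient names must match the
#'   profile's aggregate columns exactly. If the model is still on the
#'   case-control scale a message notes that [intercept_correction()] has
#'   not been applied.
#' @return A `region_estimate` data frame: `region_id`, `year`, `sex`,
#'   `logit`, `probability`, `rate_per_100k`.
#' @export
predict_region <- function(profile, model) {
  stopifnot(inherits(model, "model_spec"))
  preds <- names(model$coefficients)
  have <- setdiff(names(profile),
                  c("region_id", "year", "sex", "population_count"))
  missing_nm <- setdiff(preds, have)
  extra_nm <- setdiff(have, preds)
  if (length(missing_nm) || length(extra_nm)) {
    rr_stop(sprintf(
      "profile/model predictor mismatch; missing: [%s], extra: [%s]",
      paste(missing_nm, collapse = ", "), paste(extra_nm, collapse = ", ")))
  }
  if (!identical(model$scale, "population")) {
    message("predict_region: model is on the case-control scale; ",
            "intercept_correction() has not been applied")
  }
  xmat <- as.matrix(as.data.frame(profile)[, preds, drop = FALSE])
  eta <- as.numeric(model$intercept + xmat %*% model$coefficients)
  p <- inv_logit(eta)
  out <- data.frame(region_id = profile$region_id, year = profile$year,
                    sex = profile$sex, logit = eta, probability = p,
                    rate_per_100k = p * 1e5)
  class(out) <- c("region_estimate", "data.frame")
  out
}

#' Quantify the aggregation (Jensen) gap of synthetic estimation
#'
#' Synthetic estimation evaluates the inverse-logit at the mean covariates;
#' the exact regional risk is the mean of the individual inverse-logits.
#' This diagnostic reports both, and their difference, for one region. The
#' gap is zero for a degenerate region (identical individuals) and shrinks
#' toward zero as the slopes shrink.
#'
#' @param panel A `person_panel`.
#' @param model A `model_spec` on the population scale.
#' @param region Region identifier.
#' @param year,sex Aggregation year and sex.
#' @return List with `mean_individual_probability`,
#'   `probability_at_mean_covariates`, `gap` (former minus latter).
#' @export
jensen_gap_diagnostic <- function(panel, model, region, year, sex) {
  pf <- population_features(panel, model, year, sex)
  keep <- pf$rows$region_id == region
  if (!any(keep)) rr_stop(sprintf("region %s has no eligible persons", region))
  xmat <- as.matrix(as.data.frame(pf$features)[keep,
                    names(model$coefficients), drop = FALSE])
  eta_i <- as.numeric(model$intercept + xmat %*% model$coefficients)
  mean_p <- mean(inv_logit(eta_i))
  p_at_mean <- inv_logit(model$intercept +
                           sum(colMeans(xmat) * model$coefficients))
  list(mean_individual_probability = mean_p,
       probability_at_mean_covariates = p_at_mean,
       gap = mean_p - p_at_mean)
}
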