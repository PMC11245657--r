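#' Observed suicide rates per 100,000
#'
#' Outcome counts over the living population, per year and sex, optionally
#' per region. The denominator is the simulated population present in the
#' region-year (persons dying that year are counted in the denominator of
#' that year).
#'
#' @param panel A `person_panel`.
#' @param years Years to report (default: all panel years).
#' @param sexes Sexes to report (default both).
#' @param by_region If `TRUE`, rates per region; otherwise provincial.
#' @return Data frame with `year`, `sex`, optionally `region_id`, plus
#'   `cases`, `population`, `rate_per_100k`.
#' @export
observed_rates <- function(panel, years = NULL, sexes = c("male", "female"),
                           by_region = FALSE) {
  stopifnot(inherits(panel, "person_panel"))
  pp <- panel$panel
  if (is.null(years)) years <- sort(unique(pp$year))
  keep <- pp$year %in% years & pp$sex %in% sexes
  pp <- pp[keep]
  by_cols <- c("year", "sex", if (by_region) "region_id")
  agg <- pp[, .(cases = sum(outcome), population = .N), by = by_cols]
  if (nrow(agg) == 0L || any(agg$population == 0L)) {
    rr_stop("zero population in a reporting cell")
  }
  agg[, rate_per_100k := cases / population * 1e5]
  data.table::setorderv(agg, by_cols)
  out <- as.data.frame(agg)
  out$sex <- as.character(out$sex)
  out
}

#' Subgroup validation of a synthetic estimation model
#'
#' Compares observed and synthetic-model-predicted rates within population
#' subgroups (age bands, or health regions) for one year and sex, the
#' fairness check applied to the most recent validation year.
#'
#' @param panel A `person_panel`.
#' @param model A population-scale `model_spec`.
#' @param groups Either the string `"region"`, or a list of inclusive age
#'   bands, e.g. `list(c(15, 39), c(40, 59), c(60, Inf))`. Age bands must
#'   not overlap.
#' @param year Calendar year.
#' @param sex `"male"` or `"female"`.
#' @return Data frame: `group`, `population`, `observed_per_100k`,
#'   `predicted_per_100k`, `abs_diff_per_100k`. Empty groups are flagged
#'   with `NA` rates rather than an error.
#' @export
subgroup_validation <- function(panel, model, groups, year, sex) {
  stopifnot(inherits(panel, "person_panel"), inherits(model, "model_spec"))
  pf <- population_features(panel, model, year, sex)
  rows <- pf$rows
  if (identical(groups, "region")) {
    ids <- sort(unique(rows$region_id))
    masks <- lapply(ids, function(r) rows$region_id == r)
    labels <- as.character(ids)
  } else {
    bands <- groups
    lo <- vapply(bands, `[`, numeric(1), 1)
    hi <- vapply(bands, `[`, numeric(1), 2)
    ord <- order(lo)
    if (any(lo[ord][-1] <= hi[ord][-length(hi)])) {
      rr_stop("age bands must be disjoint")
    }
    masks <- lapply(bands, function(b) rows$age >= b[1] & rows$age <= b[2])
    labels <- vapply(bands, function(b)
      if (is.finite(b[2])) sprintf("%g-%g", b[1], b[2])
      else sprintf(">=%g", b[1]), character(1))
  }
  xmat <- as.matrix(as.data.frame(pf$features)[, names(model$coefficients),
                                               drop = FALSE])
  res <- lapply(seq_along(masks), function(i) {
    mk <- masks[[i]]
    if (!any(mk)) {
      return(data.frame(group = labels[i], population = 0L,
                        observed_per_100k = NA_real_,
                        predicted_per_100k = NA_real_,
                        abs_diff_per_100k = NA_real_))
    }
    obs <- sum(rows$outcome[mk]) / sum(mk) * 1e5
    eta <- model$intercept + sum(colMeans(xmat[mk, , drop = FALSE]) *
                                   model$coefficients)
    prd <- inv_logit(eta) * 1e5
    data.frame(group = labels[i], population = sum(mk),
               observed_per_100k = obs, predicted_per_100k = prd,
               abs_diff_per_100k = abs(prd - obs))
  })
  do.call(rbind, res)
}

#' Year-by-year performance report of the synthetic estimation models
#'
#' Applies the (population-scale) sex-specific models to every year of the
#' development and validation panels: per year and sex it aggregates
#' region profiles, predicts regional rates, and scores them against the
#' observed rates with MAE, RMSE and the top-k high-risk overlap. Also
#' tabulates provincial observed versus predicted yearly rates per 100,000.
#'
#' @param panel_train,panel_valid `person_panel` objects for the two
#'   periods (either may be `NULL` to skip).
#' @param models Named list with population-scale `model_spec`s `male` and
#'   `female`.
#' @param k Top-k size for high-risk region identification (default 5).
#' @param unit Unit for MAE/RMSE: `"per_1000"` (default) or `"per_100k"`.
#' @return An `eval_report`: list with `metrics` (period, year, sex, MAE,
#'   RMSE, top-k overlap), `yearly` (provincial observed vs predicted per
#'   100,000 and absolute differences), `regional` (per region-year-sex
#'   observed and predicted rates), and `unit`.
#' @export
yearly_report <- function(panel_train, panel_valid, models, k = 5L,
                          unit = c("per_1000", "per_100k")) {
  unit <- match.arg(unit)
  if (!all(c("male", "female") %in% names(models))) {
    rr_stop("'models' must contain elements 'male' and 'female'")
  }
  scale_div <- if (unit == "per_1000") 100 else 1
  panels <- list(development = panel_train, validation = panel_valid)
  metrics <- list(); yearly <- list(); regional <- list()
  for (period in names(panels)) {
    pan <- panels[[period]]
    if (is.null(pan)) next
    for (yr in sort(unique(pan$panel$year))) {
      for (sx in c("male", "female")) {
        model <- models[[sx]]
        prof <- aggregate_region_profile(pan, model, yr, sx)
        est <- suppressMessages(predict_region(prof, model))
        obs <- observed_rates(pan, years = yr, sexes = sx, by_region = TRUE)
        stopifnot(identical(est$region_id, obs$region_id))
        prd_v <- stats::setNames(est$rate_per_100k, est$region_id)
        obs_v <- stats::setNames(obs$rate_per_100k, obs$region_id)
        metrics[[length(metrics) + 1L]] <- data.frame(
          period = period, year = yr, sex = sx,
          mae = mae(prd_v / scale_div, obs_v / scale_div),
          rmse = rmse(prd_v / scale_div, obs_v / scale_div),
          top_k_overlap = top_k_overlap(prd_v, obs_v, k = k))
        pop <- obs$population
        prov_obs <- sum(obs$cases) / sum(pop) * 1e5
        prov_prd <- sum(prd_v * pop) / sum(pop)
        yearly[[length(yearly) + 1L]] <- data.frame(
          period = period, year = yr, sex = sx,
          observed_per_100k = prov_obs, predicted_per_100k = prov_prd,
          abs_diff_per_100k = abs(prov_prd - prov_obs))
        regional[[length(regional) + 1L]] <- data.frame(
          period = period, year = yr, sex = sx, region_id = est$region_id,
          observed_per_100k = obs_v, predicted_per_100k = unname(prd_v),
          abs_diff_per_100k = abs(unname(prd_v) - obs_v))
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 yearly = do.call(rbind, yearly),
                 regional = do.call(rbind, regional),
                 unit = unit, k = as.integer(k)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> MAE/RMSE unit: %s; top-%d overlap\n",
              x$unit, x$k))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
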