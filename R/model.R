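#' Screen candidate predictors with LASSO-penalized logistic regression
#'
#' Fits an L1-penalized logistic regression over a penalty grid, chooses the
#' penalty by cross-validated binomial deviance (unless one is supplied),
#' and returns the predictors with nonzero coefficients at that penalty.
#' Predictors are standardized internally; reported coefficients are on the
#' original scale.
#'
#' @param matrix A `feature_matrix` (or data frame) with no missing values.
#' @param outcome Binary outcome vector aligned with the rows.
#' @param penalty Optional fixed penalty (lambda). When `NULL` (default) the
#'   penalty minimizing cross-validated deviance is used.
#' @param nfolds Folds for cross-validation (default 10).
#' @param seed Seed for the fold assignment (default 1).
#' @return An object of class `lasso_screen`: list with `selected`
#'   (character), `coefficients` (named, original scale, nonzero only),
#'   `penalty`, and the underlying `glmnet`/`cv.glmnet` fit.
#' @export
lasso_screen <- function(matrix, outcome, penalty = NULL, nfolds = 10L,
                         seed = 1L) {
  x <- as.matrix(as.data.frame(matrix, check.names = FALSE))
  if (ncol(x) < 2L) rr_stop("LASSO screening needs at least 2 predictors")
  if (anyNA(x)) rr_stop("resolve missing values before screening")
  y <- as.numeric(outcome)
  if (length(y) != nrow(x)) rr_stop("outcome length mismatch")
  if (length(unique(y)) < 2L) {
    rr_stop("degenerate outcome: all 0 or all 1")
  }
  if (is.null(penalty)) {
    set.seed(as.integer(seed))
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial",
                               type.measure = "deviance", nfolds = nfolds)
    penalty <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", thresh = 1e-12)
    cvfit <- NULL
    cf <- as.matrix(stats::coef(fit, s = penalty, exact = TRUE, x = x, y = y,
                                thresh = 1e-12))
  }
  cfv <- cf[, 1]
  nz <- cfv[names(cfv) != "(Intercept)" & cfv != 0]
  structure(list(selected = names(nz), coefficients = nz,
                 intercept = cfv[["(Intercept)"]],
                 penalty = penalty, fit = fit, cv = cvfit),
            class = "lasso_screen")
}

#' @export
print.lasso_screen <- function(x, ...) {
  cat(sprintf("<lasso_screen> penalty %.4g: %d predictors retained\n",
              x$penalty, length(x$selected)))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Flag strongly correlated predictor pairs and resolve them
#'
#' Computes absolute Pearson correlations (the phi coefficient for binary
#' pairs) among the selected columns and flags every unordered pair at or
#' above the threshold. One member of each flagged pair is dropped according
#' to a priority ordering — the stand-in for subject-matter judgment about
#' policy and clinical utility: of a flagged pair, the member appearing
#' earlier in `priority` is kept. Constant columns, whose correlation is
#' undefined, are reported separately and retained.
#'
#' @param matrix A `feature_matrix` or data frame.
#' @param selected Columns to consider (default: all).
#' @param threshold Absolute correlation threshold (default 0.60).
#' @param priority Character vector ranking predictors from most to least
#'   preferred; defaults to the order of `selected`.
#' @return List with `flagged` (data frame `var1`, `var2`, `correlation`),
#'   `retained` (character), `dropped` (character), `undefined` (constant
#'   columns).
#' @export
correlation_filter <- function(matrix, selected = NULL, threshold = 0.60,
                               priority = NULL) {
  m <- as.data.frame(matrix, check.names = FALSE)
  if (is.null(selected)) selected <- names(m)
  if (!all(selected %in% names(m))) {
    rr_stop("'selected' must be a subset of the matrix columns")
  }
  if (is.null(priority)) priority <- selected
  m <- m[, selected, drop = FALSE]
  sds <- vapply(m, function(col) stats::sd(col, na.rm = TRUE), numeric(1))
  undefined <- names(sds)[is.na(sds) | sds == 0]
  usable <- setdiff(selected, undefined)
  flagged <- data.frame(var1 = character(), var2 = character(),
                        correlation = numeric())
  dropped <- character()
  if (length(usable) >= 2L) {
    cm <- suppressWarnings(
      stats::cor(m[, usable, drop = FALSE], use = "pairwise.complete.obs"))
    pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      flagged <- data.frame(
        var1 = usable[pairs[, 1]], var2 = usable[pairs[, 2]],
        correlation = cm[pairs])
      flagged <- flagged[order(-abs(flagged$correlation)), , drop = FALSE]
      rownames(flagged) <- NULL
      rank_of <- function(v) match(v, priority, nomatch = length(priority) + 1L)
      for (i in seq_len(nrow(flagged))) {
        a <- flagged$var1[i]; b <- flagged$var2[i]
        if (a %in% dropped || b %in% dropped) next
        dropped <- c(dropped, if (rank_of(a) <= rank_of(b)) b else a)
      }
    }
  }
  list(flagged = flagged, retained = setdiff(selected, dropped),
       dropped = dropped, undefined = undefined)
}

#' Fit a sex-specific logistic model by maximum likelihood
#'
#' Fits `outcome ~ predictors` with [stats::glm()]. Constant predictors are
#' dropped with a warning; apparent complete separation (non-convergence
#' with runaway coefficients or degenerate fitted probabilities) raises an
#' error naming the worst predictor. Discrimination (C statistic with
#' DeLong interval), calibration (Brier score, decile calibration bins) and
#' Wald p-values are computed on the training rows.
#'
#' @param matrix A `feature_matrix` (or data frame) with no missing values
#'   among the used columns.
#' @param outcome Binary outcome aligned with the rows.
#' @param predictors Columns to use (default: all). May be empty for an
#'   intercept-only fit.
#' @param sex Optional label (`"male"`/`"female"`) stored in the model.
#' @param control_fraction Control sampling fraction f of the design that
#'   produced the rows (default 1): needed later for intercept correction.
#' @param training_period Optional length-2 year range stored as metadata.
#' @return A `model_spec`: list with `sex`, `intercept`, `coefficients`
#'   (named, excluding the intercept), `se`, `p_values`, `odds_ratios`,
#'   `control_fraction`, `scale` (`"case_control"`; becomes `"population"`
#'   after [intercept_correction()]), `training_period`, `aic`, `bic`,
#'   `diagnostics` (C statistic, Brier score, calibration bins), and
#'   `selection_trace` (populated by [backward_select()]).
#' @export
fit_logistic <- function(matrix, outcome, predictors = NULL, sex = NA_character_,
                         control_fraction = 1, training_period = NULL) {
  m <- as.data.frame(matrix, check.names = FALSE)
  if (is.null(predictors)) predictors <- names(m)
  if (!all(predictors %in% names(m))) {
    rr_stop(sprintf("unknown predictors: %s",
                    paste(setdiff(predictors, names(m)), collapse = ", ")))
  }
  y <- as.numeric(outcome)
  if (length(y) != nrow(m)) rr_stop("outcome length mismatch")
  dat <- m[, predictors, drop = FALSE]
  if (anyNA(dat)) rr_stop("resolve missing values before fitting")

  const <- names(dat)[vapply(dat, function(v) length(unique(v)) == 1L, logical(1))]
  if (length(const)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(const, collapse = ", ")), call. = FALSE)
    predictors <- setdiff(predictors, const)
    dat <- dat[, predictors, drop = FALSE]
  }
  dat$.y <- y
  fml <- if (length(predictors)) {
    stats::reformulate(sprintf("`%s`", predictors), response = ".y")
  } else {
    .y ~ 1
  }
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  cf <- stats::coef(fit)
  if (!fit$converged || any(abs(cf[-1]) > 15) ||
      all(fit$fitted.values > 1 - 1e-8) || all(fit$fitted.values < 1e-8)) {
    worst <- if (length(cf) > 1L) names(which.max(abs(cf[-1]))) else "(Intercept)"
    rr_stop(sprintf(
      "fit failed (possible complete separation); worst predictor: %s",
      gsub("`", "", worst)), class = "regionrisk_separation_error")
  }
  sm <- summary(fit)$coefficients
  nms <- gsub("`", "", rownames(sm))
  slopes <- stats::setNames(sm[, "Estimate"], nms)
  ses <- stats::setNames(sm[, "Std. Error"], nms)
  pvs <- stats::setNames(sm[, "Pr(>|z|)"], nms)
  keep <- setdiff(nms, "(Intercept)")

  p_hat <- unname(fit$fitted.values)
  diag <- if (any(y == 1) && any(y == 0)) {
    list(
      c_statistic = c_statistic(p_hat[y == 1], p_hat[y == 0]),
      brier = brier_score(p_hat, y),
      calibration = calibration_bins(p_hat, y,
                                     n_bins = max(2L, min(10L, length(y))))
    )
  } else {
    NULL
  }

  structure(list(
    sex = sex,
    intercept = unname(slopes[["(Intercept)"]]),
    coefficients = slopes[keep],
    se = ses[c("(Intercept)", keep)],
    p_values = pvs[c("(Intercept)", keep)],
    odds_ratios = exp(slopes[keep]),
    control_fraction = control_fraction,
    scale = "case_control",
    training_period = training_period,
    aic = stats::AIC(fit),
    bic = stats::BIC(fit),
    n = length(y),
    diagnostics = diag,
    selection_trace = NULL
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, digits = 3, ...) {
  cat(sprintf("<model_spec> sex: %s; scale: %s; f = %g; n = %s\n",
              x$sex, x$scale, x$control_fraction,
              format(x$n %||% NA, big.mark = ",")))
  if (!is.null(x$training_period)) {
    cat(sprintf("  training period: %d-%d\n",
                min(x$training_period), max(x$training_period)))
  }
  tab <- data.frame(
    coefficient = round(c(x$intercept, x$coefficients), digits),
    odds_ratio = c(NA, round(exp(x$coefficients), 2)),
    row.names = c("(Intercept)", names(x$coefficients)))
  print(tab)
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  C = %.3f (%.3f-%.3f), Brier = %.4g\n",
                x$diagnostics$c_statistic$c_statistic,
                x$diagnostics$c_statistic$ci_lower,
                x$diagnostics$c_statistic$ci_upper,
                x$diagnostics$brier))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Backward elimination by information criterion
#'
#' Starting from `start_set`, repeatedly removes the predictor whose removal
#' most decreases the chosen criterion, stopping when no removal improves
#' it. The accepted-step criterion sequence is non-increasing by
#' construction; the full trace (including AIC and BIC at every accepted
#' step) is stored in the returned model's `selection_trace`.
#'
#' @param matrix A `feature_matrix` or data frame without missing values.
#' @param outcome Binary outcome vector.
#' @param start_set Nonempty character vector of starting predictors.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param ... Passed to [fit_logistic()] (`sex`, `control_fraction`,
#'   `training_period`).
#' @return The final `model_spec` with `selection_trace` filled in.
#' @export
backward_select <- function(matrix, outcome, start_set,
                            criterion = c("AIC", "BIC"), ...) {
  criterion <- match.arg(criterion)
  if (length(start_set) == 0L) rr_stop("'start_set' must be nonempty")
  crit_of <- function(ms) if (criterion == "AIC") ms$aic else ms$bic
  current <- suppressWarnings(
    fit_logistic(matrix, outcome, predictors = start_set, ...))
  kept <- names(current$coefficients)
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      aic = current$aic, bic = current$bic,
                      criterion = crit_of(current),
                      n_predictors = length(kept))
  step <- 0L
  repeat {
    if (length(kept) == 0L) break
    cand <- lapply(kept, function(v) {
      suppressWarnings(
        fit_logistic(matrix, outcome, predictors = setdiff(kept, v), ...))
    })
    crits <- vapply(cand, crit_of, numeric(1))
    best <- which.min(crits)
    if (crits[best] >= crit_of(current)) break
    step <- step + 1L
    dropped_var <- kept[best]
    current <- cand[[best]]
    kept <- setdiff(kept, dropped_var)
    trace <- rbind(trace, data.frame(
      step = step, dropped = dropped_var, aic = current$aic,
      bic = current$bic, criterion = crit_of(current),
      n_predictors = length(kept)))
  }
  current$selection_trace <- trace
  current$selection_criterion <- criterion
  current
}
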