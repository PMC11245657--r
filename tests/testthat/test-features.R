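hist1 <- function(...) {
  data.frame(event_type = "er_visit", event_date = as.Date(c(...)))
}

test_that("window indicators respect the half-open lookback interval", {
  idx <- as.Date("2010-12-31")
  # event 2 months before the index, 3-month window
  expect_equal(derive_window_indicator(hist1("2010-11-01"), idx,
                                       window_spec("er_visit", 3)), 1L)
  # event 61 months before the index, 60-month window
  expect_equal(derive_window_indicator(hist1("2005-11-15"), idx,
                                       window_spec("er_visit", 60)), 0L)
  # events 5 and 50 months back against windows 3/6/60
  h <- hist1("2010-07-31", "2006-10-31")
  got <- vapply(c(3, 6, 60), function(w)
    derive_window_indicator(h, idx, window_spec("er_visit", w)), integer(1))
  expect_equal(got, c(0L, 1L, 1L))
  # boundary: event on the index date is in; event at the lower bound is out
  expect_equal(derive_window_indicator(hist1("2010-12-31"), idx,
                                       window_spec("er_visit", 3)), 1L)
  expect_equal(derive_window_indicator(hist1("2010-09-30"), idx,
                                       window_spec("er_visit", 3)), 0L)
  # empty history
  empty <- data.frame(event_type = character(), event_date = as.Date(character()))
  expect_equal(derive_window_indicator(empty, idx,
                                       window_spec("er_visit", 12)), 0L)
  expect_error(derive_window_indicator(hist1("2010-11-01"), idx,
                                       window_spec("typo", 3),
                                       known_types = "er_visit"),
               "unknown event type")
  expect_error(window_spec("er_visit", 7), "window_months")
})

test_that("window indicators are monotone in window width", {
  set.seed(31)
  idx <- as.Date("2010-06-15")
  widths <- c(3, 6, 12, 24, 36, 48, 60)
  for (i in 1:40) {
    h <- hist1(as.Date("2004-01-01") + sample.int(2500, sample.int(6, 1)))
    ind <- vapply(widths, function(w)
      derive_window_indicator(h, idx, window_spec("er_visit", w)), integer(1))
    expect_true(all(diff(ind) >= 0))
  }
})

test_that("quantile groups follow reference cut points and clamp extremes", {
  # self-quantiling gives near-equal groups
  set.seed(7)
  x <- rnorm(1000)
  g <- assign_quantile_groups(x, 5, x)
  expect_true(max(abs(table(g) - 200)) <= 1)
  # below-reference scores clamp to group 1
  expect_equal(assign_quantile_groups(-10, 5, x), 1L)
  expect_equal(assign_quantile_groups(1e6, 5, x), 5L)
  # brute-force cut points: norms 1..100, score 51 lands in group 3 of 5
  expect_equal(assign_quantile_groups(51, 5, 1:100), 3L)
  # order isomorphism
  s <- sort(runif(100))
  expect_true(all(diff(assign_quantile_groups(s, 4, s)) >= 0))
  expect_error(assign_quantile_groups(numeric(0), 5, 1:10), "nonempty")
})

test_that("feature matrices align with the sample and record missingness", {
  p <- small_world()
  cc <- sample_case_control(p)
  specs <- list(window_spec("mood_anxiety", 12), window_spec("mood_anxiety", 60),
                window_spec("suicide_attempt_hosp", 60))
  fm <- build_feature_matrix(cc, window_specs = specs,
                             continuous = c("age", "charlson"),
                             ordinal = "deprivation_material")
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), nrow(cc$data))
  expect_true(all(c("mood_anxiety_12m", "mood_anxiety_60m", "age",
                    "deprivation_material_2") %in% names(fm)))
  expect_true(all(unlist(fm[, c("mood_anxiety_12m", "mood_anxiety_60m")]) %in% 0:1))
  # monotone nesting of windows on real histories
  expect_true(all(fm$mood_anxiety_12m <= fm$mood_anxiety_60m))
  # a person with no events of a type scores 0
  no_ev <- setdiff(cc$data$person_id,
                   p$events$person_id[p$events$event_type == "mood_anxiety"])
  if (length(no_ev)) {
    expect_true(all(fm$mood_anxiety_60m[cc$data$person_id %in% no_ev] == 0))
  }
  # derivation is pure
  fm2 <- build_feature_matrix(cc, window_specs = specs,
                              continuous = c("age", "charlson"),
                              ordinal = "deprivation_material")
  expect_identical(as.data.frame(fm), as.data.frame(fm2))
  # duplicate predictor names are rejected
  expect_error(build_feature_matrix(cc, window_specs = list(specs[[1]], specs[[1]])),
               "duplicate")
})

test_that("injected missingness hits the configured fraction", {
  p <- small_world()
  cc <- sample_case_control(p)
  n <- nrow(cc$data)
  fm <- build_feature_matrix(cc, continuous = c("age", "charlson"),
                             missing_rates = c(charlson = 0.04), seed = 11L)
  n_miss <- sum(is.na(fm$charlson))
  expect_true(n_miss >= qbinom(0.005, n, 0.04) & n_miss <= qbinom(0.995, n, 0.04))
  expect_equal(sum(is.na(fm$age)), 0L)
  expect_equal(attr(fm, "mask")[, "charlson"], is.na(fm$charlson))
})

test_that("missingness handling drops or imputes as requested", {
  m <- data.frame(a = c(1, 3, NA, 4), b = c(0L, 1L, 1L, NA))
  fm <- structure(m, mask = is.na(as.matrix(m)),
                  col_type = c(a = "continuous", b = "binary"),
                  class = c("feature_matrix", "data.frame"))
  ccres <- handle_missing(fm, "complete-case")
  expect_equal(nrow(ccres), 2L)
  expect_equal(attr(ccres, "kept_rows"), c(1L, 2L))
  imp <- handle_missing(fm, "impute")
  expect_equal(nrow(imp), 4L)
  expect_equal(imp$a[3], mean(c(1, 3, 4)))  # mean imputation
  expect_equal(imp$b[4], 1)                 # mode imputation
  expect_equal(attr(imp, "n_imputed"), 2L)
  # identity when nothing is missing
  full <- structure(data.frame(a = 1:3), mask = matrix(FALSE, 3, 1),
                    col_type = c(a = "continuous"),
                    class = c("feature_matrix", "data.frame"))
  expect_equal(handle_missing(full, "complete-case")$a, 1:3)
  expect_equal(nrow(handle_missing(full, "impute")), 3L)
  expect_error(handle_missing(fm, "oracle"), "arg")
})
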