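test_that("intercept correction shifts by ln(f) and is idempotent", {
  m <- manual_model(-1.5, c(age = 0.01), control_fraction = 1,
                    scale = "case_control")
  expect_equal(intercept_correction(m)$intercept, -1.5)  # f = 1 identity
  m2 <- manual_model(-1.5, c(age = 0.01), control_fraction = 0.01,
                     scale = "case_control")
  c2 <- intercept_correction(m2)
  expect_equal(c2$intercept, -1.5 - log(100))
  expect_equal(c2$scale, "population")
  expect_equal(intercept_correction(c2)$intercept, c2$intercept)  # idempotent
  m3 <- manual_model(-1.5, c(age = 0.01), control_fraction = 2)
  expect_error(intercept_correction(m3), "0, 1")
})

test_that("regional prediction applies coefficients to aggregates", {
  prof <- data.frame(region_id = 1:3, year = 2019, sex = "male",
                     population_count = c(10, 20, 30),
                     attempt = c(0.5, 0.1, 0))
  class(prof) <- c("region_profile", "data.frame")
  # all slopes zero: every region at inv_logit(-4.85)
  m0 <- manual_model(-4.85, c(attempt = 0))
  est0 <- predict_region(prof, m0)
  expect_equal(est0$probability, rep(inv_logit(-4.85), 3))
  expect_equal(est0$rate_per_100k, est0$probability * 1e5)
  # one predictor at proportion 0.5 with coefficient 1.88
  m1 <- manual_model(-4.85, c(attempt = 1.88))
  est1 <- predict_region(prof, m1)
  expect_equal(est1$logit[1], -4.85 + 1.88 * 0.5)
  expect_equal(est1$probability[1], inv_logit(-3.91), tolerance = 1e-12)
  # monotonicity in a positive-coefficient aggregate
  expect_true(est1$probability[1] > est1$probability[2])
  expect_true(est1$probability[2] > est1$probability[3])
  # name mismatches are reported with the offending names
  bad <- manual_model(-4.85, c(nope = 1))
  expect_error(predict_region(prof, bad), "nope")
  # a case-control-scale model triggers a message
  mc <- manual_model(-4.85, c(attempt = 1.88), scale = "case_control")
  expect_message(predict_region(prof, mc), "intercept_correction")
})

test_that("degenerate regions make the synthetic estimate exactly individual", {
  pan <- degenerate_panel(region_ages = c(30, 50), year = 2005)
  m <- manual_model(-6, c(age = 0.04), sex = "male")
  prof <- aggregate_region_profile(pan, m, 2005, "male")
  expect_equal(prof$age, c(30, 50))
  expect_equal(prof$population_count, c(4L, 4L))
  est <- predict_region(prof, m)
  # micro-oracle: identical individuals => estimate == individual prediction
  expect_identical(est$probability, inv_logit(-6 + 0.04 * c(30, 50)))
  gap <- jensen_gap_diagnostic(pan, m, 1, 2005, "male")
  expect_identical(gap$gap, 0)
})

test_that("the Jensen gap matches hand computation and vanishes with slopes", {
  # two-person region, binary predictor values 0 and 1, beta = 2, b0 = -2
  ev <- data.table::data.table(
    person_id = 2L, event_type = factor("crisis"),
    event_date = as.Date("2005-06-01"))
  pan <- degenerate_panel(region_ages = c(40), year = 2005, events = ev)
  pan$panel <- pan$panel[pan$panel$person_id %in% 1:2 & pan$panel$sex == "male", ]
  m <- manual_model(-2, c(crisis_60m = 2), sex = "male")
  gap <- jensen_gap_diagnostic(pan, m, 1, 2005, "male")
  expect_equal(gap$mean_individual_probability,
               mean(c(inv_logit(-2), inv_logit(0))))
  expect_equal(gap$probability_at_mean_covariates, inv_logit(-1))
  expect_equal(gap$gap, mean(c(inv_logit(-2), inv_logit(0))) - inv_logit(-1),
               tolerance = 1e-12)
  expect_equal(round(gap$gap, 4), 0.0407)
  # slope scaling: gap decreases to 0 as slopes shrink
  gaps <- vapply(c(1, 0.1, 0.01), function(eps) {
    me <- manual_model(-2, c(crisis_60m = 2 * eps), sex = "male")
    abs(jensen_gap_diagnostic(pan, me, 1, 2005, "male")$gap)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-5)
})

test_that("synthetic estimates respect sub-stratum aggregation linearity", {
  # splitting a region into strata and recombining aggregates by population
  # weight reproduces the whole-region profile exactly
  p <- small_world()
  m <- manual_model(-7, c(age = 0.02, mood_anxiety_60m = 1), sex = "male")
  prof <- aggregate_region_profile(p, m, 2004, "male")
  rows <- p$panel[p$panel$year == 2004 & p$panel$sex == "male" &
                    p$panel$region_id == 1, ]
  stratum <- rows$person_id %% 2 == 0
  sub <- function(mask) {
    pan2 <- p
    pan2$panel <- rows[mask, ]
    pan2$config$n_regions <- 1L
    aggregate_region_profile(pan2, m, 2004, "male")
  }
  p1 <- sub(stratum); p2 <- sub(!stratum)
  w <- c(p1$population_count, p2$population_count)
  recombined <- (p1$age * w[1] + p2$age * w[2]) / sum(w)
  expect_equal(recombined, prof$age[prof$region_id == 1], tolerance = 1e-12)
  rec_mood <- (p1$mood_anxiety_60m * w[1] + p2$mood_anxiety_60m * w[2]) / sum(w)
  expect_equal(rec_mood, prof$mood_anxiety_60m[prof$region_id == 1],
               tolerance = 1e-12)
})

test_that("aggregation errors on empty regions and unresolvable names", {
  pan <- degenerate_panel(region_ages = c(30, 50))
  pan$panel <- pan$panel[pan$panel$region_id == 1, ]  # region 2 now empty
  m <- manual_model(-6, c(age = 0.04), sex = "male")
  expect_error(aggregate_region_profile(pan, m, 2005, "male"), "zero eligible")
  m2 <- manual_model(-6, c(mystery_var = 1), sex = "male")
  pan2 <- degenerate_panel(region_ages = c(30, 50))
  expect_error(aggregate_region_profile(pan2, m2, 2005, "male"),
               "cannot resolve")
})
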