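# Small simulated worlds shared across test files. Built lazily once per
# test run; every builder is deterministic given its seed.

.world_cache <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.world_cache$small)) {
    cfg <- population_config(n_persons = 20000L, years = 2002:2006, seed = 42L)
    .world_cache$small <- generate_population(cfg)
  }
  .world_cache$small
}

# a hand-built panel: every person in a region shares identical covariates,
# so regional aggregates equal individual covariate vectors exactly
degenerate_panel <- function(region_ages = c(30, 50), year = 2005L,
                             sexes = c("male", "female"),
                             events = NULL, outcomes = NULL) {
  n_regions <- length(region_ages)
  per_region <- 4L
  rows <- list()
  pid <- 0L
  for (sx in sexes) {
    for (r in seq_len(n_regions)) {
      for (i in seq_len(per_region)) {
        pid <- pid + 1L
        rows[[pid]] <- data.frame(
          person_id = pid, year = year, sex = sx, age = region_ages[r],
          region_id = r, deprivation_social = 3L, deprivation_material = 3L,
          charlson = 0L, outcome = 0L)
      }
    }
  }
  panel <- data.table::as.data.table(do.call(rbind, rows))
  panel[, sex := factor(sex, levels = c("male", "female"))]
  if (!is.null(outcomes)) panel$outcome <- outcomes
  if (is.null(events)) {
    events <- data.table::data.table(
      person_id = integer(), event_type = factor(character()),
      event_date = as.Date(character()))
  }
  budget <- data.table::CJ(region_id = seq_len(n_regions), year = year)
  budget[, regional_budget := 300]
  cfg <- population_config(n_persons = pid, n_regions = n_regions,
                           years = year, seed = 1L)
  structure(list(panel = panel, events = events, budget = budget,
                 config = cfg,
                 true_intercepts = data.frame(year = year,
                                              sex = sexes,
                                              intercept = NA_real_)),
            class = "person_panel")
}

# minimal model_spec constructor for metric/estimation tests
manual_model <- function(intercept, coefficients, sex = "male",
                         control_fraction = 1, scale = "population") {
  structure(list(sex = sex, intercept = intercept,
                 coefficients = coefficients,
                 control_fraction = control_fraction, scale = scale,
                 training_period = NULL, selection_trace = NULL),
            class = "model_spec")
}
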