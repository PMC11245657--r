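#' Generate a multi-year, multi-region population with event histories
#'
#' Simulates a closed cohort aged 15 and over distributed across health
#' regions. Each person carries a latent severity factor (normal, with a
#' region-specific mean shift) that drives the yearly occurrence of every
#' event type, inducing both the between-predictor correlation and the
#' covariate-mediated regional variation in outcome rates. Event histories
#' are dated; lookback predictors are derived from them with the features
#' module. Outcomes are assessed once per year at a December 31 reference
#' date from the configured true logistic model; a person's first outcome
#' year terminates their panel. Event histories start five years before the
#' first study year so that 60-month windows are fully observed from year
#' one.
#'
#' When `calibrate_intercept` is set (the default), the per-sex-year
#' intercept is solved numerically so the population marginal outcome rate
#' matches the configured per-100,000 schedule; the solved intercepts are
#' stored in the returned object (`$true_intercepts`).
#'
#' @param config A [population_config()].
#' @return An object of class `person_panel`: a list with elements
#'   `panel` (person-year rows: `person_id`, `year`, `sex`, `age`,
#'   `region_id`, `deprivation_social`, `deprivation_material`, `charlson`,
#'   `outcome`), `events` (long table `person_id`, `event_type`,
#'   `event_date`), `budget` (region-year `regional_budget` lookup),
#'   `config`, and `true_intercepts`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config")) {
    rr_stop("'config' must be a population_config")
  }
  set.seed(config$seed)
  n <- config$n_persons
  years <- config$years
  re <- config$region_effects

  # persons
  region_id <- sample.int(config$n_regions, n, replace = TRUE,
                          prob = re$population_share)
  sex <- factor(ifelse(stats::runif(n) < config$sex_mix, "male", "female"),
                levels = c("male", "female"))
  age0 <- sample(15:90, n, replace = TRUE,
                 prob = c(rep(1, 45), seq(1, 0.3, length.out = 31)))
  z <- stats::rnorm(n, mean = re$severity_shift[region_id], sd = 1)
  dep_soc_score <- 0.30 * re$severity_shift[region_id] + stats::rnorm(n)
  dep_mat_score <- 0.35 * re$severity_shift[region_id] + stats::rnorm(n)
  deprivation_social <- assign_quantile_groups(dep_soc_score, 5L, dep_soc_score)
  deprivation_material <- assign_quantile_groups(dep_mat_score, 5L, dep_mat_score)
  charlson <- stats::rpois(n, lambda = 0.05 + 0.012 * (age0 - 15))

  # dated event histories over a 5-year burn-in plus the study years
  event_years <- (min(years) - 5L):max(years)
  ny_ev <- length(event_years)
  ep <- config$event_process_params
  ev_list <- vector("list", nrow(ep))
  for (k in seq_len(nrow(ep))) {
    p_k <- inv_logit(ep$base_logit[k] + ep$severity_loading[k] * z)
    hit <- stats::runif(n * ny_ev) < rep(p_k, times = ny_ev)
    idx <- which(hit)
    if (length(idx) == 0L) next
    pid <- ((idx - 1L) %% n) + 1L
    yr <- event_years[((idx - 1L) %/% n) + 1L]
    uy <- sort(unique(yr))
    ys_u <- as.Date(paste0(uy, "-01-01"))
    nd_u <- 365L + as.integer((uy %% 4 == 0 & uy %% 100 != 0) | uy %% 400 == 0)
    mi <- match(yr, uy)
    date <- ys_u[mi] + floor(stats::runif(length(idx)) * nd_u[mi])
    ev_list[[k]] <- data.table::data.table(
      person_id = pid, event_type = ep$event_type[k], event_date = date)
  }
  events <- data.table::rbindlist(ev_list)
  rm(ev_list)
  events[, event_type := factor(event_type, levels = ep$event_type)]
  data.table::setkey(events, person_id, event_type, event_date)

  # region-year budget (deterministic given config)
  budget <- data.table::CJ(region_id = seq_len(config$n_regions), year = years)
  budget[, regional_budget := re$budget_base[region_id] + 2 * (year - min(years))]

  # person-year grid
  ny <- length(years)
  panel <- data.table::data.table(
    person_id = rep(seq_len(n), times = ny),
    year = rep(years, each = n),
    sex = rep(sex, times = ny),
    age = rep(age0, times = ny) + rep(years - min(years), each = n),
    region_id = rep(region_id, times = ny),
    deprivation_social = rep(deprivation_social, times = ny),
    deprivation_material = rep(deprivation_material, times = ny),
    charlson = rep(charlson, times = ny)
  )

  # true linear predictor (slope part) at the Dec 31 reference of each year
  ref_date <- year_end_date(panel$year)
  eta <- numeric(nrow(panel))
  budget_vec <- budget[panel, on = c("region_id", "year"), regional_budget]
  for (sx in c("male", "female")) {
    rows <- which(panel$sex == sx)
    cf <- config$true_coefficients[[sx]]
    slopes <- cf[setdiff(names(cf), "(Intercept)")]
    acc <- numeric(length(rows))
    for (nm in names(slopes)) {
      b <- slopes[[nm]]
      if (b == 0) next
      w <- parse_window_name(nm)
      xv <- if (!is.null(w) && w$event_type %in% ep$event_type) {
        window_indicator_bulk(events, panel$person_id[rows], ref_date[rows],
                              w$event_type, w$window_months)
      } else if (nm == "age") {
        panel$age[rows]
      } else if (nm == "charlson") {
        panel$charlson[rows]
      } else if (nm == "regional_budget") {
        budget_vec[rows]
      } else if (grepl("^deprivation_(social|material)_[0-9]$", nm)) {
        v <- sub("_[0-9]$", "", nm)
        lv <- as.integer(sub("^.*_", "", nm))
        as.integer(panel[[v]][rows] == lv)
      } else {
        rr_stop(sprintf("true coefficient '%s' has no generating rule", nm))
      }
      acc <- acc + b * xv
    }
    eta[rows] <- acc
  }
  eta <- eta + re$intercept_offset[panel$region_id]

  # intercept per sex-year: calibrated to the rate schedule, or fixed
  sched <- config$baseline_rate_by_sex_year
  b0 <- matrix(NA_real_, nrow = ny, ncol = 2,
               dimnames = list(as.character(years), c("male", "female")))
  for (sx in c("male", "female")) {
    for (yi in seq_along(years)) {
      target <- sched[[sx]][match(years[yi], sched$year)] / 1e5
      rows <- which(panel$sex == sx & panel$year == years[yi])
      if (!config$calibrate_intercept || length(rows) == 0L) {
        b0[yi, sx] <- config$true_coefficients[[sx]][["(Intercept)"]]
      } else if (target <= 0) {
        b0[yi, sx] <- -Inf
      } else {
        e <- eta[rows]
        f <- function(b) mean(inv_logit(b + e)) - target
        b0[yi, sx] <- stats::uniroot(f, c(-30, 5), tol = 1e-10)$root
      }
    }
  }
  p_out <- inv_logit(b0[cbind(match(panel$year, years),
                              as.integer(panel$sex))] + eta)
  rm(eta, budget_vec, ref_date); gc(FALSE)
  draw <- stats::runif(nrow(panel)) < p_out
  rm(p_out)
  panel[, outcome := 0L]
  panel[draw, outcome := 1L]
  rm(draw)

  # first outcome year terminates the panel
  case_year <- panel[outcome == 1L, .(death_year = min(year)), by = person_id]
  panel <- merge(panel, case_year, by = "person_id", all.x = TRUE)
  panel <- panel[is.na(death_year) | year <= death_year]
  panel[!is.na(death_year) & year < death_year, outcome := 0L]
  panel[, death_year := NULL]
  data.table::setkey(panel, person_id, year)

  # events after a case's outcome year never exist (the person is dead)
  cy <- panel[outcome == 1L, .(person_id, death_year = year)]
  events[, ev_year := data.table::year(event_date)]
  events <- merge(events, cy, by = "person_id", all.x = TRUE)
  events <- events[is.na(death_year) | ev_year <= death_year]
  events[, c("ev_year", "death_year") := NULL]
  data.table::setkey(events, person_id, event_type, event_date)

  structure(list(panel = panel, events = events, budget = budget,
                 config = config,
                 true_intercepts = data.frame(
                   year = rep(years, 2),
                   sex = rep(c("male", "female"), each = ny),
                   intercept = c(b0[, "male"], b0[, "female"]))),
            class = "person_panel")
}

#' @export
print.person_panel <- function(x, ...) {
  cat("<person_panel>\n")
  cat(sprintf("  %s person-years (%s persons), years %d-%d, %d regions\n",
              format(nrow(x$panel), big.mark = ","),
              format(data.table::uniqueN(x$panel$person_id), big.mark = ","),
              min(x$panel$year), max(x$panel$year),
              x$config$n_regions))
  cat(sprintf("  %s dated events of %d types; %d outcome events\n",
              format(nrow(x$events), big.mark = ","),
              nlevels(x$events$event_type), sum(x$panel$outcome)))
  invisible(x)
}

#' Draw the case-control sample from a simulated panel
#'
#' Keeps every outcome row in the year range as a case (index date: the
#' December 31 reference date of the outcome year) and samples each living
#' non-case person within each year with probability `control_fraction`.
#' A person can serve as a control at most once across the whole range;
#' controls receive a uniformly random index date within their sampling
#' year.
#'
#' @param panel A `person_panel`.
#' @param year_range Length-2 inclusive year range; defaults to the panel's
#'   full range.
#' @param control_fraction Per-year sampling probability in (0, 1\];
#'   defaults to the panel config's value.
#' @param seed Seed for the control draw; defaults to the panel config's
#'   seed plus one so generation and sampling use distinct streams.
#' @return A `case_control_sample`: list with `data` (one row per subject:
#'   panel covariates plus `role`, `outcome`, `sampling_year`,
#'   `index_date`, `regional_budget`), `events`, `budget`, and `config`.
#' @export
sample_case_control <- function(panel, year_range = NULL,
                                control_fraction = NULL, seed = NULL) {
  stopifnot(inherits(panel, "person_panel"))
  if (is.null(year_range)) year_range <- range(panel$panel$year)
  if (is.null(control_fraction)) control_fraction <- panel$config$control_fraction
  if (is.null(seed)) seed <- panel$config$seed + 1L
  if (!is_scalar_number(control_fraction) || control_fraction <= 0 ||
      control_fraction > 1) {
    rr_stop("'control_fraction' must lie in (0, 1]")
  }
  yrs <- sort(as.integer(year_range))
  pyears <- range(panel$panel$year)
  if (yrs[1] < pyears[1] || yrs[2] > pyears[2]) {
    rr_stop("'year_range' must lie within the panel's years")
  }
  set.seed(as.integer(seed))
  pp <- panel$panel

  cases <- pp[outcome == 1L & year >= yrs[1] & year <= yrs[2]]
  cases[, `:=`(role = "case", sampling_year = year,
               index_date = year_end_date(year))]

  picked <- integer(0)
  ctrl_list <- list()
  log_rows <- list()
  for (y in yrs[1]:yrs[2]) {
    eligible <- pp[year == y & outcome == 0L]
    if (length(picked)) eligible <- eligible[!person_id %in% picked]
    sel <- stats::runif(nrow(eligible)) < control_fraction
    chosen <- eligible[sel]
    log_rows[[as.character(y)]] <- data.frame(
      year = y, eligible = nrow(eligible), selected = nrow(chosen))
    if (nrow(chosen) == 0L) next
    ystart <- as.Date(paste0(y, "-01-01"))
    yend <- as.Date(paste0(y, "-12-31"))
    chosen[, `:=`(role = "control", sampling_year = y,
                  index_date = ystart +
                    floor(stats::runif(.N) * (as.integer(yend - ystart) + 1L)))]
    picked <- c(picked, chosen$person_id)
    ctrl_list[[as.character(y)]] <- chosen
  }
  controls <- data.table::rbindlist(ctrl_list)
  out <- data.table::rbindlist(list(cases, controls), use.names = TRUE)
  out <- merge(out, panel$budget, by = c("region_id", "year"), all.x = TRUE)
  data.table::setorder(out, sampling_year, person_id)
  structure(list(data = out, events = panel$events, budget = panel$budget,
                 config = panel$config,
                 sampling_log = do.call(rbind, log_rows),
                 control_fraction = control_fraction),
            class = "case_control_sample")
}

#' @export
print.case_control_sample <- function(x, ...) {
  tab <- table(x$data$role)
  cat(sprintf("<case_control_sample> %d cases, %d controls, years %d-%d\n",
              tab[["case"]], tab[["control"]],
              min(x$data$sampling_year), max(x$data$sampling_year)))
  invisible(x)
}

#' Split a panel into training and validation periods by year
#'
#' @param panel A `person_panel`.
#' @param split_year First year of the validation period; must lie strictly
#'   inside the panel's year range so that neither side is empty.
#' @return List with `train` (years before `split_year`) and `validation`
#'   (years from `split_year` on), both `person_panel` objects sharing the
#'   full event table so lookback windows remain observable.
#' @export
split_train_validation <- function(panel, split_year) {
  stopifnot(inherits(panel, "person_panel"))
  yrs <- range(panel$panel$year)
  split_year <- as.integer(split_year)
  if (split_year <= yrs[1] || split_year > yrs[2]) {
    rr_stop("'split_year' must lie strictly inside the panel's year range")
  }
  subset_panel <- function(keep_years) {
    cfg <- panel$config
    cfg$years <- keep_years
    structure(list(panel = panel$panel[year %in% keep_years],
                   events = panel$events,
                   budget = panel$budget[year %in% keep_years],
                   config = cfg,
                   true_intercepts =
                     panel$true_intercepts[panel$true_intercepts$year %in%
                                             keep_years, ]),
              class = "person_panel")
  }
  list(train = subset_panel(yrs[1]:(split_year - 1L)),
       validation = subset_panel(split_year:yrs[2]))
}
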