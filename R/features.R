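#' Lookback-window predictor specification
#'
#' A window spec names an event type and a lookback width in months; the
#' derived predictor is the binary indicator that at least one event of that
#' type occurred in the half-open interval `(index_date - window, index_date]`.
#' The canonical predictor name is `"<event_type>_<window>m"`.
#'
#' @param event_type Character scalar naming the event type.
#' @param window_months Lookback width in months; one of 3, 6, 12, 24, 36,
#'   48, 60.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(event_type, window_months) {
  stopifnot(is.character(event_type), length(event_type) == 1L)
  window_months <- as.integer(window_months)
  if (!window_months %in% c(3L, 6L, 12L, 24L, 36L, 48L, 60L)) {
    rr_stop("'window_months' must be one of 3, 6, 12, 24, 36, 48, 60")
  }
  structure(list(event_type = event_type, window_months = window_months,
                 name = paste0(event_type, "_", window_months, "m")),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s (events of type '%s' in past %d months)\n",
              x$name, x$event_type, x$window_months))
  invisible(x)
}

# internal: month period for calendar arithmetic with end-of-month rollback
months_period <- function(n) lubridate::period(month = n)

# internal: parse canonical window-predictor names back into specs
parse_window_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)_([0-9]+)m$", name))[[1]]
  if (length(m) != 3L) return(NULL)
  list(event_type = m[2], window_months = as.integer(m[3]))
}

#' Derive a single lookback-window indicator
#'
#' Returns 1 if at least one event of the spec's type occurred in
#' `(index_date - window_months, index_date]`, else 0. The window is
#' half-open so that an event exactly at the lower boundary is excluded and
#' an event on the index date is included; month arithmetic rolls back
#' impossible dates (e.g. Dec 31 minus 3 months is Sep 30).
#'
#' @param history Data frame of dated events with columns `event_type` and
#'   `event_date` (Date); may have zero rows.
#' @param index_date Reference date (Date scalar).
#' @param spec A [window_spec()].
#' @param known_types Optional character vector of valid event types; if
#'   supplied and the spec's type is not among them, an error is raised.
#' @return 0 or 1.
#' @export
derive_window_indicator <- function(history, index_date, spec,
                                    known_types = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  if (!is.null(known_types) && !spec$event_type %in% known_types) {
    rr_stop(sprintf("unknown event type '%s'", spec$event_type))
  }
  index_date <- as.Date(index_date)
  if (length(index_date) != 1L || is.na(index_date)) {
    rr_stop("'index_date' must be a single non-missing date")
  }
  if (is.null(history) || nrow(history) == 0L) return(0L)
  lower <- index_date %m-% months_period(spec$window_months)
  dates <- as.Date(history$event_date[history$event_type == spec$event_type])
  as.integer(any(dates > lower & dates <= index_date))
}

# internal: vectorized window indicator over many (person, index_date) rows.
# events: data.table(person_id, event_type, event_date); keys: data.table
# with person_id and index_date. Returns integer 0/1 vector aligned to keys.
window_indicator_bulk <- function(events, person_id, index_date,
                                  event_type, window_months) {
  mask <- as.character(events[["event_type"]]) == event_type
  ev <- events[mask, c("person_id", "event_date"), with = FALSE]
  n <- length(person_id)
  if (nrow(ev) == 0L) return(integer(n))
  data.table::setkey(ev, person_id, event_date)
  # month arithmetic on unique dates only (index dates repeat heavily);
  # match on the numeric day count, not Date (Date match formats to character)
  idx_num <- as.numeric(index_date)
  ud <- unique(idx_num)
  lb_u <- as.numeric(as.Date(ud, origin = "1970-01-01") %m-%
                       months_period(window_months))
  keys <- data.table::data.table(
    person_id = person_id,
    lb = lb_u[match(idx_num, ud)],
    ub = idx_num
  )
  ev[, d := as.numeric(event_date)]
  hit <- ev[keys, on = .(person_id, d > lb, d <= ub),
            mult = "first", which = TRUE]
  ev[, d := NULL]
  as.integer(!is.na(hit))
}

#' Map scores to quantile groups against a reference distribution
#'
#' Assigns each score to one of `n_groups` ordered groups using cut points
#' from the reference distribution (`norms`), the way deprivation scores are
#' grouped against population norms. Group 1 holds the lowest scores (most
#' privileged for a deprivation index); scores outside the reference range
#' are clamped to the extreme groups.
#'
#' @param scores Numeric vector to classify.
#' @param n_groups Number of groups (default 5).
#' @param norms Numeric reference distribution supplying the cut points.
#' @return Integer vector of group labels in 1..n_groups.
#' @export
assign_quantile_groups <- function(scores, n_groups = 5L, norms = scores) {
  if (length(scores) == 0L) rr_stop("'scores' must be nonempty")
  norms <- norms[!is.na(norms)]
  if (length(norms) == 0L) rr_stop("'norms' must be nonempty")
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L) rr_stop("'n_groups' must be at least 2")
  cuts <- stats::quantile(norms, probs = seq_len(n_groups - 1L) / n_groups,
                          names = FALSE, type = 7)
  out <- findInterval(scores, cuts) + 1L
  out[out > n_groups] <- n_groups
  out[is.na(scores)] <- NA_integer_
  out
}

#' Build the predictor matrix for a case-control sample
#'
#' Derives one column per requested predictor, aligned row-for-row with the
#' sample: lookback-window indicators (from each row's own index date),
#' continuous covariates and ordinal covariates expanded into dummy columns
#' for levels 2 and up (level 1 is the reference). Missing values may be
#' injected per column at configured rates; all missingness is recorded in
#' the matrix's logical mask attribute.
#'
#' @param sample A `case_control_sample` (from [sample_case_control()]), or
#'   any list with a `data` data frame (one row per subject, including
#'   `person_id` and `index_date`) and an `events` table.
#' @param window_specs List of [window_spec()] objects.
#' @param continuous Character vector of continuous covariate columns to copy
#'   from `sample$data`.
#' @param ordinal Character vector of ordinal covariate columns (integer
#'   levels starting at 1) to expand into dummies named `<var>_<level>`.
#' @param missing_rates Optional named numeric vector: fraction of entries to
#'   set missing in the named columns (canonical predictor names).
#' @param seed Seed for missingness injection (required when `missing_rates`
#'   is supplied, so derivation stays reproducible).
#' @return A `feature_matrix`: a data frame with attributes `mask` (logical
#'   missingness matrix) and `col_type` (named character vector among
#'   `"binary"`, `"ordinal"`, `"continuous"`).
#' @export
build_feature_matrix <- function(sample, window_specs = list(),
                                 continuous = character(),
                                 ordinal = character(),
                                 missing_rates = NULL, seed = NULL) {
  dat <- if (is.data.frame(sample)) sample else sample$data
  events <- if (is.data.frame(sample)) NULL else sample$events
  if (length(window_specs) > 0L && is.null(events)) {
    rr_stop("window specs require an event table in 'sample'")
  }
  if (length(window_specs) + length(continuous) + length(ordinal) == 0L) {
    rr_stop("at least one predictor spec is required")
  }
  n <- nrow(dat)
  if (!is.null(missing_rates)) {
    if (is.null(seed)) rr_stop("'seed' is required when injecting missingness")
    set.seed(as.integer(seed))
    # ordinal sources get their missingness before dummy expansion, so all
    # dummies of one variable are missing together (one underlying record)
    for (v in intersect(names(missing_rates), ordinal)) {
      dat <- as.data.frame(dat)
      dat[[v]][stats::runif(n) < missing_rates[[v]]] <- NA
    }
  }
  cols <- list()
  types <- character()

  etypes <- if (length(window_specs) > 0L) {
    if (is.factor(events$event_type)) levels(droplevels(events$event_type))
    else unique(as.character(events$event_type))
  }
  declare <- function(nm) {
    if (nm %in% names(cols)) {
      rr_stop(sprintf("duplicate predictor names: %s", nm))
    }
    nm
  }
  for (spec in window_specs) {
    stopifnot(inherits(spec, "window_spec"))
    declare(spec$name)
    if (!spec$event_type %in% etypes) {
      # an event type with no events anywhere is fine (all zeros) only if it
      # is a declared type; with no registry we accept and return zeros
      cols[[spec$name]] <- integer(n)
    } else {
      cols[[spec$name]] <- window_indicator_bulk(
        events, dat$person_id, as.Date(dat$index_date),
        spec$event_type, spec$window_months)
    }
    types[spec$name] <- "binary"
  }
  for (v in continuous) {
    if (!v %in% names(dat)) rr_stop(sprintf("continuous covariate '%s' not found", v))
    cols[[declare(v)]] <- as.numeric(dat[[v]])
    types[v] <- "continuous"
  }
  for (v in ordinal) {
    if (!v %in% names(dat)) rr_stop(sprintf("ordinal covariate '%s' not found", v))
    lev <- sort(unique(dat[[v]][!is.na(dat[[v]])]))
    for (l in lev[lev > min(lev)]) {
      nm <- paste0(v, "_", l)
      col <- as.integer(dat[[v]] == l)
      col[is.na(dat[[v]])] <- NA_integer_
      cols[[declare(nm)]] <- col
      types[nm] <- "binary"
    }
  }
  mat <- as.data.frame(cols, check.names = FALSE, optional = TRUE)

  if (!is.null(missing_rates)) {
    for (v in setdiff(names(missing_rates), ordinal)) {
      if (!v %in% names(mat)) next
      hit <- stats::runif(n) < missing_rates[[v]]
      mat[[v]][hit] <- NA
    }
  }

  mask <- is.na(as.matrix(mat))
  structure(mat, mask = mask, col_type = types,
            class = c("feature_matrix", "data.frame"))
}

#' Resolve missing values in a feature matrix
#'
#' @param matrix A `feature_matrix`.
#' @param strategy `"complete-case"` drops every row with any missing entry;
#'   `"impute"` replaces missing continuous entries with the column mean and
#'   missing binary/ordinal entries with the column mode (ties to the
#'   smaller value).
#' @return A `feature_matrix` with no missing entries. Attribute
#'   `kept_rows` (complete-case) gives the retained row indices of the
#'   input, so outcome vectors can be subset to match; attribute
#'   `n_imputed` (impute) counts replaced cells.
#' @export
handle_missing <- function(matrix, strategy = c("complete-case", "impute")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(matrix, "feature_matrix"))
  types <- attr(matrix, "col_type")
  m <- as.data.frame(matrix, check.names = FALSE)
  if (strategy == "complete-case") {
    keep <- which(stats::complete.cases(m))
    out <- m[keep, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, mask = is.na(as.matrix(out)), col_type = types,
              kept_rows = keep, n_dropped = nrow(m) - length(keep),
              class = c("feature_matrix", "data.frame"))
  } else {
    n_imputed <- 0L
    for (v in names(m)) {
      idx <- which(is.na(m[[v]]))
      if (length(idx) == 0L) next
      n_imputed <- n_imputed + length(idx)
      if (identical(types[[v]], "continuous")) {
        m[[v]][idx] <- mean(m[[v]], na.rm = TRUE)
      } else {
        tab <- table(m[[v]])
        mode_val <- as.numeric(names(tab)[which.max(tab)])
        m[[v]][idx] <- mode_val
      }
    }
    structure(m, mask = is.na(as.matrix(m)), col_type = types,
              kept_rows = seq_len(nrow(m)), n_imputed = n_imputed,
              class = c("feature_matrix", "data.frame"))
  }
}
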