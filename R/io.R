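#' Convert a logistic coefficient to a display odds ratio
#'
#' @param coefficient Finite numeric vector of log-odds-ratio coefficients.
#' @return `exp(coefficient)` rounded to 2 decimals, the display convention
#'   of the packaged coefficient tables.
#' @export
coefficient_to_or <- function(coefficient) {
  if (!is.numeric(coefficient) || any(!is.finite(coefficient))) {
    rr_stop("'coefficient' must be finite")
  }
  round(exp(coefficient), 2)
}

# internal: normalize typographic minus signs to ASCII
normalize_minus <- function(x) {
  gsub("−|–|—", "-", x)
}

format_p_display <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.2f", p)))
}

#' Read a serialized coefficient table into a model
#'
#' The on-disk format is a comma-separated table with columns
#' `predictor,coefficient,odds_ratio,p_value`, a final `Constant` row
#' (empty odds ratio and p value), and `# key: value` metadata header lines
#' (`sex`, `training_period`, `control_fraction`, `scale`). Typographic
#' minus signs are normalized to ASCII on ingest. Display columns are kept
#' verbatim so that writing a model read from a canonical file reproduces
#' it byte for byte.
#'
#' @param path Path to the coefficient-table file.
#' @return A `model_spec`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) rr_stop(sprintf("no such file: '%s'", path))
  lines <- normalize_minus(readLines(path, encoding = "UTF-8"))
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = "character", check.names = FALSE)
  need <- c("predictor", "coefficient", "odds_ratio", "p_value")
  if (!identical(names(tab), need)) {
    rr_stop(sprintf("expected columns %s", paste(need, collapse = ",")))
  }
  dup <- tab$predictor[duplicated(tab$predictor)]
  if (length(dup)) {
    rr_stop(sprintf("duplicate predictor '%s' (line %d)",
                    dup[1], which(tab$predictor == dup[1])[2] + 1L))
  }
  coefs <- suppressWarnings(as.numeric(tab$coefficient))
  if (anyNA(coefs)) {
    bad <- which(is.na(coefs))[1]
    rr_stop(sprintf("non-numeric coefficient '%s' (line %d)",
                    tab$coefficient[bad], bad + 1L))
  }
  is_const <- tolower(tab$predictor) == "constant"
  if (sum(is_const) != 1L) {
    rr_stop("the table must contain exactly one 'Constant' row")
  }
  f <- if (!is.null(meta$control_fraction)) as.numeric(meta$control_fraction) else 1
  period <- if (!is.null(meta$training_period)) {
    as.integer(strsplit(meta$training_period, "-")[[1]])
  } else NULL
  structure(list(
    sex = meta$sex %||% NA_character_,
    intercept = coefs[is_const],
    coefficients = stats::setNames(coefs[!is_const], tab$predictor[!is_const]),
    odds_ratios = exp(coefs[!is_const]),
    control_fraction = f,
    scale = meta$scale %||% "case_control",
    training_period = period,
    table = tab,
    selection_trace = NULL
  ), class = "model_spec")
}

#' Write a model as a coefficient table
#'
#' See [read_model()] for the format. Computation always uses the
#' full-precision coefficients; the odds-ratio column is 2-decimal display
#' rounding. Writing is atomic (write-then-rename), so a partial file never
#' parses as a valid table.
#'
#' @param model A `model_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  hdr <- c(
    sprintf("# sex: %s", model$sex),
    if (!is.null(model$training_period))
      sprintf("# training_period: %d-%d",
              min(model$training_period), max(model$training_period)),
    sprintf("# control_fraction: %.15g", model$control_fraction),
    sprintf("# scale: %s", model$scale))
  if (!is.null(model$table)) {
    tab <- model$table
  } else {
    p <- model$p_values[names(model$coefficients)]
    tab <- data.frame(
      predictor = c(names(model$coefficients), "Constant"),
      coefficient = sprintf("%.15g", c(model$coefficients, model$intercept)),
      odds_ratio = c(sprintf("%.2f", coefficient_to_or(model$coefficients)), ""),
      p_value = c(if (is.null(model$p_values)) rep("", length(model$coefficients))
                  else format_p_display(p), ""),
      check.names = FALSE)
  }
  quote_field <- function(x) {
    ifelse(grepl("[,\"]", x), paste0('"', gsub('"', '""', x), '"'), x)
  }
  body <- c(paste(names(tab), collapse = ","),
            apply(tab, 1L, function(r) paste(quote_field(r), collapse = ",")))
  atomic_write_lines(c(hdr, body), path)
}

#' Load a packaged coefficient-table fixture
#'
#' The package ships the published sex-specific models as coefficient
#' tables: `"male_model_2002_2010"` (20 predictors plus constant, intercept
#' -4.85) and `"female_model_2002_2010"` (22 predictors plus constant,
#' intercept -6.47).
#'
#' @param name Fixture name.
#' @return A `model_spec`.
#' @export
load_model_fixture <- function(name = c("male_model_2002_2010",
                                        "female_model_2002_2010")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "regionrisk")
  if (path == "") rr_stop("fixture not found; is the package installed?")
  read_model(path)
}

#' Load the packaged training-data characteristics table
#'
#' Group sizes and printed percentages of the training case-control data
#' (2002-2010): cases and controls by sex, tabulated over age bands,
#' urbanicity and the two deprivation quintile variables. Percentages are
#' as printed (truncated at two decimals); counts are exact.
#'
#' @return Data frame with columns `variable`, `category`, `sex`, `group`,
#'   `count`, `pct`.
#' @export
load_training_characteristics <- function() {
  path <- system.file("extdata", "training_characteristics_2002_2010.csv",
                      package = "regionrisk")
  if (path == "") rr_stop("fixture not found; is the package installed?")
  utils::read.csv(path, check.names = FALSE)
}
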