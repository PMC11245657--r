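#' Inverse logit
#'
#' Numerically stable logistic function.
#'
#' @param x Numeric vector of log-odds.
#' @return Probabilities in \[0, 1\].
#' @export
inv_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[neg])
  out[neg] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Logit
#'
#' @param p Probabilities strictly inside (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("logit() requires probabilities strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

# internal: stop with a consistent error class so callers can test on it
rr_stop <- function(msg, class = "regionrisk_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: check scalar
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# internal: md5 of a serialized object (for run provenance logging)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# internal: vectorized Dec 31 of a year, via a unique-year lookup
year_end_date <- function(years) {
  uy <- unique(years)
  d <- as.Date(paste0(uy, "-12-31"))
  d[match(years, uy)]
}

# internal: atomic file write (write to temp in same dir, then rename)
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) rr_stop(sprintf("could not write '%s'", path))
  invisible(path)
}
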