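#' Slugify an item or group name
#'
#' Lower-cases a name and collapses every run of non-alphanumeric characters
#' to a single underscore, so that free-text food item names become stable
#' machine identifiers (e.g. "Peach/nectarine" -> "peach_nectarine").
#'
#' @param x character vector of names.
#' @return character vector of identifiers.
#' @export
slugify <- function(x) {
  out <- tolower(trimws(x))
  out <- gsub("[^a-z0-9]+", "_", out)
  gsub("^_+|_+$", "", out)
}

#' Round half away from zero
#'
#' Decimal rounding where ties are rounded away from zero (the convention of
#' printed epidemiological tables), unlike [round()] which rounds half to
#' even. `round_half_up(0.59, 1)` is 0.6 and `round_half_up(-8.2, 0)` is -8.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative: `-1` rounds to
#'   the nearest 10).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a class so callers can condition on the failure mode
hpds_error <- function(msg, class) {
  stop(structure(
    class = c(class, "hpds_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# require named columns in a data.frame input
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    hpds_error(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "hpds_schema_error"
    )
  }
  invisible(df)
}
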