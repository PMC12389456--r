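#' Quartile characteristics table
#'
#' Summarises a cohort within score quartiles the way baseline-characteristic
#' tables are printed: continuous variables as mean (SD, n-1 denominator),
#' categorical variables as N [%] of the quartile column.
#'
#' @param data data.frame holding a `quartile` column (factor or character)
#'   plus the variables to summarise.
#' @param variables columns to summarise; defaults to every column except
#'   `participant_id` and `quartile`. Numeric columns are treated as
#'   continuous, everything else as categorical.
#' @return object of class `hpds_quartile_table`: list with `n` (named
#'   per-quartile counts), `continuous` (variable, quartile, mean, sd) and
#'   `categorical` (variable, level, quartile, n, pct).
#' @export
quartile_characteristics <- function(data, variables = NULL) {
  check_columns(data, "quartile", "cohort data")
  q <- factor(data$quartile)
  if (is.null(variables)) {
    variables <- setdiff(names(data), c("participant_id", "quartile"))
  }
  n_q <- table(q)
  cont <- list(); catg <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cont[[v]] <- data.frame(
        variable = v, quartile = levels(q),
        mean = as.numeric(tapply(x, q, mean)),
        sd = as.numeric(tapply(x, q, stats::sd)),
        stringsAsFactors = FALSE
      )
    } else {
      x <- factor(x)
      tab <- table(x, q)
      pct <- prop.table(tab, margin = 2) * 100
      catg[[v]] <- data.frame(
        variable = v,
        level = rep(rownames(tab), ncol(tab)),
        quartile = rep(colnames(tab), each = nrow(tab)),
        n = as.vector(tab),
        pct = as.vector(pct),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(n = stats::setNames(as.vector(n_q), names(n_q)),
         continuous = if (length(cont)) do.call(rbind, c(cont, make.row.names = FALSE)) else NULL,
         categorical = if (length(catg)) do.call(rbind, c(catg, make.row.names = FALSE)) else NULL),
    class = "hpds_quartile_table"
  )
}

#' @export
print.hpds_quartile_table <- function(x, digits = 1, ...) {
  cat("<hpds_quartile_table>\n n per quartile:",
      paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  if (!is.null(x$continuous)) {
    wide <- stats::reshape(
      transform(x$continuous,
                cell = sprintf("%s (%s)",
                               format(round_half_up(mean, digits), nsmall = digits),
                               format(round_half_up(sd, digits), nsmall = digits)))[,
        c("variable", "quartile", "cell")],
      idvar = "variable", timevar = "quartile", direction = "wide")
    names(wide) <- sub("^cell\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read a quartile table at printed precision
#'
#' The table is serialised as long-format CSV with every numeric cell rounded
#' half-up to `digits` decimals (the precision at which such tables are
#' printed); reading it back reproduces exactly those printed cells.
#'
#' @param table an `hpds_quartile_table`.
#' @param path CSV path.
#' @param digits decimals kept for means/SDs/percentages.
#' @return `path` (write) or an `hpds_quartile_table` whose cells carry the
#'   printed precision (read).
#' @export
write_quartile_table <- function(table, path, digits = 1) {
  stopifnot(inherits(table, "hpds_quartile_table"))
  rows <- list(data.frame(section = "n", variable = "n", level = "",
                          quartile = names(table$n), value1 = as.numeric(table$n),
                          value2 = NA_real_, stringsAsFactors = FALSE))
  if (!is.null(table$continuous)) {
    rows <- c(rows, list(with(table$continuous, data.frame(
      section = "continuous", variable = variable, level = "",
      quartile = quartile, value1 = round_half_up(mean, digits),
      value2 = round_half_up(sd, digits), stringsAsFactors = FALSE))))
  }
  if (!is.null(table$categorical)) {
    rows <- c(rows, list(with(table$categorical, data.frame(
      section = "categorical", variable = variable, level = level,
      quartile = quartile, value1 = n,
      value2 = round_half_up(pct, digits), stringsAsFactors = FALSE))))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quartile_table
#' @export
read_quartile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$level[is.na(df$level)] <- ""
  n_rows <- df[df$section == "n", ]
  cont <- df[df$section == "continuous", ]
  catg <- df[df$section == "categorical", ]
  structure(
    list(
      n = stats::setNames(n_rows$value1, n_rows$quartile),
      continuous = if (nrow(cont)) data.frame(
        variable = cont$variable, quartile = cont$quartile,
        mean = cont$value1, sd = cont$value2, stringsAsFactors = FALSE) else NULL,
      categorical = if (nrow(catg)) data.frame(
        variable = catg$variable, level = catg$level, quartile = catg$quartile,
        n = catg$value1, pct = catg$value2, stringsAsFactors = FALSE) else NULL
    ),
    class = "hpds_quartile_table"
  )
}

#' Q4 minus Q1 contrast of a table variable
#'
#' Difference and percent change between the top and bottom score quartile
#' means, computed at the precision the means are given in, with the rounded
#' headline value alongside the exact one (printed contrasts are often
#' loosely rounded, so both are kept visible).
#'
#' @param q1_mean,q4_mean the Q1 and Q4 means (at printed precision).
#' @param variable variable name carried through to the output.
#' @param rounding `"integer"`, `"nearest_10"`, or `"one_decimal"` -- the
#'   half-up rounding applied to the headline difference.
#' @return data.frame with `variable`, `q1_mean`, `q4_mean`, `difference`
#'   (exact), `difference_rounded`, `percent_change` (exact, relative to Q1),
#'   `percent_change_rounded` (integer percent), `rounding`.
#' @examples
#' q4_vs_q1_contrast(14.6, 22.3, "fiber_g_d")     # +7.7, headline +8
#' @export
q4_vs_q1_contrast <- function(q1_mean, q4_mean, variable = "",
                              rounding = c("integer", "nearest_10", "one_decimal")) {
  rounding <- match.arg(rounding)
  diff <- q4_mean - q1_mean
  digits <- switch(rounding, integer = 0, nearest_10 = -1, one_decimal = 1)
  pct <- if (q1_mean != 0) 100 * diff / abs(q1_mean) else NA_real_
  data.frame(
    variable = variable, q1_mean = q1_mean, q4_mean = q4_mean,
    difference = diff,
    difference_rounded = round_half_up(diff, digits),
    percent_change = pct,
    percent_change_rounded = round_half_up(pct, 0),
    rounding = rounding,
    stringsAsFactors = FALSE
  )
}

#' Incidence proportion as a printed percentage
#'
#' @param n_events number of incident events (0 <= n_events <= n_cohort).
#' @param n_cohort cohort size (> 0).
#' @param decimals decimal places of the printed percentage (half-up).
#' @return the percentage, rounded half-up to `decimals`.
#' @examples
#' incidence_proportion(20692, 192274, 1)   # 10.8
#' incidence_proportion(1131, 192274, 2)    # 0.59
#' @export
incidence_proportion <- function(n_events, n_cohort, decimals = 1) {
  if (n_cohort <= 0) hpds_error("n_cohort must be > 0", "hpds_validation_error")
  if (any(n_events < 0) || any(n_events > n_cohort)) {
    hpds_error("n_events must lie in [0, n_cohort]", "hpds_validation_error")
  }
  round_half_up(100 * n_events / n_cohort, decimals)
}

#' Forest-style summary table of quartile Cox results
#'
#' Flattens a list of quartile-exposure Cox results into report rows grouped
#' by outcome, with Q1 shown as the reference (HR 1.00, no CI), and
#' Benjamini-Hochberg adjustment applied across all non-reference rows of
#' the run (the FDR family is the whole table; the `fdr_family` column makes
#' that explicit).
#'
#' @param results named list of `hpds_cox_result` objects (names are ignored;
#'   outcomes are taken from each result's spec).
#' @param fdr_q FDR level for adjusted p-values.
#' @param include_reference include a Q1 reference row per outcome.
#' @return data.frame with columns `outcome`, `exposure_level`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `p_adjusted`, `trend_p`, `n`, `n_events`,
#'   `strata`, `fdr_family`.
#' @export
forest_table <- function(results, fdr_q = 0.05, include_reference = TRUE) {
  if (!length(results)) {
    return(data.frame(outcome = character(), exposure_level = character(),
                      hr = numeric(), ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), p_adjusted = numeric(), trend_p = numeric(),
                      n = integer(), n_events = integer(), strata = character(),
                      fdr_family = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(results, function(res) {
    stopifnot(inherits(res, "hpds_cox_result"))
    est <- res$estimates
    qrows <- est[grepl("^quartileQ", est$term), , drop = FALSE]
    out <- data.frame(
      outcome = res$spec$outcome,
      exposure_level = sub("^quartile", "", qrows$term),
      hr = qrows$hr, ci_low = qrows$ci_low, ci_high = qrows$ci_high,
      p = qrows$p, trend_p = res$trend_p, n = res$n, n_events = res$n_events,
      strata = paste(res$strata_applied, collapse = ";"),
      stringsAsFactors = FALSE
    )
    if (include_reference) {
      ref <- data.frame(outcome = res$spec$outcome, exposure_level = "Q1",
                        hr = 1, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, trend_p = res$trend_p, n = res$n,
                        n_events = res$n_events,
                        strata = paste(res$strata_applied, collapse = ";"),
                        stringsAsFactors = FALSE)
      out <- rbind(ref, out)
    }
    out
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab$p_adjusted <- NA_real_
  idx <- !is.na(tab$p)
  if (any(idx)) tab$p_adjusted[idx] <- bh_adjust(tab$p[idx], fdr_q)$p_adjusted
  tab$fdr_family <- "run"
  tab[, c("outcome", "exposure_level", "hr", "ci_low", "ci_high", "p",
          "p_adjusted", "trend_p", "n", "n_events", "strata", "fdr_family")]
}

#' Render a forest table as plain text
#'
#' @param tab data.frame from [forest_table()].
#' @return character vector of report lines.
#' @export
format_forest_table <- function(tab) {
  lines <- character()
  for (oc in unique(tab$outcome)) {
    sub <- tab[tab$outcome == oc, ]
    lines <- c(lines, sprintf("%s (n = %d, events = %d, trend p = %.3g)",
                              oc, sub$n[1], sub$n_events[1], sub$trend_p[1]))
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, if (is.na(sub$p[i])) {
        sprintf("  %-3s 1.00 (reference)", sub$exposure_level[i])
      } else {
        sprintf("  %-3s %.2f [%.2f, %.2f]  p = %.3g (adj %.3g)",
                sub$exposure_level[i], sub$hr[i], sub$ci_low[i],
                sub$ci_high[i], sub$p[i], sub$p_adjusted[i])
      })
    }
  }
  lines
}
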