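#' Quintile cutpoints for one food group
#'
#' Empirical 20/40/60/80th percentiles of a cohort's intake distribution,
#' using the linear-interpolation percentile definition (type 7 in
#' [stats::quantile()]). Quintile membership is sensitive to the percentile
#' definition, so it is fixed and documented rather than configurable.
#' Boundaries that coincide (typical when more than 20% of the cohort
#' consumes zero of a group) are flagged as degenerate; [score_group()]
#' merges the corresponding quintiles.
#'
#' @param values numeric vector of one group's cohort intakes (grams/week).
#' @return list with `thresholds` (named numeric, length 4, nondecreasing)
#'   and `degenerate` (logical, length 4: boundary equals its predecessor or,
#'   for the first, the cohort minimum and maximum collapse there).
#' @export
quintile_cutpoints <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) {
    hpds_error("need at least 5 non-missing values to form quintiles",
               "hpds_insufficient_data_error")
  }
  th <- stats::quantile(values, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                        names = TRUE)
  degenerate <- c(FALSE, th[-1] == th[-4])
  if (length(unique(values)) == 1L) degenerate[] <- TRUE
  # a boundary shared with the minimum means the lowest quintiles collapse
  degenerate <- degenerate | th == min(values)
  list(thresholds = unname(th), degenerate = unname(degenerate))
}

#' Signed quintile score for one intake value
#'
#' The quintile rank r is the number of cutpoint thresholds strictly below
#' the intake (r in 0..4); a value tied with a threshold falls into the lower
#' quintile, so zero-consumers of a zero-inflated group all receive the
#' lowest rank, and collapsed boundaries merge quintiles automatically. The
#' subscore is `direction * (r - 2)`: centered so that the middle quintile
#' contributes 0, the top quintile of a heart-protective (+1) group +2, and
#' the top quintile of a discouraged (-1) group -2.
#'
#' @param intake numeric vector of intakes (grams/week).
#' @param cutpoints result of [quintile_cutpoints()] for the same cohort.
#' @param direction +1 or -1.
#' @return integer vector of subscores in -2..2.
#' @export
score_group <- function(intake, cutpoints, direction) {
  stopifnot(direction %in% c(-1, 1))
  th <- cutpoints$thresholds
  r <- rowSums(outer(intake, th, ">"))
  as.integer(direction * (r - 2))
}

#' Compute the heart-protective diet score for a cohort
#'
#' For each of the taxonomy's food groups, ranks the cohort's weekly intake
#' into quintiles ([quintile_cutpoints()]), scores each participant
#' ([score_group()]), and sums the 22 signed subscores into a total in
#' -44..44 (11 positive and 11 negative groups, each contributing -2..2).
#' Score quartiles (Q1 = lowest adherence, the reference in hazard models)
#' are assigned from the cohort total-score distribution.
#'
#' @param intake participants x groups matrix of grams/week from
#'   [aggregate_group_intake()] (columns must match the taxonomy's groups).
#' @param taxonomy the `hpds_taxonomy` the intake was aggregated under.
#' @return an object of class `hpds_score`: list with
#'   \describe{
#'     \item{scores}{data.frame: `participant_id`, `total_score`, `quartile`,
#'       and one `subscore_<group_id>` column per group.}
#'     \item{cutpoints}{per-group cutpoint list.}
#'     \item{summary}{cohort mean, sd, min, max of the total score.}
#'   }
#' @examples
#' tax <- load_taxonomy()
#' sim <- simulate_cohort(sim_config(n = 200, seed = 1))
#' intake <- aggregate_group_intake(sim$recalls, tax)
#' res <- compute_hpds(intake, tax)
#' res$summary
#' @export
compute_hpds <- function(intake, taxonomy) {
  stopifnot(inherits(taxonomy, "hpds_taxonomy"))
  group_ids <- taxonomy$groups$group_id
  if (!identical(colnames(intake), group_ids)) {
    hpds_error("intake matrix columns do not match taxonomy groups (order matters)",
               "hpds_schema_error")
  }
  if (any(intake < 0)) {
    hpds_error("intake matrix has negative entries", "hpds_schema_error")
  }
  cutpoints <- lapply(group_ids, function(g) quintile_cutpoints(intake[, g]))
  names(cutpoints) <- group_ids
  sub <- vapply(seq_along(group_ids), function(j) {
    score_group(intake[, j], cutpoints[[j]], taxonomy$groups$direction[j])
  }, integer(nrow(intake)))
  if (is.null(dim(sub))) sub <- matrix(sub, nrow = 1)
  colnames(sub) <- paste0("subscore_", group_ids)
  total <- as.integer(rowSums(sub))
  scores <- data.frame(
    participant_id = rownames(intake),
    total_score = total,
    quartile = assign_score_quartiles(total),
    sub,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(
      scores = scores,
      cutpoints = cutpoints,
      summary = c(mean = mean(total), sd = stats::sd(total),
                  min = min(total), max = max(total))
    ),
    class = "hpds_score"
  )
}

#' @export
print.hpds_score <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hpds_score> n = %d; total score mean %.2f (SD %.2f), range [%g, %g]\n",
              nrow(x$scores), s["mean"], s["sd"], s["min"], s["max"]))
  invisible(x)
}

#' Assign cohort score quartiles
#'
#' Labels Q1..Q4 from the 25/50/75th percentiles (linear interpolation) of
#' the total-score distribution; a score tied with a cutpoint falls into the
#' lower quartile. When the distribution is so concentrated that all
#' cutpoints coincide with the minimum, every participant is labelled Q1 and
#' a degeneracy warning is issued.
#'
#' @param totals numeric vector of total scores, length >= 4.
#' @return factor with levels Q1..Q4.
#' @export
assign_score_quartiles <- function(totals) {
  if (length(totals) < 4) {
    hpds_error("need at least 4 participants to form score quartiles",
               "hpds_insufficient_data_error")
  }
  cut3 <- stats::quantile(totals, probs = c(0.25, 0.5, 0.75), type = 7)
  r <- rowSums(outer(totals, cut3, ">"))
  if (all(r == 0) && length(unique(totals)) == 1L) {
    warning("degenerate score distribution: all totals equal; everyone in Q1",
            call. = FALSE)
  }
  factor(paste0("Q", r + 1), levels = paste0("Q", 1:4))
}

#' Reliability of the score across repeated recalls
#'
#' Pearson product-moment correlation (with its two-sided t-test p-value)
#' between the baseline score (first recall occasion) and the score averaged
#' over repeated occasions, quantifying how well a single 24 h recall tracks
#' the longer-run diet signal.
#'
#' @param baseline_scores numeric vector of baseline scores.
#' @param averaged_scores numeric vector of averaged scores, same participants
#'   in the same order.
#' @return list with `r` (correlation) and `p_value`.
#' @export
reliability <- function(baseline_scores, averaged_scores) {
  if (length(baseline_scores) != length(averaged_scores)) {
    hpds_error("baseline and averaged score vectors differ in length",
               "hpds_schema_error")
  }
  if (length(baseline_scores) < 3) {
    hpds_error("need at least 3 pairs for a correlation", "hpds_insufficient_data_error")
  }
  if (stats::sd(baseline_scores) == 0 || stats::sd(averaged_scores) == 0) {
    hpds_error("correlation undefined: a score vector has zero variance",
               "hpds_degenerate_error")
  }
  ct <- stats::cor.test(baseline_scores, averaged_scores, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Write scores to CSV
#'
#' @param result an `hpds_score` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path) {
  stopifnot(inherits(result, "hpds_score"))
  utils::write.csv(result$scores, path, row.names = FALSE)
  invisible(path)
}
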