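#' Specification of one Cox model
#'
#' Describes one cause-specific Cox proportional hazards fit on the age
#' timescale: the exposure (score quartiles with Q1 as reference, the
#' continuous score, or a single standardized food-group intake), the
#' adjustment covariates, any stratification factors, and an optional
#' multiplicative interaction term.
#'
#' @param outcome outcome name (must match the outcome table).
#' @param exposure `"score_quartiles"`, `"continuous_score"` or
#'   `"single_food_group"`.
#' @param covariates character vector of adjustment covariate column names.
#' @param strata character vector of stratification factor column names
#'   (these enter `survival::strata()` instead of the linear predictor).
#' @param food_group group_id of the exposure when
#'   `exposure = "single_food_group"`.
#' @param interaction optional covariate name for a multiplicative
#'   exposure-by-covariate interaction.
#' @param ties tie-handling method; Efron by default (age-scale data are
#'   tie-heavy), Breslow available.
#' @return list of class `hpds_cox_spec`.
#' @export
cox_spec <- function(outcome,
                     exposure = c("score_quartiles", "continuous_score",
                                  "single_food_group"),
                     covariates = character(),
                     strata = character(),
                     food_group = NULL,
                     interaction = NULL,
                     ties = c("efron", "breslow")) {
  exposure <- match.arg(exposure)
  ties <- match.arg(ties)
  if (exposure == "single_food_group" && is.null(food_group)) {
    hpds_error("single_food_group exposure requires a food_group", "hpds_spec_error")
  }
  structure(
    list(outcome = outcome, exposure = exposure, covariates = covariates,
         strata = strata, food_group = food_group, interaction = interaction,
         ties = ties),
    class = "hpds_cox_spec"
  )
}

#' Remove prevalent cases of an outcome
#'
#' Drops participants flagged as prevalent cases of the given outcome at
#' baseline, so that only incident cases contribute person-time.
#'
#' @param outcomes outcome data.frame with columns `participant_id`,
#'   `outcome`, `prevalent_at_baseline`.
#' @param outcome outcome name to filter on.
#' @return the outcome rows for `outcome` with prevalent cases removed; the
#'   number excluded is reported via `message()`.
#' @export
exclude_prevalent <- function(outcomes, outcome) {
  check_columns(outcomes, c("participant_id", "outcome", "prevalent_at_baseline"),
                "outcome table")
  rows <- outcomes[outcomes$outcome == outcome, , drop = FALSE]
  if (!nrow(rows)) {
    hpds_error(sprintf("no rows for outcome '%s'", outcome), "hpds_schema_error")
  }
  n_prev <- sum(rows$prevalent_at_baseline == 1)
  kept <- rows[rows$prevalent_at_baseline != 1, , drop = FALSE]
  if (!nrow(kept)) {
    hpds_error(sprintf("all participants are prevalent cases of '%s'", outcome),
               "hpds_empty_cohort_error")
  }
  message(sprintf("outcome '%s': excluded %d prevalent case(s), %d remain",
                  outcome, n_prev, nrow(kept)))
  kept
}

#' Assemble the analysis table for one outcome
#'
#' Joins scores, covariates and the (prevalent-case-filtered) outcome rows
#' into one modelling data.frame with the left-truncated age interval
#' (`entry_age`, `exit_age`, `event`), the score exposure columns, and the
#' covariates.
#'
#' @param scores an `hpds_score` object or its `$scores` data.frame.
#' @param covariates covariate data.frame keyed by `participant_id`.
#' @param outcomes outcome data.frame (all outcomes; filtered internally).
#' @param outcome outcome name.
#' @param drop_prevalent exclude prevalent cases first (default `TRUE`).
#' @return modelling data.frame, one row per participant present in all
#'   three inputs.
#' @export
assemble_cox_data <- function(scores, covariates, outcomes, outcome,
                              drop_prevalent = TRUE) {
  if (inherits(scores, "hpds_score")) scores <- scores$scores
  check_columns(scores, c("participant_id", "total_score", "quartile"), "score table")
  rows <- if (drop_prevalent) exclude_prevalent(outcomes, outcome) else {
    outcomes[outcomes$outcome == outcome, , drop = FALSE]
  }
  check_columns(rows, c("entry_age", "exit_age", "event"), "outcome table")
  dat <- merge(rows[, c("participant_id", "entry_age", "exit_age", "event")],
               scores, by = "participant_id")
  dat <- merge(dat, covariates, by = "participant_id")
  if (!nrow(dat)) hpds_error("no participants common to all inputs",
                             "hpds_empty_cohort_error")
  if (any(dat$exit_age <= dat$entry_age)) {
    hpds_error("exit_age must exceed entry_age for every participant",
               "hpds_schema_error")
  }
  dat$quartile <- factor(dat$quartile, levels = paste0("Q", 1:4))
  dat
}

exposure_term <- function(spec) {
  switch(spec$exposure,
         score_quartiles = "quartile",
         continuous_score = "total_score",
         single_food_group = spec$food_group)
}

# the formula environment is the caller's frame so that post-fit utilities
# (cox.zph) can re-resolve the data object held there
cox_formula <- function(spec, extra = NULL, env = parent.frame()) {
  rhs <- c(exposure_term(spec), extra, spec$covariates,
           if (length(spec$strata)) sprintf("strata(%s)", spec$strata))
  stats::as.formula(paste("survival::Surv(entry_age, exit_age, event) ~",
                          paste(rhs, collapse = " + ")), env = env)
}

#' Fit one cause-specific Cox model
#'
#' Partial-likelihood fit on the age scale with left truncation at entry age
#' and Efron tie handling. For quartile exposures Q1 is the reference and
#' hazard ratios for Q2-Q4 are returned; a quartile with zero events is
#' flagged non-estimable with a warning rather than an error.
#'
#' @param data modelling data.frame from [assemble_cox_data()] (for
#'   `single_food_group` exposures it must also hold the standardized group
#'   intake column).
#' @param spec an [cox_spec()].
#' @return object of class `hpds_cox_result`: list with `estimates`
#'   (data.frame: term, hr, ci_low, ci_high, p, n_events_level), `n`,
#'   `n_events`, `trend_p` (for quartile exposures), `strata_applied`,
#'   `spec`, and the underlying `fit`.
#' @export
fit_cox <- function(data, spec) {
  stopifnot(inherits(spec, "hpds_cox_spec"))
  term <- exposure_term(spec)
  check_columns(data, c("entry_age", "exit_age", "event", term), "analysis data")
  if (spec$exposure == "score_quartiles") {
    ev_by_level <- tapply(data$event, data$quartile, sum)
    ev_by_level[is.na(ev_by_level)] <- 0
    if (any(ev_by_level == 0)) {
      warning(sprintf("zero events in exposure level(s) %s: HR non-estimable",
                      paste(names(ev_by_level)[ev_by_level == 0], collapse = ", ")),
              call. = FALSE)
    }
  }
  fit <- survival::coxph(cox_formula(spec), data = data, ties = spec$ties)
  sm <- summary(fit)
  est <- data.frame(
    term = rownames(sm$coefficients),
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  trend_p <- if (spec$exposure == "score_quartiles" &&
                 "total_score" %in% names(data)) {
    trend_test(data, spec)
  } else NA_real_
  structure(
    list(estimates = est, n = sm$n, n_events = sm$nevent, trend_p = trend_p,
         strata_applied = spec$strata, spec = spec, fit = fit),
    class = "hpds_cox_result"
  )
}

#' @export
print.hpds_cox_result <- function(x, ...) {
  cat(sprintf("<hpds_cox_result> outcome '%s', exposure %s: n = %d, events = %d\n",
              x$spec$outcome, x$spec$exposure, x$n, x$n_events))
  print(within(x$estimates, {
    hr <- round(hr, 3); ci_low <- round(ci_low, 3); ci_high <- round(ci_high, 3)
    p <- signif(p, 3)
  }))
  if (!is.na(x$trend_p)) cat(sprintf("trend p = %.3g\n", x$trend_p))
  invisible(x)
}

#' Linear trend test across the score
#'
#' Wald p-value for the continuous score coefficient in the otherwise
#' identical Cox model (the quartile exposure replaced by the raw score).
#'
#' @inheritParams fit_cox
#' @return two-sided Wald p-value.
#' @export
trend_test <- function(data, spec) {
  check_columns(data, "total_score", "analysis data")
  if (stats::sd(data$total_score) == 0) {
    hpds_error("trend test non-estimable: score is constant", "hpds_degenerate_error")
  }
  spec2 <- spec
  spec2$exposure <- "continuous_score"
  class(spec2) <- class(spec)
  fit <- survival::coxph(cox_formula(spec2), data = data, ties = spec$ties)
  unname(summary(fit)$coefficients["total_score", "Pr(>|z|)"])
}

#' Proportional-hazards diagnostics with stratification fallback
#'
#' Fits the model, tests every covariate's Schoenfeld residuals against time
#' (`survival::cox.zph`), and moves covariates violating proportionality
#' (p < `alpha`) from the linear predictor into strata. The revised spec is
#' returned for refitting; the decision trail is in the diagnostics table.
#'
#' @inheritParams fit_cox
#' @param alpha violation threshold on the Schoenfeld test p-value.
#' @return list with `diagnostics` (data.frame: term, chisq, df, p,
#'   stratified), `global_p`, and `spec` (revised).
#' @export
check_ph_and_stratify <- function(data, spec, alpha = 0.05) {
  if (!length(spec$covariates)) {
    return(list(diagnostics = data.frame(term = character(), chisq = numeric(),
                                         df = numeric(), p = numeric(),
                                         stratified = logical()),
                global_p = NA_real_, spec = spec))
  }
  fit <- survival::coxph(cox_formula(spec), data = data, ties = spec$ties)
  zph <- survival::cox.zph(fit)
  tab <- as.data.frame(zph$table)
  global_p <- tab["GLOBAL", "p"]
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  diag <- data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
                     p = tab$p, row.names = NULL, stringsAsFactors = FALSE)
  # the zph table is per model term (covariate), exposure term included;
  # only adjustment covariates are eligible for stratification
  diag$stratified <- diag$term %in% spec$covariates & diag$p < alpha
  revised <- spec
  to_strata <- diag$term[diag$stratified]
  revised$covariates <- setdiff(spec$covariates, to_strata)
  revised$strata <- union(spec$strata, to_strata)
  class(revised) <- class(spec)
  list(diagnostics = diag, global_p = global_p, spec = revised)
}

#' Multiplicative interaction test with subgroup fits
#'
#' Adds an exposure-by-modifier product term to the model and returns its
#' Wald p-value; when the interaction is significant at `alpha`, the model is
#' refit within modifier subgroups (a numeric modifier such as the Townsend
#' deprivation index is split at its cohort median).
#'
#' @inheritParams fit_cox
#' @param modifier covariate name (e.g. `"sex"` or `"tdi"`).
#' @param alpha significance level deciding whether subgroup fits are run.
#' @return list with `interaction_p`, `modifier`, and `subgroups` (named list
#'   of `hpds_cox_result`, empty when the interaction is not significant).
#' @export
interaction_test <- function(data, spec, modifier, alpha = 0.05) {
  check_columns(data, modifier, "analysis data")
  mod <- data[[modifier]]
  if (length(unique(mod)) < 2) {
    hpds_error(sprintf("interaction non-estimable: modifier '%s' is constant",
                       modifier), "hpds_degenerate_error")
  }
  term <- exposure_term(spec)
  # interaction tested on the continuous exposure for a single-df Wald test
  spec_c <- spec
  if (spec$exposure == "score_quartiles") {
    spec_c$exposure <- "continuous_score"
    class(spec_c) <- class(spec)
    term <- "total_score"
  }
  covs <- union(setdiff(spec_c$covariates, modifier), modifier)
  spec_c$covariates <- covs
  fml <- cox_formula(spec_c, extra = sprintf("%s:%s", term, modifier))
  fit <- survival::coxph(fml, data = data, ties = spec$ties)
  cf <- summary(fit)$coefficients
  int_rows <- grep(":", rownames(cf))
  p_int <- min(cf[int_rows, "Pr(>|z|)"])

  subgroups <- list()
  if (!is.na(p_int) && p_int < alpha) {
    groups <- if (is.numeric(mod)) {
      split_at <- stats::median(mod)
      ifelse(mod <= split_at, sprintf("%s<=median", modifier),
             sprintf("%s>median", modifier))
    } else as.character(mod)
    spec_sub <- spec
    spec_sub$covariates <- setdiff(spec$covariates, modifier)
    class(spec_sub) <- class(spec)
    for (g in unique(groups)) {
      subgroups[[g]] <- fit_cox(data[groups == g, , drop = FALSE], spec_sub)
    }
  }
  list(interaction_p = unname(p_int), modifier = modifier, subgroups = subgroups)
}

#' One Cox model per food group
#'
#' Fits the same adjusted Cox model once per food group, with the group's
#' weekly intake standardized to mean 0 / SD 1 as the (continuous) exposure,
#' and adjusts the 22 p-values with Benjamini-Hochberg within the family of
#' per-group models.
#'
#' @param data modelling data.frame from [assemble_cox_data()].
#' @param intake participants x groups intake matrix (grams/week); rows are
#'   matched to `data$participant_id`.
#' @param taxonomy the taxonomy defining the groups.
#' @param spec base [cox_spec()] providing outcome, covariates and ties.
#' @param fdr_q FDR level for the rejection flag.
#' @return data.frame with one row per group: `group_id`, `direction`, `hr`
#'   (per SD of intake), `ci_low`, `ci_high`, `p`, `p_adjusted`, `rejected`.
#' @export
per_food_group_models <- function(data, intake, taxonomy, spec, fdr_q = 0.05) {
  idx <- match(data$participant_id, rownames(intake))
  if (anyNA(idx)) hpds_error("intake matrix is missing participants in data",
                             "hpds_schema_error")
  res <- lapply(seq_len(nrow(taxonomy$groups)), function(j) {
    g <- taxonomy$groups$group_id[j]
    x <- intake[idx, g]
    if (stats::sd(x) == 0) {
      return(data.frame(group_id = g, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_))
    }
    dat <- data
    dat[[g]] <- as.numeric(scale(x))
    spec_g <- cox_spec(outcome = spec$outcome, exposure = "single_food_group",
                       covariates = spec$covariates, strata = spec$strata,
                       food_group = g, ties = spec$ties)
    fit <- fit_cox(dat, spec_g)
    est <- fit$estimates[fit$estimates$term == g, ]
    data.frame(group_id = g, hr = est$hr, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p)
  })
  out <- do.call(rbind, res)
  out$direction <- taxonomy$groups$direction
  adj <- bh_adjust(out$p[!is.na(out$p)], q = fdr_q)
  out$p_adjusted <- NA_real_
  out$p_adjusted[!is.na(out$p)] <- adj$p_adjusted
  out$rejected <- !is.na(out$p_adjusted) & out$p_adjusted <= fdr_q
  out[, c("group_id", "direction", "hr", "ci_low", "ci_high", "p",
          "p_adjusted", "rejected")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and the rejection set at FDR level `q`. The
#' family over which p-values are adjusted is whatever vector is passed in;
#' callers make the family explicit (e.g. all outcome models of one run, or
#' the 22 per-food-group models).
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @param q FDR level.
#' @return list with `p_adjusted` (same order as input) and `rejected`
#'   (logical: adjusted p <= q).
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    hpds_error("p-values must lie in [0, 1]", "hpds_validation_error")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}
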