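#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the generator. The defaults encode the
#' study conditions the analysis pipeline is designed for: a middle-aged
#' cohort recruited at ages 40-69, one to five 24 h recalls per participant,
#' zero-inflated right-skewed food-group intakes tied together by a latent
#' standard-normal "healthy eating" factor h (sign-aligned with each group's
#' scoring direction), Weibull proportional-hazards outcomes on the age
#' timescale with administrative censoring after 12.3 years of follow-up, and
#' event fractions of order 10% for incidence and 0.6% for mortality.
#'
#' @param n cohort size (>= 4).
#' @param seed RNG seed; every draw in the generator flows from it.
#' @param latent_loading per-group (or scalar) effect of h on log-intake,
#'   applied with the group's direction so that larger h means more of every
#'   heart-protective group and less of every discouraged one.
#' @param zero_prob per-group (or scalar) baseline probability of consuming
#'   none of the group; `NULL` uses built-in per-group defaults that make
#'   staple groups common and niche groups rare.
#' @param zero_slope logistic slope of the zero probability on
#'   `direction * h` (larger h, fewer zeros in heart-protective groups).
#' @param meanlog,sdlog per-group (or scalar) log-normal location/scale of
#'   weekly intake among consumers; `meanlog = NULL` defaults to
#'   `log(2 serves/week x serve size)` per group.
#' @param recall_noise_sd intra-individual SD, on the log scale, of occasion-
#'   specific intakes around the person-level mean.
#' @param n_recalls number of recall occasions per participant.
#' @param entry_age_range uniform recruitment age range in years.
#' @param admin_censor_years administrative censoring horizon after entry.
#' @param outcomes data.frame describing the simulated outcomes: columns
#'   `name`, `weibull_shape`, `weibull_scale` (age-scale baseline hazard
#'   parameters), `log_hr_per_sd` (log hazard ratio per SD of the true latent
#'   score), `prevalent_prob` (probability of being a prevalent case at
#'   baseline). The default simulates one incidence outcome ("CVD") and one
#'   mortality outcome ("CVD_death").
#' @param multi_item if `TRUE`, split each group's simulated mass uniformly
#'   at random across that group's taxonomy items; the default emits one
#'   item per group, which keeps recall tables small while still exercising
#'   item-to-group aggregation.
#' @return a validated list of class `hpds_sim_config`.
#' @export
sim_config <- function(n,
                       seed = 1L,
                       latent_loading = 0.6,
                       zero_prob = NULL,
                       zero_slope = 0.8,
                       meanlog = NULL,
                       sdlog = 0.8,
                       recall_noise_sd = 0.45,
                       n_recalls = 1L,
                       entry_age_range = c(40, 69),
                       admin_censor_years = 12.3,
                       outcomes = default_sim_outcomes(),
                       multi_item = FALSE) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    latent_loading = latent_loading, zero_prob = zero_prob,
    zero_slope = zero_slope, meanlog = meanlog, sdlog = sdlog,
    recall_noise_sd = recall_noise_sd, n_recalls = as.integer(n_recalls),
    entry_age_range = entry_age_range,
    admin_censor_years = admin_censor_years,
    outcomes = outcomes, multi_item = isTRUE(multi_item)
  )
  if (is.na(cfg$n) || cfg$n < 4) hpds_error("sim config: n must be >= 4", "hpds_config_error")
  if (!is.null(zero_prob) && any(zero_prob < 0 | zero_prob > 1)) {
    hpds_error("sim config: zero_prob must lie in [0, 1]", "hpds_config_error")
  }
  if (cfg$recall_noise_sd < 0) {
    hpds_error("sim config: recall_noise_sd must be >= 0", "hpds_config_error")
  }
  if (cfg$n_recalls < 1) hpds_error("sim config: n_recalls must be >= 1", "hpds_config_error")
  if (length(entry_age_range) != 2 || diff(entry_age_range) < 0) {
    hpds_error("sim config: entry_age_range must be (lo, hi) with lo <= hi",
               "hpds_config_error")
  }
  if (cfg$admin_censor_years <= 0) {
    hpds_error("sim config: admin_censor_years must be > 0", "hpds_config_error")
  }
  check_columns(outcomes, c("name", "weibull_shape", "weibull_scale",
                            "log_hr_per_sd", "prevalent_prob"),
                "sim config outcomes")
  if (any(outcomes$weibull_shape <= 0) || any(outcomes$weibull_scale <= 0)) {
    hpds_error("sim config: Weibull shape and scale must be > 0", "hpds_config_error")
  }
  structure(cfg, class = "hpds_sim_config")
}

#' Default simulated outcomes
#'
#' One incidence outcome and one mortality outcome on the age timescale.
#' With recruitment ages uniform on 40-69 and a 12.3-year horizon, the
#' age-rising Weibull baselines (shape 5) give event fractions of about 10%
#' ("CVD") and 0.6% ("CVD_death"), the orders of magnitude of the cohort the
#' pipeline targets.
#'
#' @return data.frame of outcome settings; see [sim_config()].
#' @export
default_sim_outcomes <- function() {
  data.frame(
    name = c("CVD", "CVD_death"),
    weibull_shape = c(5, 5),
    weibull_scale = c(96, 173.4),
    log_hr_per_sd = c(-0.10, -0.25),
    prevalent_prob = c(0.03, 0),
    stringsAsFactors = FALSE
  )
}

# per-group baseline probability of consuming none of the group in a week:
# staples (dairy, tea, refined grains) low, niche groups (soup, starchy veg,
# sweetener) high
default_zero_prob <- function(taxonomy) {
  defaults <- c(
    wholegrains = 0.15, fruits = 0.15, nonstarchy_vegetables = 0.10,
    starchy_vegetables = 0.90, nuts_seeds = 0.80, legumes_beans = 0.55,
    uncoated_fish_seafood = 0.55, eggs = 0.60, reduced_fat_dairy = 0.35,
    tea_coffee_lowcal_drinks = 0.05, homemade_soup = 0.90,
    refined_grains = 0.25, potatoes = 0.35, meat_poultry_processed = 0.25,
    coated_fish_seafood = 0.90, full_fat_dairy = 0.15, processed_soup = 0.80,
    sweets_desserts = 0.25, savory_snacks = 0.85, sugary_drinks = 0.75,
    artificial_sweetener = 0.75, unhealthy_fat = 0.45
  )
  p <- defaults[taxonomy$groups$group_id]
  p[is.na(p)] <- 0.5
  unname(p)
}

# recycle a scalar or length-G parameter across taxonomy groups
per_group <- function(x, taxonomy, what) {
  G <- nrow(taxonomy$groups)
  if (length(x) == 1L) return(rep(x, G))
  if (length(x) != G) {
    hpds_error(sprintf("sim config: %s must have length 1 or %d", what, G),
               "hpds_config_error")
  }
  x
}

# person-level mean log weekly intake and consumption indicator per group
simulate_intake_latents <- function(config, taxonomy, h) {
  G <- nrow(taxonomy$groups)
  n <- length(h)
  dir <- taxonomy$groups$direction
  loading <- per_group(config$latent_loading, taxonomy, "latent_loading")
  sdlog <- per_group(config$sdlog, taxonomy, "sdlog")
  meanlog <- if (is.null(config$meanlog)) {
    log(2 * taxonomy$groups$serve_size_g)
  } else per_group(config$meanlog, taxonomy, "meanlog")
  zp <- if (is.null(config$zero_prob)) default_zero_prob(taxonomy) else {
    per_group(config$zero_prob, taxonomy, "zero_prob")
  }
  # consumption: logit P(zero) = logit(zp) - zero_slope * dir * h
  p_zero <- stats::plogis(
    outer(-config$zero_slope * h, dir) + rep(stats::qlogis(zp), each = n)
  )
  mu <- outer(h, loading * dir) + rep(meanlog, each = n)
  list(mu = mu, p_zero = p_zero, sdlog = sdlog)
}

# turn a weekly intake matrix into item-level 24 h recall rows
intake_to_recall_rows <- function(weekly, taxonomy, recall_index, multi_item) {
  n <- nrow(weekly)
  group_ids <- taxonomy$groups$group_id
  rows <- vector("list", length(group_ids))
  for (j in seq_along(group_ids)) {
    g <- group_ids[j]
    w <- weekly[, j]
    keep <- which(w > 0)
    if (!length(keep)) next
    items <- taxonomy$items$item_id[taxonomy$items$group_id == g]
    if (multi_item && length(items) > 1) {
      picked <- sample(items, length(keep), replace = TRUE)
    } else {
      picked <- rep(items[1], length(keep))
    }
    rows[[j]] <- data.frame(
      participant_id = rownames(weekly)[keep],
      recall_index = recall_index,
      item_id = picked,
      amount_g = w[keep] / 7,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), recall_index = integer(),
                      item_id = character(), amount_g = numeric())
  }
  out[order(out$participant_id, out$item_id), , drop = FALSE]
}

# baseline covariates loosely tied to h so that high scorers look like the
# health-conscious stratum of a middle-aged cohort
simulate_covariates <- function(n, h) {
  income_levels <- c("<18k", "18-31k", "31-52k", "52-100k", ">100k")
  pa_levels <- c("low", "moderate", "high")
  smoke_levels <- c("never", "former", "current")
  pa_base <- c(0.14, 0.49, 0.37)
  sex <- ifelse(stats::runif(n) < stats::plogis(stats::qlogis(0.433) - 0.30 * h),
                "male", "female")
  pa_shift <- stats::plogis(0.25 * h)  # in (0,1); tilts mass toward "high"
  pa <- vapply(seq_len(n), function(i) {
    p <- pa_base * c(1 - pa_shift[i], 1, 1 + pa_shift[i])
    sample(pa_levels, 1, prob = p / sum(p))
  }, character(1))
  alcohol <- ifelse(stats::runif(n) < 0.2, 0,
                    stats::rgamma(n, shape = 0.8, scale = 25 * exp(-0.1 * h)))
  data.frame(
    participant_id = sprintf("p%05d", seq_len(n)),
    sex = sex,
    ethnicity = ifelse(stats::runif(n) < 0.955, "white", "other"),
    tdi = stats::rnorm(n, -1.6, 2.9),
    income = sample(income_levels, n, replace = TRUE,
                    prob = c(0.14, 0.23, 0.28, 0.24, 0.07)),
    education_degree = stats::runif(n) < stats::plogis(stats::qlogis(0.43) + 0.25 * h),
    supplement_use = stats::runif(n) < stats::plogis(stats::qlogis(0.52) + 0.20 * h),
    cancer_history = stats::runif(n) < 0.09,
    hyperglycemia_t2dm_history = stats::runif(n) < 0.05,
    physical_activity = factor(pa, levels = pa_levels),
    sitting_hours = pmax(0, stats::rnorm(n, 4.7 - 0.3 * h, 2.3)),
    sleep_score = pmin(5, pmax(0, round(stats::rnorm(n, 3.7 + 0.05 * h, 1)))),
    smoking = vapply(seq_len(n), function(i) {
      cur <- stats::plogis(stats::qlogis(0.08) - 0.30 * h[i])
      sample(smoke_levels, 1, prob = c(0.62 * (1 - cur), 0.38 * (1 - cur), cur))
    }, character(1)),
    alcohol_g_day = alcohol,
    stringsAsFactors = FALSE
  )
}

#' Draw left-truncated Weibull proportional-hazards event times
#'
#' Samples event ages on the age timescale from a Weibull baseline hazard
#' with cumulative hazard `(t/scale)^shape * exp(lp)`, conditional on
#' survival to the entry age (left truncation), and applies administrative
#' censoring `admin_years` after entry. No event before entry is ever
#' emitted, mirroring an incident-case design.
#'
#' @param entry_age vector of entry ages.
#' @param lp linear predictor on the log-hazard scale.
#' @param shape,scale Weibull parameters of the baseline hazard.
#' @param admin_years administrative censoring horizon after entry.
#' @return data.frame with `entry_age`, `exit_age`, `event`.
#' @export
simulate_event_ages <- function(entry_age, lp, shape, scale, admin_years) {
  u <- stats::runif(length(entry_age))
  t_event <- scale * ((entry_age / scale)^shape - log(u) / exp(lp))^(1 / shape)
  t_cens <- entry_age + admin_years
  data.frame(
    entry_age = entry_age,
    exit_age = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates, from one seed, every table the pipeline consumes: an item-level
#' 24 h recall table, a baseline covariate table, a per-outcome survival
#' table with left-truncated age intervals, and the ground truth (the latent
#' healthy-eating factor h used as the "true score"). Group intakes are
#' zero-inflated log-normal with the latent factor pushing every
#' heart-protective group up and every discouraged group down; outcome
#' hazards follow a Weibull proportional-hazards model on the age scale with
#' linear predictor `log_hr_per_sd * h` (h is standard normal, so h is the
#' exposure in SD units).
#'
#' @param config an [sim_config()] object.
#' @param taxonomy taxonomy whose items the recall rows reference; defaults
#'   to the packaged 22-group taxonomy.
#' @return list of class `hpds_sim` with elements `recalls`, `covariates`,
#'   `outcomes`, `truth` (data.frame `participant_id`, `h`), and `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(n = 100, seed = 42))
#' head(sim$outcomes)
#' @export
simulate_cohort <- function(config, taxonomy = load_taxonomy()) {
  stopifnot(inherits(config, "hpds_sim_config"))
  set.seed(config$seed)
  n <- config$n
  ids <- sprintf("p%05d", seq_len(n))
  h <- stats::rnorm(n)

  G <- nrow(taxonomy$groups)
  sd_occ <- config$recall_noise_sd
  # person-level draws shared across occasions: amount level, and a
  # consumption propensity z governing which groups the person tends to eat
  sdlog <- per_group(config$sdlog, taxonomy, "sdlog")
  base_draw <- matrix(stats::rnorm(n * G), n, G) * rep(sdlog, each = n)
  z <- matrix(stats::rnorm(n * G), n, G)
  recalls <- vector("list", config$n_recalls)
  for (occ in seq_len(config$n_recalls)) {
    # intra-individual variation has a day-level component coherent across
    # food groups (the whole day eaten "better" or "worse": h perturbed per
    # occasion) and a group-level episodic component (which items happened
    # to be eaten that day); both scale with recall_noise_sd, so occasions
    # coincide exactly when it is 0
    h_occ <- if (sd_occ > 0) h + sd_occ * stats::rnorm(n) else h
    lat <- simulate_intake_latents(config, taxonomy, h_occ)
    cons_cut <- sqrt(1 + sd_occ^2) * stats::qnorm(lat$p_zero)
    if (sd_occ > 0) {
      amt_noise <- matrix(stats::rnorm(n * G, 0, sd_occ), n, G)
      consumes <- (z + matrix(stats::rnorm(n * G, 0, sd_occ), n, G)) > cons_cut
    } else {
      amt_noise <- 0
      consumes <- z > cons_cut
    }
    weekly <- exp(lat$mu + base_draw + amt_noise) * consumes
    rownames(weekly) <- ids
    recalls[[occ]] <- intake_to_recall_rows(weekly, taxonomy, occ,
                                            config$multi_item)
  }
  recall_tab <- do.call(rbind, recalls)
  rownames(recall_tab) <- NULL

  covariates <- simulate_covariates(n, h)

  entry_age <- stats::runif(n, config$entry_age_range[1], config$entry_age_range[2])
  outcome_rows <- lapply(seq_len(nrow(config$outcomes)), function(i) {
    oc <- config$outcomes[i, ]
    ev <- simulate_event_ages(entry_age, oc$log_hr_per_sd * h,
                              oc$weibull_shape, oc$weibull_scale,
                              config$admin_censor_years)
    data.frame(
      participant_id = ids,
      outcome = oc$name,
      entry_age = ev$entry_age,
      exit_age = ev$exit_age,
      event = ev$event,
      prevalent_at_baseline = as.integer(stats::runif(n) < oc$prevalent_prob),
      stringsAsFactors = FALSE
    )
  })
  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL

  structure(
    list(recalls = recall_tab, covariates = covariates, outcomes = outcomes,
         truth = data.frame(participant_id = ids, h = h,
                            stringsAsFactors = FALSE),
         config = config),
    class = "hpds_sim"
  )
}

#' Simulate repeated recall occasions only
#'
#' Convenience wrapper returning just the multi-occasion recall table of
#' [simulate_cohort()]; occasion 1 is the baseline. Occasion-specific
#' log-intakes are the person-level log-mean plus Normal(0, recall_noise_sd)
#' noise, and consumption itself is episodic: each occasion's zero/nonzero
#' indicator comes from the person's consumption propensity plus occasion
#' noise of the same SD, so at `recall_noise_sd = 0` every occasion is
#' identical.
#'
#' @inheritParams simulate_cohort
#' @return a recall data.frame with `n_recalls` occasions per participant.
#' @export
simulate_repeat_recalls <- function(config, taxonomy = load_taxonomy()) {
  if (config$n_recalls < 2) {
    hpds_error("simulate_repeat_recalls needs n_recalls >= 2", "hpds_config_error")
  }
  simulate_cohort(config, taxonomy)$recalls
}

#' Baseline-vs-averaged score reliability in simulation
#'
#' Simulates `n_recalls` occasions, scores each occasion against its own
#' cohort quintiles, and correlates the baseline (occasion 1) score with the
#' mean score over all occasions ("score-then-average", the default order;
#' `average = "intake"` averages the intake matrices before scoring instead).
#'
#' @inheritParams simulate_cohort
#' @param average `"score"` (average per-occasion scores) or `"intake"`
#'   (average intakes, then score once).
#' @return list with `r`, `p_value`, `baseline`, `averaged`.
#' @export
repeat_recall_reliability <- function(config, taxonomy = load_taxonomy(),
                                      average = c("score", "intake")) {
  average <- match.arg(average)
  recalls <- simulate_repeat_recalls(config, taxonomy)
  occasions <- sort(unique(recalls$recall_index))
  mats <- lapply(occasions, function(occ) {
    aggregate_group_intake(recalls[recalls$recall_index == occ, ], taxonomy)
  })
  base_total <- compute_hpds(mats[[1]], taxonomy)$scores$total_score
  if (average == "score") {
    totals <- vapply(mats, function(m) compute_hpds(m, taxonomy)$scores$total_score,
                     numeric(nrow(mats[[1]])))
    avg_total <- rowMeans(totals)
  } else {
    avg_mat <- Reduce(`+`, mats) / length(mats)
    class(avg_mat) <- class(mats[[1]])
    avg_total <- compute_hpds(avg_mat, taxonomy)$scores$total_score
  }
  rel <- reliability(base_total, avg_total)
  c(rel, list(baseline = base_total, averaged = avg_total))
}

#' Calibrate recall noise to a target reliability
#'
#' Bisection search for the intra-individual noise SD at which the
#' baseline-vs-averaged score correlation hits `target_r`. Reliability is
#' monotone decreasing in the noise SD, so bisection converges; each
#' evaluation re-simulates under the same seed so the objective is
#' deterministic.
#'
#' @param target_r target Pearson correlation (the moderate-reliability
#'   regime of repeated 24 h recalls is around 0.5).
#' @param config a [sim_config()] with `n_recalls >= 2`; its
#'   `recall_noise_sd` is the parameter searched over.
#' @param taxonomy taxonomy passed through to the simulator.
#' @param interval search interval for the noise SD.
#' @param iterations number of bisection steps.
#' @return list with `recall_noise_sd` (calibrated value) and `r` (achieved
#'   correlation).
#' @export
calibrate_recall_noise <- function(target_r = 0.53, config,
                                   taxonomy = load_taxonomy(),
                                   interval = c(0.05, 4), iterations = 12) {
  eval_r <- function(sd) {
    cfg <- config
    cfg$recall_noise_sd <- sd
    repeat_recall_reliability(cfg, taxonomy)$r
  }
  lo <- interval[1]; hi <- interval[2]
  r_lo <- eval_r(lo); r_hi <- eval_r(hi)
  if (!(r_lo >= target_r && r_hi <= target_r)) {
    hpds_error(sprintf(
      "target r = %.2f not bracketed by interval [%g, %g] (r = %.3f, %.3f)",
      target_r, lo, hi, r_lo, r_hi), "hpds_calibration_error")
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (eval_r(mid) >= target_r) lo <- mid else hi <- mid
  }
  sd_star <- (lo + hi) / 2
  list(recall_noise_sd = sd_star, r = eval_r(sd_star))
}
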