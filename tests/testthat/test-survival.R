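tax <- load_taxonomy()

# small simulated analysis set shared across tests
make_analysis_data <- function(n = 1500, seed = 61, log_hr = -0.3) {
  set.seed(seed)
  h <- rnorm(n)
  entry <- runif(n, 40, 69)
  ev <- simulate_event_ages(entry, log_hr * h, 5, 96, 12.3)
  data.frame(participant_id = sprintf("p%05d", seq_len(n)),
             entry_age = ev$entry_age, exit_age = ev$exit_age,
             event = ev$event, total_score = h,
             quartile = assign_score_quartiles(h),
             sex = sample(c("male", "female"), n, replace = TRUE),
             tdi = rnorm(n),
             stringsAsFactors = FALSE)
}

test_that("a known hazard ratio is recovered from exponential data", {
  # two-group exponential: group 1 hazard 1/80, group 0 hazard as reference,
  # true HR 0.8 on the age scale with left truncation
  set.seed(101)
  n <- 10000
  x <- rep(0:1, each = n / 2)
  entry <- runif(n, 40, 69)
  ev <- simulate_event_ages(entry, log(0.8) * x, shape = 1, scale = 40,
                            admin_years = 12.3)
  dat <- data.frame(entry_age = ev$entry_age, exit_age = ev$exit_age,
                    event = ev$event, g = x)
  fit <- survival::coxph(survival::Surv(entry_age, exit_age, event) ~ g, dat)
  se <- sqrt(diag(fit$var))
  expect_lt(abs(coef(fit) - log(0.8)), 3 * se)
})

test_that("quartile fits return HRs vs Q1 and recoding the reference inverts them", {
  dat <- make_analysis_data()
  spec <- cox_spec("CVD", "score_quartiles", covariates = c("sex", "tdi"))
  fit <- fit_cox(dat, spec)
  expect_s3_class(fit, "hpds_cox_result")
  expect_equal(sum(grepl("^quartileQ", fit$estimates$term)), 3L)
  expect_true(all(fit$estimates$hr > 0))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$hr &
                  fit$estimates$hr <= fit$estimates$ci_high))
  expect_lte(fit$n_events, fit$n)
  expect_false(is.na(fit$trend_p))

  dat2 <- dat
  dat2$quartile <- relevel(factor(dat$quartile), ref = "Q4")
  fit2 <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ quartile + sex + tdi, dat2)
  hr_q4 <- fit$estimates$hr[fit$estimates$term == "quartileQ4"]
  expect_equal(unname(exp(coef(fit2)["quartileQ1"])), 1 / hr_q4,
               tolerance = 1e-8)
})

test_that("an exposure level with zero events is flagged non-estimable", {
  dat <- make_analysis_data(n = 400, seed = 7)
  dat$event[dat$quartile == "Q4"] <- 0
  spec <- cox_spec("CVD", "score_quartiles")
  w <- capture_warnings(fit_cox(dat, spec))
  expect_true(any(grepl("Q4", w)))
})

test_that("the trend test needs a non-constant score", {
  dat <- make_analysis_data(n = 200, seed = 15)
  dat$total_score <- 0
  expect_error(trend_test(dat, cox_spec("CVD", "score_quartiles")),
               class = "hpds_degenerate_error")
})

test_that("proportional data keep their covariates unstratified", {
  dat <- make_analysis_data()
  spec <- cox_spec("CVD", "score_quartiles", covariates = c("sex", "tdi"))
  res <- check_ph_and_stratify(dat, spec)
  expect_named(res, c("diagnostics", "global_p", "spec"))
  expect_equal(nrow(res$diagnostics), 3L)  # exposure + 2 covariates
  expect_false(any(res$diagnostics$stratified &
                   !res$diagnostics$term %in% c("sex", "tdi")))
})

test_that("a covariate with a time-varying effect is moved to strata", {
  # piecewise hazard: x doubles the hazard before age 60 and halves it after,
  # a textbook proportional-hazards violation
  set.seed(303)
  n <- 4000
  x <- rep(0:1, each = n / 2)
  entry <- runif(n, 40, 55)
  draw_piecewise <- function(a, xi) {
    lam1 <- 0.02 * ifelse(xi == 1, 2, 1)
    lam2 <- 0.02 * ifelse(xi == 1, 0.5, 1)
    t1 <- a + rexp(1, lam1)
    if (t1 <= 60) t1 else 60 + rexp(1, lam2)
  }
  t_ev <- mapply(draw_piecewise, entry, x)
  exit <- pmin(t_ev, entry + 15)
  dat <- data.frame(entry_age = entry, exit_age = exit,
                    event = as.integer(t_ev <= entry + 15),
                    total_score = rnorm(n), x = x)
  dat$quartile <- assign_score_quartiles(dat$total_score)
  spec <- cox_spec("X", "score_quartiles", covariates = "x")
  res <- check_ph_and_stratify(dat, spec)
  expect_true(res$diagnostics$stratified[res$diagnostics$term == "x"])
  expect_true("x" %in% res$spec$strata)
  expect_false("x" %in% res$spec$covariates)
})

test_that("an empty covariate list leaves the spec unchanged", {
  dat <- make_analysis_data(n = 200, seed = 1)
  spec <- cox_spec("CVD", "score_quartiles")
  res <- check_ph_and_stratify(dat, spec)
  expect_equal(nrow(res$diagnostics), 0L)
  expect_identical(res$spec, spec)
})

test_that("interaction tests require a varying modifier and detect strong ones", {
  dat <- make_analysis_data(n = 300, seed = 23)
  dat$sex <- "male"
  expect_error(interaction_test(dat, cox_spec("CVD", "score_quartiles"), "sex"),
               class = "hpds_degenerate_error")

  # sex-specific log-HR: -0.5 in females, 0 in males
  set.seed(404)
  n <- 8000
  sex <- sample(c("male", "female"), n, replace = TRUE)
  h <- rnorm(n)
  entry <- runif(n, 40, 69)
  ev <- simulate_event_ages(entry, ifelse(sex == "female", -0.5, 0) * h,
                            5, 96, 12.3)
  dat2 <- data.frame(entry_age = ev$entry_age, exit_age = ev$exit_age,
                     event = ev$event, total_score = h,
                     quartile = assign_score_quartiles(h), sex = sex,
                     stringsAsFactors = FALSE)
  res <- interaction_test(dat2, cox_spec("CVD", "score_quartiles"), "sex")
  expect_lt(res$interaction_p, 0.05)
  expect_setequal(names(res$subgroups), c("male", "female"))
  # a numeric modifier is split at its median for the subgroup fits
  dat2$tdi <- rnorm(n) + 0.3 * h  # correlated modifier
  res2 <- interaction_test(dat2, cox_spec("CVD", "score_quartiles"), "tdi",
                           alpha = 1)  # force subgroup fits
  expect_setequal(names(res2$subgroups), c("tdi<=median", "tdi>median"))
})

test_that("prevalent cases are excluded before modelling", {
  oc <- data.frame(participant_id = sprintf("p%02d", 1:10), outcome = "CVD",
                   entry_age = 50, exit_age = 60, event = 0,
                   prevalent_at_baseline = c(1, 1, rep(0, 8)))
  expect_message(kept <- exclude_prevalent(oc, "CVD"), "2 prevalent")
  expect_equal(nrow(kept), 8L)
  oc$prevalent_at_baseline <- 0
  expect_equal(nrow(suppressMessages(exclude_prevalent(oc, "CVD"))), 10L)
  oc$prevalent_at_baseline <- 1
  expect_error(suppressMessages(exclude_prevalent(oc, "CVD")),
               class = "hpds_empty_cohort_error")
})

test_that("assemble_cox_data joins tables and rejects invalid intervals", {
  sim <- simulate_cohort(sim_config(n = 80, seed = 2), tax)
  intake <- aggregate_group_intake(sim$recalls, tax)
  scores <- compute_hpds(intake, tax)
  dat <- suppressMessages(
    assemble_cox_data(scores, sim$covariates, sim$outcomes, "CVD"))
  expect_true(all(c("entry_age", "exit_age", "event", "total_score",
                    "quartile", "sex") %in% names(dat)))
  bad <- sim$outcomes
  bad$exit_age <- bad$entry_age
  expect_error(suppressMessages(
    assemble_cox_data(scores, sim$covariates, bad, "CVD")),
    class = "hpds_schema_error")
})

test_that("per-food-group models score each group per SD with BH adjustment", {
  sim <- simulate_cohort(sim_config(n = 600, seed = 37), tax)
  intake <- aggregate_group_intake(sim$recalls, tax)
  scores <- compute_hpds(intake, tax)
  dat <- suppressMessages(
    assemble_cox_data(scores, sim$covariates, sim$outcomes, "CVD"))
  res <- per_food_group_models(dat, intake, tax, cox_spec("CVD"))
  expect_equal(nrow(res), 22L)
  expect_equal(res$group_id, tax$groups$group_id)
  expect_true(all(res$hr > 0, na.rm = TRUE))
  # two groups given identical intake columns yield identical estimates
  tax2 <- toy_taxonomy(list(
    list(group_id = "g1", direction = 1, serve_size_g = 10, items = list("A")),
    list(group_id = "g2", direction = -1, serve_size_g = 10, items = list("B"))
  ))
  intake2 <- intake[, 1:2]
  colnames(intake2) <- c("g1", "g2")
  intake2[, "g2"] <- intake2[, "g1"]
  res2 <- per_food_group_models(dat, intake2, tax2, cox_spec("CVD"))
  expect_equal(res2$hr[1], res2$hr[2])
  expect_equal(res2$p[1], res2$p[2])
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(0.03)$p_adjusted, 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
               rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5))$p_adjusted, rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "hpds_validation_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "hpds_validation_error")
})
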