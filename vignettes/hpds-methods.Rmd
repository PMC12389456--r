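---
title: "Methods: score construction, simulation design, and survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score construction, simulation design, and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpds)
```

## The score and its conventions

The heart-protective diet score extends the plant-based diet index family
(PDI / hPDI / uPDI) by scoring the healthiness of animal-source foods as
well: fish and seafood, eggs, and reduced-fat dairy carry positive
directions, while red and processed meat, full-fat dairy, and discretionary
foods carry negative ones. The packaged taxonomy maps 176 recall items to
22 groups, 11 per direction, each with a serve size in grams (drinks in mL
are treated 1:1 as grams, the recall instrument's serve convention).

Scoring is *cohort-relative*: each group's weekly intake is ranked into
quintiles of the analysis cohort, so the score is only comparable within
the cohort whose cutpoints produced it. Three conventions are fixed and
deliberate:

* **Percentile definition.** Cutpoints are the empirical 20/40/60/80th
  percentiles with linear interpolation between order statistics (type 7 in
  `quantile()`). Quintile membership near a boundary is sensitive to this
  choice, so it is documented rather than configurable.
* **Ties go down.** An intake equal to a cutpoint falls into the lower
  quintile. With more than 20% zero consumers — common for niche groups —
  consecutive cutpoints collapse to zero and the lowest quintiles merge, so
  all zero consumers of a heart-protective group receive the lowest rank
  (−2 after centering). This is deterministic and conservative for
  non-consumers; the collapsed boundaries are flagged per group.
* **Centered signed scores.** The subscore is `direction × (rank − 2)`,
  an integer in [−2, 2]; totals are integers in [−44, 44] with an
  interpretable zero (everyone in every middle quintile). An hPDI-style
  1–5 coding with reverse scoring is an affine transform of the same ranks
  and would change no ordering. Published cohort analyses of this index
  report a non-integer score range, which cannot be reproduced from the
  centered-integer convention; the appendix-level arithmetic behind it is
  not available, and this divergence is a documented non-goal.

Aggregation multiplies a single 24 h recall by 7 to obtain grams/week,
matching the units in which group intakes are reported. With repeated
recalls the default policy uses the earliest occasion (maximising
downstream follow-up time); a mean-of-first-k policy averages the weekly
amounts of the available occasions.

For the "averaged" score used in reliability analysis, the default order is
**score-then-average**: each occasion is scored against its own cohort
cutpoints and the per-occasion totals are averaged. Averaging intakes
before scoring is also supported (`average = "intake"`); the two orders
differ because ranking is nonlinear, and neither is canonical.

## What the synthetic cohort emulates

`simulate_cohort()` generates every table the pipeline consumes from one
seed. Its defaults encode the study conditions the pipeline targets, chosen
once:

* **Recruitment and follow-up.** Entry ages uniform on 40–69; 12.3 years of
  administrative censoring after entry.
* **Intakes.** A standard-normal latent "healthy eating" factor *h* drives
  all 22 groups coherently: log-intake gains `loading × direction × h`
  (default loading 0.6), and the probability of consuming none of a group
  follows a logistic in `direction × h` (slope 0.8) around per-group
  baseline zero rates (staples rare at zero, niche groups mostly zero).
  Amounts among consumers are log-normal (person-level SD 0.8 on the log
  scale) around `2 serves/week × serve size`.
* **Outcomes.** Weibull proportional hazards on the *age* scale (shape 5,
  so hazard rises steeply with age), with linear predictor
  `log_hr_per_sd × h`, sampled conditional on survival to entry age
  (left truncation — no event before entry is ever emitted) and censored
  administratively. The default baseline scales (96 for the incidence
  outcome, 173.4 for the mortality outcome) were solved numerically so that
  with zero effect the event fractions are ≈10.8% and ≈0.59% under the
  entry-age and follow-up defaults — the orders of magnitude of the target
  design.
* **Recall repeats.** Intra-individual variation has two components, both
  scaled by `recall_noise_sd`: a *day-level* perturbation of *h* itself,
  coherent across groups (whole days eaten "better" or "worse"), and
  *group-level* episodic noise in both consumption (whether the item was
  eaten that day, via a latent propensity threshold that preserves the
  marginal zero rate) and amount. The coherent component matters: because
  the score sums 22 groups, purely group-level noise averages out and the
  score would stay highly reliable at any noise level. With both
  components, reliability falls continuously from 1 (at SD 0, occasions are
  identical by construction) towards the `1/√k` floor of a k-occasion
  average, so the moderate-reliability regime (r ≈ 0.53) is attainable and
  `calibrate_recall_noise()` finds it by bisection (12 steps on [0.05, 4],
  deterministic given the seed).
* **Covariates.** Sex, ethnicity, deprivation (TDI), income, education,
  supplement use, disease history, physical activity, sitting, sleep,
  smoking, and alcohol are drawn with marginals resembling a middle-aged
  volunteer cohort and mild dependence on *h* (higher scorers more often
  female, never-smokers, active, degree-holding), giving realistic
  confounding structure without claiming any joint-distribution fidelity.

What the generator does **not** emulate: item-level dietary correlation
beyond the group structure (by default one item per group is emitted;
`multi_item = TRUE` splits group mass across items), seasonal or secular
trends, informative censoring, competing risks (other-cause mortality is
independent censoring; cause-specific hazards are the estimand), missing
covariates (synthetic data are complete, so the multiple-imputation step of
a real analysis is out of scope), and diagnosis-code ascertainment (the
outcome table arrives pre-resolved). Passing tests therefore demonstrate
the *pipeline's* correctness and calibration under a known
data-generating process, not fidelity to any particular cohort.

## Survival modelling choices

* Age is the timescale: `Surv(entry_age, exit_age, event)` with left
  truncation at entry, the standard guard against age confounding in
  cohort studies with staggered entry ages.
* Efron tie handling by default (age-scale data are tie-heavy); Breslow is
  selectable.
* Prevalent cases of each outcome are excluded before fitting, with the
  count logged.
* Proportional hazards are checked per covariate via Schoenfeld residuals;
  covariates with p < 0.05 move from the linear predictor into `strata()`.
  Only adjustment covariates are eligible — the exposure is never silently
  stratified away, and violations on it remain visible in the diagnostics
  table.
* The trend test keeps the raw continuous score in the otherwise identical
  model and reports its Wald p-value (quartile-median scoring of the trend
  is a coarser alternative and is not used).
* Interaction tests use a multiplicative term on the continuous exposure
  (single degree of freedom); significant modifiers trigger subgroup fits,
  with numeric modifiers split at the cohort median.
* The FDR family defaults to *all models of one run* (the whole forest
  table), made explicit in an `fdr_family` column; the 22 per-food-group
  models form their own family. Both choices are selectable because the
  family definition is a genuine analytic degree of freedom.
* A quartile with zero events yields a flagged warning and a non-estimable
  HR rather than an error; with extremely sparse outcomes the
  proportional-hazards diagnostic itself can fail on a singular fit, in
  which case the pipeline keeps the unstratified specification and logs
  the fact.

## Numerical and degenerate-input conventions

Quintile cutpoints require ≥ 5 non-missing values, quartile assignment ≥ 4
participants; an all-constant score distribution puts everyone in Q1 with a
degeneracy warning. Correlations are undefined (a classed error) when
either vector has zero variance. Reporting arithmetic rounds **half away
from zero** (`round_half_up()`), the convention of printed epidemiological
tables, and every contrast keeps the exact value next to the rounded
headline because published prose contrasts are often loosely rounded.
Quartile characteristic tables use the n−1 SD and serialise at printed
precision, so a written table read back reproduces its printed cells
exactly.

## Problem sizes used by the test suite

The suite exercises the scorer against an independent brute-force ranking
oracle on 100 random cohorts of up to 100 participants; estimator
calibration uses 50 replicates of n = 10,000 for hazard-ratio recovery and
CI coverage, 100 replicates of n = 2,000 for the null size of the trend
test, and n = 800 with five recall occasions for the reliability
calibration — sizes at which Monte-Carlo error is small relative to the
tolerances being checked while the whole suite stays fast on one CPU.

## Known limitations

The score is cohort-relative by construction; cutpoints from one cohort
must not be applied to another without declaring so. The centered-integer
convention cannot reproduce published non-integer score distributions (see
above). The simulator's covariate effects on the hazard default to zero —
confounding strength is a user choice, not a calibrated quantity — and its
zero-inflation/log-normal forms are modelling conveniences, not fitted
distributions. Fine–Gray competing-risk models, penalized Cox, and
time-varying coefficient models (beyond diagnostics) are out of scope.
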