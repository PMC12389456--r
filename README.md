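# hpds

Construction and survival analysis of a **heart-protective diet score
(HPDS)** — a 22-food-group, quintile-rank, signed diet-quality index built
from 24 h dietary recall data — together with the epidemiological pipeline
around it and a synthetic cohort generator that makes every stage testable
without access to restricted cohort data.

The package is for nutritional epidemiologists who want to compute a
guideline-aligned predominantly plant-based diet score (one that also
credits fish, eggs, and reduced-fat dairy) on recall-level data, relate it
to disease incidence and mortality with cause-specific Cox models, and
validate each analysis step against simulation ground truth.

## The score

Food and drink items are mapped to 22 food groups, 11 heart-protective
(direction +1: wholegrains, fruits, non-starchy and starchy vegetables,
nuts and seeds, legumes, uncoated fish, eggs, reduced-fat dairy,
tea/coffee/low-calorie drinks, homemade soup) and 11 discouraged
(direction −1: refined grains, potatoes, meat/poultry/processed meat,
coated fish, full-fat dairy, processed soup, sweets and desserts, savory
snacks, sugary drinks, artificial sweetener, unhealthy fats). Alcoholic
beverages, highly processed vegetarian alternatives, vegetable fats, and
salted nuts are deliberately excluded.

For participant *i* and group *g*, weekly intake `x_ig` (one 24 h recall
contributes `7 × amount`) is ranked into cohort quintiles; with quintile
rank `r_ig ∈ {0,…,4}` (ties at a cutpoint fall into the lower quintile) and
direction `d_g ∈ {+1, −1}`:

```
HPDS_i = Σ_g  d_g × (r_ig − 2),      HPDS_i ∈ [−44, +44]
```

so the middle quintile of every group contributes 0, the top quintile of a
heart-protective group +2, and the top quintile of a discouraged group −2.
Cohort score quartiles Q1 (lowest adherence, reference) to Q4 are the
exposure in the hazard models, which use age as the timescale with left
truncation at entry age, Efron tie handling, Schoenfeld-residual
proportional-hazards checks with a stratification fallback, a continuous-
score trend test, and Benjamini–Hochberg FDR control across the run.

## Worked example

```r
library(hpds)

tax    <- load_taxonomy()                       # packaged 22-group taxonomy
sim    <- simulate_cohort(sim_config(n = 2000, seed = 2026), tax)
intake <- aggregate_group_intake(sim$recalls, tax)
scores <- compute_hpds(intake, tax)
scores
#> <hpds_score> n = 2000; total score mean 0.62 (SD 15.86), range [-42, 44]

dat <- assemble_cox_data(scores, sim$covariates, sim$outcomes, "CVD")
#> outcome 'CVD': excluded 65 prevalent case(s), 1935 remain
fit_cox(dat, cox_spec("CVD", "score_quartiles",
                      covariates = c("sex", "tdi", "smoking")))
#> <hpds_cox_result> outcome 'CVD', exposure score_quartiles: n = 1935, events = 215
#>            term    hr ci_low ci_high     p
#> 1    quartileQ2 0.961  0.666   1.386 0.830
#> 2    quartileQ3 0.943  0.651   1.365 0.754
#> 3    quartileQ4 0.846  0.576   1.242 0.392
#> 4       sexmale 1.243  0.949   1.626 0.114
#> 5           tdi 0.993  0.949   1.039 0.773
#> 6 smokingformer 1.300  0.761   2.221 0.337
#> 7  smokingnever 1.096  0.649   1.850 0.732
#> trend p = 0.373
```

Each row is a hazard ratio versus the bottom score quartile (Q1): here the
top quartile's HR of 0.85 reflects the generator's protective latent-score
effect, attenuated by recall measurement error; at this demo cohort size
the confidence intervals are wide and the trend test is not significant.
`run_pipeline(run_config(out_dir = "out", seed = 1, n = 2000))` chains
simulate → score → analyze → report and writes CSV artifacts plus an
MD5 manifest; `inst/scripts/hpds_pipeline.R` wraps it for the shell.

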