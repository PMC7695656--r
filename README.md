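# nafldiet

Dietary pattern analysis for longitudinal NAFLD cohort studies.

`nafldiet` is for epidemiologists studying how overall dietary quality
relates to non-alcoholic fatty liver disease (NAFLD) in population-based
cohorts with repeated food-frequency questionnaire (FFQ) and
liver-imaging visits. Rather than testing isolated nutrients, it treats
diet as a whole along two complementary routes:

* **A priori indices** — fixed-definition quality scores computed from
  28 empirical food groups and nutrient totals: an adapted Mediterranean
  Diet Score (MDS, 0–8; sex-specific median cut-offs, alcohol component
  removed for a hepatic outcome), the Dutch Dietary Guidelines score
  (DDG, 0–14) and a WHO recommendation score (0–6).
* **A posteriori patterns** — population-specific patterns from
  minimum-residual (minres) factor analysis of the food-group
  correlation matrix with varimax rotation. Adherence is the
  loading-weighted intake `Λ'x`, standardized by the *baseline* mean and
  SD at both visits so change is comparable over time.

Disease associations are estimated with Bayesian random-intercept
logistic models of steatosis (and Gaussian models of BMI as a candidate
mediator) fitted in JAGS,

```
logit P(y_ij = 1) = x_ij' β + b_i,   b_i ~ N(0, σ_b²),
```

with missing covariates imputed *simultaneously* with β through
conditional models (linear / logistic / cumulative-logit), so the
reported 95% credible intervals already carry the missing-data
uncertainty. Supporting machinery includes the cohort eligibility rules
(FFQ energy window, transient-elastography reliability, alcohol misuse,
the 8 kPa steatofibrosis proxy), residual-method energy adjustment with
three-variant Spearman nutrient profiles, univariable energy-adjusted
food-group screens, and a seed-reproducible synthetic cohort generator
with a ground-truth record for parameter-recovery validation.

## Worked example

```r
library(nafldiet)

## simulate a cohort at the default study conditions, then filter
sim <- generate_cohort(sim_config(n_participants = 800, seed = 2024))
flt <- apply_exclusions(sim$cohort)
print(flt$tally)
#> Exclusion tally (first-rule attribution)
#>   participants in: 800, excluded: 306, retained: 494 (61.8%)
#>   missing_ultrasound           78
#>   ffq_missing_or_unreliable    75
#>   te_unreliable                36
#>   te_failure                   6
#>   viral_hepatitis              3
#>   alcohol_misuse               77
#>   steatogenic_drugs            15
#>   intracardiac_device          8
#>   high_lsm_no_steatosis        8

## a priori scores (medians here: MDS 4, DDG 8, WHO 2)
scored <- score_cohort(flt$cohort)
base <- scored[scored$visit == 1, ]

## a posteriori patterns: five weak, interpretable factors
R <- cor(as.matrix(base[, paste0("fg_", food_groups())]))
sol <- varimax_rotate(fit_minres(R, 5))
rownames(sol$loadings) <- food_groups()
round(sol$explained_variance_share, 2)
#> 4.36 3.79 3.68 3.48 3.35        (total 18.7% of intake variance)
defining_groups(sol)$factor1
#> "fruit" "tomatoes" "vegetables" "red_meat" "poultry" "fish"

## adherence scores with baseline scaling carried to follow-up,
## then the joint Bayesian mixed model (Model-1 covariates)
ad <- adherence_scores(sol$loadings, base)
fu <- scored[scored$visit == 2, ]
sc <- rbind(ad$scores,
            adherence_scores(sol$loadings, fu, scaling = ad$scaling)$scores)
modeled <- merge(scored, sc, by = c("id", "visit"))
fit <- fit_logistic_mixed(modeled, model_spec(
  "nafld", exposures = grep("^score_factor", names(modeled), value = TRUE),
  covariates = "model1", n_chains = 2, n_adapt = 300, n_burn = 300,
  n_iter = 600, seed = 1))
print(fit)
#>                 term estimate ci_lower ci_upper tail_prob      scale
#>                 time    0.685    0.574    0.801     0.001 odds_ratio
#>        score_factor1    0.765    0.363    1.581     0.452 odds_ratio
#>        score_factor3    0.460    0.242    0.913     0.032 odds_ratio
#>  sd_random_intercept    6.203    5.047    7.574     0.001         sd
#>  ...
```

Reading the output: odds ratios are per original unit (per year of
follow-up time, per SD of adherence). The time OR of 0.69 recovers the
configured 0.74/year decay of steatosis odds; the large intercept SD
reflects the strong within-person persistence of steatosis the generator
encodes. Diet effects are *null* in the default simulation, so the five
pattern ORs scatter around 1 — an isolated tail probability below 0.05
among five exposures at n ≈ 500, as for `score_factor3` here, is the
expected false-positive behaviour, not a signal.

`run_pipeline(pipeline_config(...))` chains the stages (filter, score,
patterns, profile, model, report) and writes every table, figure-twin
CSV and a reproducibility manifest to an output directory; a thin
command-line wrapper lives in `inst/scripts/nafldiet-pipeline.R`.

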