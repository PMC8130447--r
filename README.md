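# effectscore

Deterministic, model-agnostic effect scores for interpreting binary-outcome
clinical risk models.

## The problem

Flexible classifiers (gradient boosting, random forests, neural networks)
often predict clinical outcomes — say, incident heart failure among
type-2-diabetes patients — better than logistic regression, but they do not
come with coefficients. The usual remedies have drawbacks: a tree ensemble's
built-in "importance score" misranks correlated predictors and has no
clinical interpretation; Shapley values and LIME are expensive and
stochastic, so repeated runs disagree; random-perturbation methods feed the
model feature values that never occur in real patients.

The effect score is a deterministic alternative that works on any model
exposing a probability prediction `f(x)` for the positive class. For feature
`i` with observed value `x_i^j` in patient `j` and a chosen reference value
`x_i^r` (comorbidity absent, or the cohort's minimum age):

```
es_ij = logit(f(x_1^j, ..., x_i^j, ...)) - logit(f(x_1^j, ..., x_i^r, ...))
```

Only observed values are ever substituted. Patients sharing the same
observed value are averaged, and the per-feature effect score is

```
ES_i = sum over distinct observed values v of | mean es over patients with value v |
```

For a binary comorbidity with reference "absent", `ES_i` is the mean logit
shift among carriers: `ES = 1.75` reads "holding everything else fixed, a
patient with this condition has, on average, a logit of risk 1.75 higher
than one without it". For a logistic model this recovers exactly the fitted
`|beta_i|`; for black-box models it is the model-agnostic analogue.
Categorical and continuous features are ranked separately (their scores are
not comparable), and continuous features get a per-patient effect scatter
with a LOWESS trendline instead of a single summary.

The package also ships:

* a synthetic EHR-cohort simulator (Gaussian-copula-correlated binary
  comorbidities, uniform age, logistic outcome with recorded ground truth)
  so every behaviour is testable with known answers;
* a model-building pipeline (bootstrap augmentation, train/test split,
  cross-validated tuning of logistic regression / random forest / gradient
  boosting / neural network, ROC-AUC selection) with a leakage-safe default
  ordering;
* baseline explainers for comparison: permutation importance, exact
  enumeration Shapley values in logit space, impurity reports, and
  rank-agreement summaries.

## Worked example

```r
library(effectscore)

cohort <- simulate_cohort(n = 723, seed = 2024)   # 10 comorbidities + age + hf
mean(cohort$hf)
#> [1] 0.178

sel <- run_pipeline(cohort, "hf", bootstrap_target_n = 10723, seed = 2024)
tidy(sel)
#> # A tibble: 4 × 4
#>   model           auc n_train n_test
#>   <chr>         <dbl>   <int>  <int>
#> 1 logistic      0.928    8578    145
#> 2 neural_net    0.835    8578    145
#> 3 random_forest 0.895    8578    145
#> 4 xgboost       0.830    8578    145

spec   <- feature_spec(cohort, "hf")              # references: absent / min age
scores <- effect_scores(cohort, sel$model, spec)
rank_features(scores, kind = "categorical")
#> # A tibble: 10 × 6
#>    feature    kind   effect_score  rank n_levels clipped_predictions
#>  1 copd       binary        1.79      1        2                   0
#>  2 cancer     binary        1.60      2        2                   0
#>  3 ckd        binary        1.58      3        2                   0
#>  4 htn        binary        1.56      4        2                   0
#>  5 ihd        binary        1.48      5        2                   0
#>  6 asthma     binary        1.33      6        2                   0
#>  7 anemia     binary        1.26      7        2                   0
#>  8 arthritis  binary        1.04      8        2                   0
#>  9 af         binary        0.836     9        2                   0
#> 10 depression binary        0.526    10        2                   0
```

The top score says: in this simulated cohort, the selected model attributes
to COPD an average shift of 1.79 in the logit of heart-failure risk,
comorbidity carriers versus non-carriers, all else fixed. (The simulation
draws true log-odds between 1.0 and 1.75; at n = 723 the fitted scores
scatter around those values.) For the one continuous feature:

```r
profile <- effect_profile(cohort, sel$model, "age", spec)  # scatter + LOWESS
autoplot(profile)
```

A command-line front end over the same functions lives at
`inst/cli/effectscore` with subcommands `simulate`, `fit`, `explain`,
`plot` and `compare`; each stage writes a manifest JSON recording its seed
and output files.

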