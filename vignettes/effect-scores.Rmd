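---
title: "Effect scores: deterministic interpretation of clinical risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect scores: deterministic interpretation of clinical risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effectscore)
```

## The model being explained, and the explanation model

We consider a cohort of `n` patients described by `m` features — binary
comorbidity indicators, possibly multi-level categorical variables, and
continuous variables such as age — together with a binary outcome, and a
fitted classifier exposing only one operation: `f(x)`, the predicted
probability of the positive class for a feature row `x`. Nothing else is
assumed about the model; logistic regressions, tree ensembles and neural
networks all satisfy the contract (`as_risk_model()` adapts the common
classes, `predict_risk()` enforces outputs in [0, 1]).

The effect value of feature `i` for patient `j` is the change in the
log-odds of the prediction when the patient's observed value is swapped for
a fixed reference value, all other features held at the patient's own
values:

$$es_{i,j} = \mathrm{logit}\, f(x_1^j, \dots, x_i^j, \dots) -
             \mathrm{logit}\, f(x_1^j, \dots, x_i^r, \dots).$$

Three properties make this usable clinically:

* **Only observed values are substituted.** The counterfactual row differs
  from a real patient's row in a single coordinate, set to a value that
  occurs in the cohort — no synthetic feature combinations of the kind
  random-perturbation importance methods inject.
* **Determinism.** There is no sampling anywhere in the computation; two
  runs on the same cohort, model and configuration are bit-identical. This
  is the practical advantage over Shapley sampling and LIME.
* **Logit scale.** For a logistic model the logit of `f` is linear, so
  `es_{i,j} = beta_i (x_i^j - x_i^r)` exactly, and the method degrades
  gracefully into the familiar coefficient reading.

Patients sharing an observed value are averaged (`collapse_by_value()`),
and the per-feature score is the sum of absolute per-value means:

$$ES_i = \sum_{v \in \text{distinct values}} \left| \overline{es}_{i,(v)} \right|.$$

For a binary comorbidity with reference "absent" the reference group
contributes exactly zero (structurally — those patients are assigned 0
without a model call), so `ES` is the absolute mean logit shift among
carriers: "carriers' log-odds are on average `ES` higher". That
interpretation contract is the reason averaging-then-summing is the
default aggregation. A plain sum of `|es|` over all `n` observations is
available as `aggregate = "literal"`; it grows with carrier counts and
loses the per-patient reading, but is retained as the literal form of the
procedure's summation step.

Rankings are produced per kind. Binary/categorical features are ranked in
one list and continuous features in another, never together: a continuous
feature's score sums over its (typically all-distinct) observed values and
lives on a different scale. `rank_features()` refuses mixed lists; ties
break by ascending feature name so results are reproducible. Two further
caveats inherited by any user: scores of categorical variables with very
different level counts are not directly comparable, and effect scores
describe the fitted model, not causal effects.

## Tunable parameters

* `eps` (default `1e-7`): probabilities are clamped to `[eps, 1 - eps]`
  before the logit, since tree ensembles can emit exactly 0 or 1. The
  result metadata counts how many predictions the clamp actually moved
  (`clipped_predictions`); a large count warns that scores are dominated
  by the clamp, not the model. Shrinking `eps` never changes effects for
  models whose outputs stay inside the band.
* Reference values: binary comorbidities default to absent (0),
  categorical features to the modal level, continuous features to the
  observed minimum (so age effects read "relative to the youngest
  patients"). All are overridable per feature (`feature_spec()`); a
  reference must be an admissible level (categorical) or inside the
  observed range (continuous).
* `frac` (default 2/3): the LOWESS smoothing fraction for continuous
  effect profiles — the share of points entering each local linear fit.
  The trend is evaluated at the sorted distinct observed values and is
  deterministic.

## The synthetic cohort generator

Because the motivating cohorts are proprietary EHR extracts, the package
ships a generator (`simulate_cohort()`) whose defaults emulate a small
type-2-diabetes cohort followed for incident heart failure: 723 patients;
ten binary comorbidities (ischemic heart disease, hypertension, atrial
fibrillation, COPD, cancer, chronic kidney disease, anemia, asthma,
arthritis, depression) with true log-odds coefficients spanning 1.0-1.75,
the magnitude range typical of published effect-score tables; age uniform
on [40, 90] years entering at 0.05 logit/year, centred at the range
minimum so the youngest age is the zero-contribution reference; and an
intercept of -6.9, calibrated once by large-n simulation to an event rate
near 18.5% (about 134 cases per 723 patients). Comorbidity co-occurrence
comes from a Gaussian copula: latent multivariate-normal draws (default
exchangeable correlation 0.2) thresholded at the normal quantile of each
target prevalence, which preserves the marginals exactly while inducing
dependence. The true linear predictor of every patient is recorded for
oracle checks.

What the generator deliberately does not emulate: longitudinal encounters
and follow-up censoring, ICD-coded phenotyping, age-dependent comorbidity
onset (age and comorbidities are independent by default so that
closed-form oracles stay exact), measurement error, and missingness
(missing values are rejected at load time; imputation is out of scope).
Passing tests therefore demonstrate correctness of the computations and
the claimed invariances, not robustness to real EHR pathology.

## The model pipeline and the leakage question

`run_pipeline()` reproduces a common small-cohort workflow: bootstrap the
cohort to a larger size, split 80/20, tune each of four families (logistic
regression; random forest; gradient-boosted trees; a single-hidden-layer
feed-forward network with weight decay and a sigmoid output — a deliberately
simple, configurable network rather than any architecture search) by
k-fold cross-validation over small fixed grids, and select by test ROC-AUC,
ties going to the earlier-listed family.

Bootstrapping *before* splitting puts copies of one patient on both sides
of the split, so a flexible model can memorise its way to inflated test
AUC on pure noise. The default is therefore `leakage_safe = TRUE`: split
first, bootstrap only the training set. The literal order is kept behind
`leakage_safe = FALSE` because the contrast itself is informative; the
validation suite demonstrates it on null cohorts (no true effects), where
the safe order's selected-model test AUC stays near 0.5 while the leaky
order's random forest exceeds 0.9.

## Baselines and the correlated-twin demonstration

`permutation_importance()` shuffles observed values within a column
(never random numbers) and reports the mean ROC-AUC drop.
`exact_shapley_logit()` enumerates all `2^m` feature subsets (capped at
`m = 12`) with an interventional value function in logit space and a
single all-reference baseline, matching the effect score's reference
semantics; efficiency (`sum(phi) = v(full) - v(none)`) is checked to 1e-9,
and for additive-in-logit models each Shapley value coincides with the
corresponding effect value. `impurity_importance()` reads the ensemble's
own split-gain report and treats it as an external number.

The misranking demonstration pairs a causal comorbidity (true log-odds
1.5) with a null twin at latent correlation 0.95 and fits a random forest.
The forest's per-split feature subsampling is precisely the mechanism that
lets a correlated null feature accumulate impurity credit, so its built-in
report splits credit between the pair (the twin's median share is about a
third), while the effect score computed on the same fitted forest ranks
the causal feature first in every replicate. A deterministic greedy
booster on this clean two-feature simulation would never split on the
twin, which is why the forest is the faithful carrier of this failure
mode.

## Numerical choices and degenerate inputs

* Effects at the reference are exact zeros by construction, not computed
  differences; the reference group can never contribute rounding noise.
* Logit clipping (`eps`) is the only guard against infinite logits; all
  effect values are finite by construction.
* Rank ties: descending score, then ascending name, everywhere a ranking
  is produced (effect scores, importance reports).
* Categorical levels declared in a cohort configuration take precedence
  over observed values; observed values outside the declared set are load
  errors naming the offending level, and empty cells are load errors
  naming row and column.
* Continuous references are validated against the observed range with a
  1e-8 relative tolerance so a reference equal to an observed extremum
  survives CSV round-trips.
* `split_train_test()` uses `round(fraction * n)` training rows; a two-row
  cohort at fraction 0.5 splits 1/1.

## Problem sizes in the validation suite

The suite exercises the closed-form logistic equivalence at n = 5,000,
rank recovery under gradient boosting at n = 10,000 over 10 seeds, the
correlated-twin contrast at n = 4,000 over 20 seeds, the leakage contrast
at n = 1,000 source rows bootstrapped to 5,000 over 10 seeds, coefficient
recovery at n = 50,000, and Shapley agreement at m = 6 over 40
observations — sizes chosen so each check's sampling error is small
relative to the tolerance it asserts while the whole suite runs in a few
minutes on one CPU. The end-to-end workflow in `scripts/acceptance.R`
additionally runs the full study-scale pipeline (723 patients bootstrapped
to 10,723, five-fold tuning of all four families).

## Known limitations

* Effect scores explain the model; under strong feature correlation the
  model itself may redistribute credit, and no reference-based method can
  undo that.
* Continuous-vs-categorical comparisons are refused by design, and
  categorical features with very different level counts are only loosely
  comparable.
* The exact Shapley baseline is exponential in `m`; no sampling
  approximation is provided.
* The neural-network family is a single-hidden-layer network; it stands in
  for "a simple feed-forward model", not for deep architectures.
* The generator's prevalences and correlation are plausible defaults, not
  calibrated to any proprietary cohort.
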