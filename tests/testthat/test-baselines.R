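# Baseline explainers: permutation importance, exact Shapley values in logit
# space, impurity reports and rank comparisons.

test_that("exact Shapley values satisfy efficiency on arbitrary models", {
  co <- simulate_cohort(n = 500, seed = 51)
  spec <- feature_spec(co, "hf")
  xgb <- fit_risk_model(co, "hf", "xgboost", list(nrounds = 40, max_depth = 3), seed = 1)
  for (i in c(2, 57, 301)) {
    sh <- exact_shapley_logit(co[i, setdiff(names(co), "hf")], xgb, spec)
    expect_equal(sum(sh$shapley), attr(sh, "v_full") - attr(sh, "v_none"),
                 tolerance = 1e-9)
  }
})

test_that("for additive-in-logit models Shapley equals the core effect value", {
  co <- tiny_cohort(n = 60, m = 5, seed = 52)
  betas <- withr::with_seed(52, stats::setNames(runif(5, -1.5, 1.5), paste0("f", 1:5)))
  mod <- true_logistic_model(betas, intercept = -0.4)
  spec <- feature_spec(co, "y")
  evs <- purrr::map(names(betas), ~ effect_values(co, mod, .x, spec))
  names(evs) <- names(betas)
  for (i in c(1, 17, 42)) {
    sh <- exact_shapley_logit(co[i, paste0("f", 1:5)], mod, spec)
    core <- purrr::map_dbl(names(betas), ~ evs[[.x]]$effect[i])
    expect_equal(sh$shapley, core, tolerance = 1e-9)
  }
})

test_that("two-feature Shapley matches the hand enumeration", {
  mod <- risk_model(function(d) plogis(0.3 * d$a + 0.9 * d$b + 0.2 * d$a * d$b))
  obs <- tibble::tibble(a = 1, b = 1)
  refs <- list(a = 0, b = 0)
  v <- function(a, b) logit(predict_risk(mod, tibble::tibble(a = a, b = b)))
  phi1 <- 0.5 * (v(1, 0) - v(0, 0)) + 0.5 * (v(1, 1) - v(0, 1))
  phi2 <- 0.5 * (v(0, 1) - v(0, 0)) + 0.5 * (v(1, 1) - v(1, 0))
  sh <- exact_shapley_logit(obs, mod, references = refs)
  expect_equal(sh$shapley, c(phi1, phi2), tolerance = 1e-12)
})

test_that("the all-reference observation has all-zero Shapley values", {
  co <- tiny_cohort(n = 30, m = 4, seed = 53)
  mod <- true_logistic_model(stats::setNames(runif(4), paste0("f", 1:4)))
  spec <- feature_spec(co, "y")
  ref_row <- tibble::tibble(f1 = 0, f2 = 0, f3 = 0, f4 = 0)
  sh <- exact_shapley_logit(ref_row, mod, spec)
  expect_identical(sh$shapley, rep(0, 4))
})

test_that("enumeration refuses more than 12 features", {
  refs <- as.list(stats::setNames(rep(0, 13), paste0("f", 1:13)))
  mod <- risk_model(function(d) rep(0.5, nrow(d)))
  obs <- tibble::as_tibble(as.list(stats::setNames(rep(1, 13), paste0("f", 1:13))))
  expect_error(exact_shapley_logit(obs, mod, references = refs), "12 features")
})

test_that("permutation importance isolates features the model uses", {
  co <- tiny_cohort(n = 800, m = 3, seed = 54)
  betas <- c(f1 = 3, f2 = 0)  # f2, f3 unused
  withr::with_seed(54, co$y <- rbinom(800, 1, plogis(-0.5 + 3 * co$f1)))
  mod <- true_logistic_model(betas)
  rep1 <- permutation_importance(co, mod, "y", n_repeats = 5, seed = 55)
  expect_tbl_cols(rep1, c("method", "feature", "score", "rank"))
  # unused features: no AUC change at all
  expect_equal(rep1$score[rep1$feature %in% c("f2", "f3")], c(0, 0))
  # permuting the single informative feature destroys discrimination
  base <- attr(rep1, "baseline_auc")
  expect_lt(base - rep1$score[rep1$feature == "f1"], 0.55)
  expect_identical(
    as.data.frame(rep1),
    as.data.frame(permutation_importance(co, mod, "y", n_repeats = 5, seed = 55))
  )
  one_class <- dplyr::mutate(co, y = 1)
  expect_error(permutation_importance(one_class, mod, "y"), "single-class")
})

test_that("impurity importance is read off the fitted ensemble", {
  co <- simulate_cohort(n = 800, seed = 56)
  xgb <- fit_risk_model(co, "hf", "xgboost", list(nrounds = 30), seed = 2)
  imp <- impurity_importance(xgb)
  expect_setequal(imp$feature, setdiff(names(co), "hf"))
  expect_true(all(imp$score >= 0))
  expect_equal(imp$rank, seq_len(nrow(imp)))
  rf <- fit_risk_model(co, "hf", "random_forest", list(num.trees = 50), seed = 3)
  expect_setequal(impurity_importance(rf)$feature, setdiff(names(co), "hf"))
  expect_error(impurity_importance(true_logistic_model(c(ihd = 1))), "xgboost or ranger")
})

test_that("rank comparisons report Spearman/Kendall and displacement", {
  a <- tibble::tibble(feature = letters[1:5], rank = 1:5)
  expect_equal(attr(compare_rankings(a, a), "spearman"), 1.0)
  rev_b <- tibble::tibble(feature = letters[1:5], rank = 5:1)
  expect_equal(attr(compare_rankings(a, rev_b), "spearman"), -1.0)
  expect_error(compare_rankings(a, a[1:3, ]), "same feature set")

  # effect-score order vs a built-in impurity order over the 9 shared
  # risk factors; frozen from 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 114
  es_order <- tibble::tibble(
    feature = c("IHD", "HTN", "AF", "COPD", "Cancer", "CKD", "Anemia",
                "Arthritis", "Depression"),
    rank = 1:9
  )
  imp_order <- tibble::tibble(
    feature = c("CKD", "COPD", "Anemia", "IHD", "Depression", "AF", "HTN",
                "Cancer", "Arthritis"),
    rank = 1:9
  )
  cmp <- compare_rankings(es_order, imp_order)
  expect_equal(attr(cmp, "spearman"), 1 - 6 * 114 / (9 * (81 - 1)), tolerance = 1e-12)
  expect_equal(glance(cmp)$spearman, 0.05, tolerance = 1e-12)
  expect_equal(cmp$displacement[cmp$feature == "CKD"], -5)
})

test_that("scores without ranks are ranked before comparison", {
  a <- tibble::tibble(feature = c("x", "y", "z"), score = c(0.3, 0.9, 0.1))
  b <- tibble::tibble(feature = c("x", "y", "z"), effect_score = c(1.0, 2.0, 0.5))
  cmp <- compare_rankings(a, b)
  expect_equal(attr(cmp, "spearman"), 1.0)
})
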