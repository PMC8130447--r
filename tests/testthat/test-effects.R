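# Core effect-score computation: per-observation logit differences against a
# reference, duplicate-value averaging, aggregation and ranking.

test_that("effect values match the closed form for additive-in-logit models", {
  for (seed in 1:3) {
    co <- tiny_cohort(n = 300, m = 4, seed = seed)
    betas <- withr::with_seed(seed, stats::setNames(runif(4, -2, 2), paste0("f", 1:4)))
    mod <- true_logistic_model(betas, intercept = -0.5)
    spec <- feature_spec(co, "y")
    for (nm in names(betas)) {
      ev <- effect_values(co, mod, nm, spec)
      expect_equal(ev$effect, betas[[nm]] * (co[[nm]] - 0), tolerance = 1e-9)
    }
  }
})

test_that("observations at the reference get exactly zero without a model call", {
  co <- tiny_cohort(n = 100, m = 2, seed = 2)
  calls <- 0L
  counting_model <- risk_model(function(d) {
    calls <<- calls + nrow(d)
    plogis(0.8 * d$f1 - 0.3 * d$f2)
  })
  spec <- feature_spec(co, "y")
  ev <- effect_values(co, counting_model, "f1", spec)
  n_carriers <- sum(co$f1 == 1)
  expect_identical(ev$effect[co$f1 == 0], rep(0, sum(co$f1 == 0)))
  # two prediction batches (observed + counterfactual), carriers only
  expect_identical(calls, 2L * n_carriers)
})

test_that("a model emitting values outside [0, 1] violates the contract", {
  co <- tiny_cohort(n = 20, m = 2, seed = 3)
  bad <- risk_model(function(d) rep(1.5, nrow(d)), label = "broken")
  spec <- feature_spec(co, "y")
  expect_error(effect_values(co, bad, "f1", spec), "contract")
})

test_that("collapse_by_value averages within distinct observed values", {
  ev <- structure(
    tibble::tibble(
      .row = 1:4, feature = "f", value = c(0, 0, 1, 1), effect = c(0, 0, 2, 1)
    ),
    class = c("effect_values", "tbl_df", "tbl", "data.frame")
  )
  got <- collapse_by_value(ev)
  expect_equal(got$value, c(0, 1))
  expect_equal(got$mean_effect, c(0, 1.5))
  expect_equal(got$n, c(2L, 2L))

  # all observations sharing one value collapse to a single group
  ev$value <- rep(1, 4)
  one <- collapse_by_value(ev)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_effect, mean(ev$effect))

  # all-unique continuous values: identity
  ev$value <- c(1.1, 2.2, 3.3, 4.4)
  idt <- collapse_by_value(ev)
  expect_equal(idt$mean_effect, ev$effect)
})

test_that("binary effect score equals |beta| under a logistic model", {
  co <- tiny_cohort(n = 400, m = 3, seed = 4)
  betas <- c(f1 = 1.75, f2 = -0.8, f3 = 0.3)
  mod <- true_logistic_model(betas, intercept = -1)
  spec <- feature_spec(co, "y")
  es <- effect_scores(co, mod, spec)
  expect_equal(
    es$effect_score[match(names(betas), es$feature)],
    abs(unname(betas)),
    tolerance = 1e-9
  )
  # the literal mode instead sums |es| over all n observations
  lit <- effect_scores(co, mod, spec, aggregate = "literal")
  expect_equal(
    lit$effect_score[lit$feature == "f1"],
    1.75 * sum(co$f1 == 1),
    tolerance = 1e-9
  )
})

test_that("a feature the model ignores scores exactly zero", {
  co <- tiny_cohort(n = 150, m = 3, seed = 5)
  mod <- true_logistic_model(c(f1 = 1.2, f2 = -0.4))  # f3 never read
  spec <- feature_spec(co, "y")
  es <- effect_scores(co, mod, spec)
  expect_identical(es$effect_score[es$feature == "f3"], 0)
})

test_that("ranking is non-increasing with alphabetical tie-breaks, one kind at a time", {
  scores <- tibble::tibble(
    feature = c("IHD", "HTN", "AF", "COPD", "Cancer", "CKD", "Anemia",
                "Asthma", "Arthritis", "Depression"),
    kind = "binary",
    effect_score = c(1.75, 1.68, 1.52, 1.52, 1.48, 1.40, 1.36, 1.34, 1.02, 1.00)
  )
  ranked <- rank_features(scores)
  # tie at 1.52 resolved by ascending name (AF before COPD)
  expect_equal(
    ranked$feature,
    c("IHD", "HTN", "AF", "COPD", "Cancer", "CKD", "Anemia", "Asthma",
      "Arthritis", "Depression")
  )
  expect_true(all(diff(ranked$effect_score) <= 0))
  expect_equal(ranked$rank, 1:10)

  # all-equal scores fall back to alphabetical order
  flat <- dplyr::mutate(scores, effect_score = 1)
  expect_equal(rank_features(flat)$feature, sort(scores$feature))

  # a single feature ranks first
  expect_equal(rank_features(scores[1, ])$rank, 1L)

  # continuous and categorical features never share a ranking
  mixed <- dplyr::bind_rows(
    scores, tibble::tibble(feature = "age", kind = "continuous", effect_score = 99)
  )
  expect_error(rank_features(mixed), "separately")
  expect_equal(nrow(rank_features(mixed, kind = "continuous")), 1L)
})

test_that("swapping a binary feature's levels negates level means, preserves ES", {
  co <- tiny_cohort(n = 250, m = 2, seed = 6)
  betas <- c(f1 = 1.3, f2 = -0.7)
  mod <- true_logistic_model(betas)
  spec <- feature_spec(co, "y")
  es <- effect_scores(co, mod, spec, features = "f1")

  # relabel: carriers become non-carriers; the model must see original coding
  flipped <- dplyr::mutate(co, f1 = 1 - f1)
  mod_flip <- risk_model(function(d) {
    mod$predict(dplyr::mutate(d, f1 = 1 - f1))
  })
  spec_flip <- feature_spec(flipped, "y")
  es_flip <- effect_scores(flipped, mod_flip, spec_flip, features = "f1")

  expect_equal(es_flip$effect_score, es$effect_score, tolerance = 1e-9)
  m1 <- attr(es, "level_means")
  m2 <- attr(es_flip, "level_means")
  expect_equal(
    m2$mean_effect[m2$value == 1],
    -m1$mean_effect[m1$value == 1],
    tolerance = 1e-9
  )
})

test_that("the full core is deterministic on identical inputs", {
  co <- tiny_cohort(n = 200, m = 3, seed = 7)
  mod <- true_logistic_model(c(f1 = 0.9, f2 = -0.2, f3 = 0.5))
  spec <- feature_spec(co, "y")
  a <- effect_scores(co, mod, spec)
  b <- effect_scores(co, mod, spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "values"), attr(b, "values"))
})

test_that("shrinking eps leaves effects unchanged when predictions avoid the clip band", {
  co <- tiny_cohort(n = 150, m = 2, seed = 8)
  mod <- true_logistic_model(c(f1 = 1.0, f2 = 0.6))  # probabilities well inside (0,1)
  spec <- feature_spec(co, "y")
  a <- effect_values(co, mod, "f1", spec, eps = 1e-5)
  b <- effect_values(co, mod, "f1", spec, eps = 1e-9)
  expect_identical(a$effect, b$effect)
  expect_identical(attr(a, "n_clipped"), 0L)
})
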