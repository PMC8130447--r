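# Shared fixtures: cohorts and models built in code at test time.

# A risk model whose logit is exactly linear in the named features:
# the closed-form oracle for effect values (es_i = beta_i * (x_i - ref_i)).
true_logistic_model <- function(betas, intercept = 0, label = "true logistic") {
  risk_model(
    function(d) {
      x <- as.matrix(as.data.frame(d)[, names(betas), drop = FALSE])
      plogis(intercept + as.numeric(x %*% betas))
    },
    label = label, features = names(betas)
  )
}

# Small independent-Bernoulli cohort with an outcome column.
tiny_cohort <- function(n = 200, m = 3, prev = 0.4, seed = 1, outcome = "y") {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rbinom(n * m, 1, prev), n, m))
    names(x) <- paste0("f", seq_len(m))
    x[[outcome]] <- rbinom(n, 1, 0.3)
    tibble::as_tibble(x)
  })
}

# Null cohort: outcome carries no signal from any feature.
null_cohort <- function(n, seed) {
  simulate_cohort(
    n = n,
    coefficients = stats::setNames(rep(0, 10), names(default_coefficients())),
    age_coefficient = 0, intercept = -1.5, seed = seed
  )
}

expect_tbl_cols <- function(x, cols) {
  expect_true(all(cols %in% names(x)), info = paste(setdiff(cols, names(x)), collapse = ", "))
}
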