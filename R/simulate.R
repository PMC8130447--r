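#' Correlated binary comorbidities via a Gaussian copula
#'
#' Draws latent multivariate-normal vectors with the given correlation and
#' thresholds each margin at the normal quantile of `1 - prevalence`, so each
#' column is Bernoulli with exactly the requested marginal probability while
#' the latent correlation induces realistic co-occurrence between conditions.
#'
#' @param latent_correlation Either a single off-diagonal value in `[0, 1)`
#'   (expanded to an exchangeable correlation matrix) or a symmetric
#'   positive-definite correlation matrix with unit diagonal.
#' @param prevalences Named numeric vector of marginal probabilities, each
#'   strictly inside (0, 1); names become column names.
#' @param n Number of patients to draw.
#' @param seed Integer seed; the draw is reproducible under it. `NULL` uses
#'   the current RNG state.
#' @return A tibble of 0/1 columns, one per comorbidity.
#'
#' @examples
#' gaussian_copula_binary(0.3, c(htn = 0.5, ihd = 0.2), n = 5, seed = 1)
#' @export
gaussian_copula_binary <- function(latent_correlation, prevalences, n, seed = NULL) {
  if (is.null(names(prevalences)) || any(!nzchar(names(prevalences)))) {
    abort("`prevalences` must be a fully named vector.")
  }
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("Prevalences must lie strictly inside (0, 1).")
  }
  m <- length(prevalences)
  R <- expand_correlation(latent_correlation, m)
  draw <- function() {
    z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = R)
    z <- matrix(z, nrow = n)
    x <- sweep(z, 2, qnorm(1 - prevalences), FUN = ">") * 1L
    colnames(x) <- names(prevalences)
    as_tibble(as.data.frame(x))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

expand_correlation <- function(latent_correlation, m) {
  if (is.matrix(latent_correlation)) {
    R <- latent_correlation
    if (nrow(R) != m || ncol(R) != m) {
      abort(sprintf("Correlation matrix must be %d x %d.", m, m))
    }
    if (any(abs(R - t(R)) > 1e-12) || any(abs(diag(R) - 1) > 1e-12)) {
      abort("Correlation matrix must be symmetric with unit diagonal.")
    }
  } else {
    stopifnot(length(latent_correlation) == 1)
    R <- matrix(latent_correlation, m, m)
    diag(R) <- 1
  }
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) abort("Latent correlation matrix is not positive definite.")
  R
}

#' Default generative parameters for the synthetic diabetes cohort
#'
#' Ten binary comorbidities commonly studied as heart-failure risk factors,
#' with log-odds coefficients spanning the 1.0-1.75 range typical of such
#' cohorts and plausible marginal prevalences among older type-2-diabetes
#' patients. These are the named defaults of [simulate_cohort()].
#'
#' @return A named numeric vector.
#' @export
default_coefficients <- function() {
  c(
    ihd = 1.75, htn = 1.68, af = 1.52, copd = 1.52, cancer = 1.48,
    ckd = 1.40, anemia = 1.36, asthma = 1.34, arthritis = 1.02, depression = 1.00
  )
}

#' @rdname default_coefficients
#' @export
default_prevalences <- function() {
  c(
    ihd = 0.20, htn = 0.55, af = 0.12, copd = 0.15, cancer = 0.12,
    ckd = 0.18, anemia = 0.20, asthma = 0.10, arthritis = 0.25, depression = 0.20
  )
}

#' Simulate an EHR-like cohort with known ground truth
#'
#' Generates a patient-by-feature table emulating a type-2-diabetes cohort
#' followed for incident heart failure: correlated binary comorbidities from a
#' Gaussian copula, age uniform on a range, and a binary outcome drawn from a
#' logistic model whose coefficients are recorded as ground truth. Age enters
#' the linear predictor centred at the range minimum, so the youngest age is
#' the natural zero-contribution reference. Optional quadratic-age and
#' pairwise-interaction terms make the outcome nonlinear in the features.
#'
#' @param n Cohort size (default 723 patients).
#' @param prevalences Named marginal comorbidity probabilities.
#' @param latent_correlation Scalar exchangeable value or full matrix for the
#'   copula latents (default 0.2).
#' @param coefficients Named log-odds coefficients, aligned with
#'   `prevalences`. A coefficient of 0 makes a feature a null feature.
#' @param intercept Log-odds intercept; the default (-6.9) gives an event
#'   rate near 18.5% under the other defaults (roughly 134 cases per 723
#'   patients).
#' @param age_range Two ascending numbers, ages drawn uniformly between them
#'   (default 40-90 years).
#' @param age_coefficient Log-odds per year of age (default 0.05).
#' @param age_quadratic Coefficient on `(age - min)^2`; default 0 (linear).
#' @param interactions Optional data frame with columns `f1`, `f2`, `beta`
#'   adding `beta * x_f1 * x_f2` terms.
#' @param outcome Name of the outcome column (default `"hf"`).
#' @param seed Integer seed for reproducibility.
#'
#' @return A tibble with the comorbidity columns, `age`, and the 0/1 outcome.
#'   Attributes `true_params` (the full generative configuration) and
#'   `true_logit` (each patient's generative linear predictor) are attached
#'   for oracle checks.
#' @export
simulate_cohort <- function(n = 723,
                            prevalences = default_prevalences(),
                            latent_correlation = 0.2,
                            coefficients = default_coefficients(),
                            intercept = -6.9,
                            age_range = c(40, 90),
                            age_coefficient = 0.05,
                            age_quadratic = 0,
                            interactions = NULL,
                            outcome = "hf",
                            seed = NULL) {
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("`age_range` must be two ascending numbers.")
  }
  if (!setequal(names(coefficients), names(prevalences))) {
    abort("`coefficients` and `prevalences` must be named for the same features.")
  }
  coefficients <- coefficients[names(prevalences)]

  build <- function() {
    com <- gaussian_copula_binary(latent_correlation, prevalences, n, seed = NULL)
    age <- runif(n, age_range[1], age_range[2])
    eta <- intercept +
      as.numeric(as.matrix(com) %*% coefficients) +
      age_coefficient * (age - age_range[1]) +
      age_quadratic * (age - age_range[1])^2
    if (!is.null(interactions)) {
      for (k in seq_len(nrow(interactions))) {
        eta <- eta + interactions$beta[k] * com[[interactions$f1[k]]] * com[[interactions$f2[k]]]
      }
    }
    y <- rbinom(n, 1, plogis(eta))
    out <- dplyr::bind_cols(com, tibble(age = age))
    out[[outcome]] <- y
    structure(
      out,
      true_params = list(
        n = n, prevalences = prevalences,
        latent_correlation = latent_correlation,
        coefficients = coefficients, intercept = intercept,
        age_range = age_range, age_coefficient = age_coefficient,
        age_quadratic = age_quadratic, interactions = interactions,
        outcome = outcome, seed = seed
      ),
      true_logit = eta
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
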