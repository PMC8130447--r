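#' Permutation feature importance
#'
#' For each feature, the mean drop in ROC-AUC over `n_repeats` independent
#' within-column permutations of its observed values (observed values are
#' shuffled rather than replaced with random numbers, so no impossible
#' feature values enter the model).
#'
#' @param data Cohort including the outcome column.
#' @param model A `risk_model` (or coercible).
#' @param outcome Name of the 0/1 outcome column.
#' @param n_repeats Number of permutations per feature (default 10).
#' @param seed Integer seed.
#' @param features Features to score; default all non-outcome columns.
#' @return An `importance_report` tibble with columns `method`, `feature`,
#'   `score` (mean AUC drop) and `rank`; attributes record `n_repeats`,
#'   `seed` and the baseline AUC.
#' @export
permutation_importance <- function(data, model, outcome, n_repeats = 10,
                                   seed = NULL, features = NULL) {
  if (n_repeats < 1) abort("`n_repeats` must be at least 1.")
  if (length(unique(data[[outcome]])) < 2) {
    abort("ROC-AUC is undefined on a single-class cohort.")
  }
  model <- as_risk_model(model)
  features <- features %||% setdiff(names(data), outcome)
  x <- data[, setdiff(names(data), outcome), drop = FALSE]
  y <- data[[outcome]]
  base_auc <- auc_score(y, predict_risk(model, x))

  run <- function() {
    purrr::map_dfr(features, function(nm) {
      drops <- purrr::map_dbl(seq_len(n_repeats), function(r) {
        xp <- x
        xp[[nm]] <- sample(xp[[nm]])
        base_auc - auc_score(y, predict_risk(model, xp))
      })
      tibble(method = "permutation", feature = nm, score = mean(drops))
    })
  }
  rep <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rep <- rep %>%
    dplyr::arrange(dplyr::desc(score), feature) %>%
    dplyr::mutate(rank = dplyr::row_number())
  structure(rep,
    n_repeats = n_repeats, seed = seed, baseline_auc = base_auc,
    class = c("importance_report", class(rep))
  )
}

#' Impurity importance reported by a fitted tree ensemble
#'
#' Extracts the ensemble's own split-based importance (total gain for
#' gradient-boosted trees, impurity decrease for random forests) and treats
#' it as an external number — the built-in ranking known to misbehave when
#' predictors are correlated. Features the ensemble never split on get
#' score 0.
#'
#' @param model A `risk_model` wrapping an `xgb.Booster` or `ranger` fit.
#' @return An `importance_report` tibble (`method`, `feature`, `score`,
#'   `rank`).
#' @export
impurity_importance <- function(model) {
  model <- as_risk_model(model)
  fit <- model$fit
  if (inherits(fit, "xgb.Booster")) {
    imp <- xgboost::xgb.importance(model = fit)
    scores <- stats::setNames(rep(0, length(model$features)), model$features)
    scores[imp$Feature] <- imp$Gain
  } else if (inherits(fit, "ranger")) {
    if (is.null(fit$variable.importance)) {
      abort("Fit the ranger forest with `importance = \"impurity\"`.")
    }
    scores <- fit$variable.importance
  } else {
    abort("Impurity importance requires an xgboost or ranger fit.")
  }
  rep <- tibble(method = "impurity", feature = names(scores), score = as.numeric(scores)) %>%
    dplyr::arrange(dplyr::desc(score), feature) %>%
    dplyr::mutate(rank = dplyr::row_number())
  structure(rep, class = c("importance_report", class(rep)))
}

#' Exact Shapley values in logit space for one observation
#'
#' Full-enumeration Shapley attribution with an interventional value
#' function: `v(S)` is the logit of the model's prediction with features in
#' `S` at the observation's values and all other features at their reference
#' values. The returned values satisfy the efficiency axiom:
#' `sum(phi) = v(all features) - v(none)` — the all-reference baseline.
#' Enumeration costs `2^m` model evaluations, so `m` is capped at 12.
#'
#' @param observation A one-row data frame over the cohort's features.
#' @param model A `risk_model` (or coercible).
#' @param spec A `feature_spec` carrying the reference values (or supply
#'   `references` directly).
#' @param references Optional named list of per-feature reference values,
#'   used instead of `spec`.
#' @param eps Logit clipping bound.
#' @return A tibble with columns `feature`, `value`, `reference`, `shapley`
#'   (logit units) and attributes `v_full`, `v_none`.
#' @export
exact_shapley_logit <- function(observation, model, spec = NULL,
                                references = NULL, eps = 1e-7) {
  model <- as_risk_model(model)
  if (is.null(references)) {
    if (is.null(spec)) abort("Supply `spec` or `references`.")
    references <- stats::setNames(spec$reference, spec$name)
  }
  feats <- names(references)
  m <- length(feats)
  if (m > 12) {
    abort(paste(
      "Exact enumeration is limited to 12 features (2^m subsets);",
      "use a sampling approximation (not provided here) for larger m."
    ))
  }
  if (nrow(observation) != 1) abort("`observation` must be a single row.")

  n_masks <- bitwShiftL(1L, m)
  masks <- seq_len(n_masks) - 1L
  # rows: features with bit set -> observed value, else reference
  grid <- observation[rep(1L, n_masks), feats, drop = FALSE]
  for (i in seq_len(m)) {
    off <- bitwAnd(masks, bitwShiftL(1L, i - 1L)) == 0L
    grid[[feats[i]]][off] <- references[[feats[i]]]
  }
  v <- logit(predict_risk(model, grid), eps)

  sizes <- vapply(masks, function(mm) sum(bitwAnd(mm, bitwShiftL(1L, 0:(m - 1))) != 0L), integer(1))
  w <- factorial(0:(m - 1)) * factorial(m - 1 - (0:(m - 1))) / factorial(m)
  phi <- vapply(seq_len(m), function(i) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    idx_wo <- without + 1L
    idx_wi <- without + bit + 1L
    sum(w[sizes[idx_wo] + 1L] * (v[idx_wi] - v[idx_wo]))
  }, numeric(1))

  structure(
    tibble(
      feature = feats,
      value = purrr::map_chr(feats, ~ format(observation[[.x]][1])),
      reference = purrr::map_chr(feats, ~ format(references[[.x]])),
      shapley = phi
    ),
    v_full = v[n_masks], v_none = v[1],
    class = c("shapley_values", c("tbl_df", "tbl", "data.frame"))
  )
}

#' Compare two feature rankings
#'
#' Joins two importance or effect-score reports on feature, computes
#' per-feature rank displacement, and Spearman and Kendall rank correlations.
#'
#' @param report_a,report_b Tibbles with a `feature` column and either a
#'   `rank` or a `score`/`effect_score` column to rank by.
#' @return A tibble (`feature`, `rank_a`, `rank_b`, `displacement`) with
#'   attributes `spearman` and `kendall`; see also its `glance()` method.
#' @export
compare_rankings <- function(report_a, report_b) {
  ra <- extract_ranks(report_a, "a")
  rb <- extract_ranks(report_b, "b")
  if (!setequal(ra$feature, rb$feature)) {
    abort("The two reports must rank the same feature set.")
  }
  out <- dplyr::inner_join(ra, rb, by = "feature") %>%
    dplyr::mutate(displacement = rank_b - rank_a) %>%
    dplyr::arrange(rank_a)
  structure(
    out,
    spearman = cor(out$rank_a, out$rank_b, method = "spearman"),
    kendall = cor(out$rank_a, out$rank_b, method = "kendall"),
    class = c("ranking_comparison", class(out))
  )
}

extract_ranks <- function(report, suffix) {
  if (!"feature" %in% names(report)) abort("Reports need a `feature` column.")
  if ("rank" %in% names(report)) {
    r <- report$rank
  } else {
    score_col <- intersect(c("score", "effect_score", "shapley"), names(report))[1]
    if (is.na(score_col)) abort("Reports need a `rank` or score column.")
    r <- rank(-report[[score_col]], ties.method = "first")
  }
  tibble(feature = report$feature, !!paste0("rank_", suffix) := r)
}
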