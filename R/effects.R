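#' Per-observation effect values for one feature
#'
#' The atomic quantity of the effect-score method: for each patient `j`, the
#' logit of the model's predicted risk at the observed row minus the logit at
#' the same row with feature `i` set to its reference value,
#' `es_ij = logit(f(x_1^j, ..., x_i^j, ...)) - logit(f(x_1^j, ..., x_i^r, ...))`.
#' Patients whose observed value already equals the reference contribute
#' exactly 0, without a model call; only observed values are ever substituted,
#' never synthesized ones.
#'
#' @param data Cohort data frame (may include the outcome column; the model
#'   reads only its own features).
#' @param model A `risk_model` or anything `as_risk_model()` accepts.
#' @param feature Name of the feature to perturb.
#' @param spec A `feature_spec` for the cohort (carries the reference value).
#' @param eps Logit clipping bound, see [logit()].
#'
#' @return A tibble of class `effect_values` with columns `.row`, `feature`,
#'   `value` (the observed value) and `effect` (logit units), one row per
#'   observation, and attributes `reference`, `kind`, `eps` and `n_clipped`
#'   (how many predictions the logit clamp moved).
#'
#' @examples
#' cohort <- tibble::tibble(ihd = c(0, 0, 1, 1), age = c(40, 55, 60, 72))
#' mod <- risk_model(function(d) plogis(-2 + 1.75 * d$ihd + 0.05 * (d$age - 40)),
#'                   label = "true model")
#' spec <- feature_spec(cbind(cohort, hf = c(0, 0, 1, 1)), "hf")
#' effect_values(cohort, mod, "ihd", spec)   # carriers get exactly 1.75
#' @export
effect_values <- function(data, model, feature, spec, eps = 1e-7) {
  model <- as_risk_model(model)
  row <- spec_row(spec, feature)
  ref <- row$reference[[1]]
  x <- data[[feature]]
  if (anyNA(x)) abort(sprintf("Feature '%s' contains missing values.", feature))

  n <- nrow(data)
  es <- numeric(n)
  clipped <- 0L
  idx <- which(x != ref)
  if (length(idx) > 0) {
    obs <- data[idx, , drop = FALSE]
    cf <- obs
    cf[[feature]] <- vctrs_recycle(ref, length(idx))
    p_obs <- predict_risk(model, obs)
    p_ref <- predict_risk(model, cf)
    es[idx] <- logit(p_obs, eps) - logit(p_ref, eps)
    clipped <- n_clipped(p_obs, eps) + n_clipped(p_ref, eps)
  }

  out <- tibble(.row = seq_len(n), feature = feature, value = x, effect = es)
  structure(
    out,
    reference = ref, kind = row$kind[[1]], eps = eps, n_clipped = clipped,
    class = c("effect_values", class(out))
  )
}

vctrs_recycle <- function(x, n) rep(x, length.out = n)

#' Average effect values within distinct observed feature values
#'
#' Observations sharing the same observed value of the feature are collapsed
#' to the arithmetic mean of their effect values (duplicated values are
#' averaged, not summed). For a continuous feature with all-unique values this
#' is the identity.
#'
#' @param effects An `effect_values` tibble from [effect_values()].
#' @return A tibble with one row per distinct observed value: `value`,
#'   `mean_effect` and the group size `n`.
#' @export
collapse_by_value <- function(effects) {
  if (nrow(effects) == 0) abort("`effects` is empty.")
  effects %>%
    dplyr::group_by(value) %>%
    dplyr::summarise(mean_effect = mean(effect), n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(value)
}

#' Aggregate effect values into a single effect score
#'
#' The per-feature effect score ES is the sum of absolute per-distinct-value
#' mean effects (default, `aggregate = "grouped"`). For a binary comorbidity
#' with reference "absent" this equals the absolute mean logit shift among
#' carriers, so a score of 1.75 reads: holding all other features fixed, the
#' logit of the outcome is on average 1.75 higher for a patient with the
#' condition than for one without it. `aggregate = "literal"` instead sums
#' `|es|` over all n observations without collapsing duplicates.
#'
#' @param effects An `effect_values` tibble.
#' @param aggregate `"grouped"` (collapse duplicates, then sum absolute group
#'   means; the default) or `"literal"` (plain sum of absolute
#'   per-observation values).
#' @return A single nonnegative number in logit units.
#' @export
effect_score <- function(effects, aggregate = c("grouped", "literal")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "literal") {
    return(sum(abs(effects$effect)))
  }
  sum(abs(collapse_by_value(effects)$mean_effect))
}

#' Effect scores for every feature of a cohort
#'
#' Runs the full effect-score computation for each feature: per-observation
#' logit differences against the feature's reference value, duplicate-value
#' averaging, aggregation, and ranking within feature kind (categorical-like
#' and continuous features are ranked separately and must not be compared
#' against each other).
#'
#' @inheritParams effect_values
#' @param features Character vector of features to score; default all features
#'   in `spec`.
#' @param aggregate See [effect_score()].
#'
#' @return A tibble of class `effect_scores` with columns `feature`, `kind`,
#'   `effect_score`, `rank` (within kind, descending score, ties broken by
#'   name), `n_levels` (distinct observed values) and `clipped_predictions`.
#'   Attributes `values` (per-observation effects, long) and `level_means`
#'   (per-distinct-value means) carry the underlying detail;
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods are
#'   provided.
#' @export
effect_scores <- function(data, model, spec, features = NULL, eps = 1e-7,
                          aggregate = c("grouped", "literal")) {
  aggregate <- match.arg(aggregate)
  model <- as_risk_model(model)
  features <- features %||% spec$name
  validate_feature_spec(spec[match(features, spec$name), ], data)

  per_feature <- purrr::map(features, function(nm) {
    ev <- effect_values(data, model, nm, spec, eps = eps)
    lm <- collapse_by_value(ev)
    list(
      row = tibble(
        feature = nm,
        kind = attr(ev, "kind"),
        effect_score = if (aggregate == "literal") sum(abs(ev$effect)) else sum(abs(lm$mean_effect)),
        n_levels = nrow(lm),
        clipped_predictions = attr(ev, "n_clipped")
      ),
      values = as_tibble(ev),
      level_means = dplyr::mutate(lm, feature = nm, .before = 1)
    )
  })

  scores <- purrr::map_dfr(per_feature, "row")
  # rank within kind; categorical-like kinds (binary/categorical) never mix
  # with continuous in one ranking
  scores <- scores %>%
    dplyr::mutate(.rank_kind = ifelse(kind == "continuous", "continuous", "categorical")) %>%
    dplyr::group_by(.rank_kind) %>%
    dplyr::arrange(dplyr::desc(effect_score), feature, .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select(feature, kind, effect_score, rank, n_levels, clipped_predictions)

  structure(
    scores,
    values = purrr::map_dfr(per_feature, "values"),
    level_means = purrr::map_dfr(per_feature, "level_means"),
    eps = eps, aggregate = aggregate, model_label = model$label, n_obs = nrow(data),
    class = c("effect_scores", class(scores))
  )
}

#' Rank features of one kind by effect score
#'
#' Orders features non-increasingly by effect score, ties broken by ascending
#' feature name. Continuous and categorical features are never ranked in one
#' list: comparing a continuous feature's score with a categorical one's is
#' not meaningful, and mixing kinds is an error.
#'
#' @param scores A tibble with columns `feature`, `kind` and `effect_score`
#'   (e.g. from [effect_scores()]).
#' @param kind Optional kind to filter to (`"binary"`/`"categorical"` count as
#'   one categorical-like group, `"continuous"` as the other).
#' @return The filtered tibble, ordered, with a recomputed `rank` column.
#' @export
rank_features <- function(scores, kind = NULL) {
  stopifnot(all(c("feature", "kind", "effect_score") %in% names(scores)))
  group_of <- function(k) ifelse(k == "continuous", "continuous", "categorical")
  if (!is.null(kind)) {
    scores <- scores[group_of(scores$kind) == group_of(kind), , drop = FALSE]
  }
  if (nrow(scores) == 0) abort("No features of the requested kind.")
  if (length(unique(group_of(scores$kind))) > 1) {
    abort(paste(
      "Cannot rank continuous and categorical features in one list;",
      "their effect scores are not comparable. Rank each kind separately."
    ))
  }
  scores %>%
    dplyr::arrange(dplyr::desc(effect_score), feature) %>%
    dplyr::mutate(rank = dplyr::row_number())
}
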