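#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an effect-score result
#'
#' @param x An [effect_scores()] result.
#' @param detail `"scores"` (one row per feature, the default), `"levels"`
#'   (per-distinct-value mean effects) or `"observations"` (per-patient
#'   effect values, long).
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy effect_scores
#' @export
tidy.effect_scores <- function(x, detail = c("scores", "levels", "observations"), ...) {
  detail <- match.arg(detail)
  switch(detail,
    scores = as_tibble(x),
    levels = attr(x, "level_means"),
    observations = attr(x, "values")
  )
}

#' One-row summary of an effect-score result
#'
#' @param x An [effect_scores()] result.
#' @param ... Ignored.
#' @return A one-row tibble: number of observations and features, clipping
#'   bound, aggregation mode, model label and total clipped predictions.
#' @method glance effect_scores
#' @export
glance.effect_scores <- function(x, ...) {
  tibble(
    n_obs = attr(x, "n_obs"),
    n_features = nrow(x),
    eps = attr(x, "eps"),
    aggregate = attr(x, "aggregate"),
    model = attr(x, "model_label"),
    clipped_predictions = sum(x$clipped_predictions)
  )
}

#' @export
print.effect_scores <- function(x, ...) {
  cat(sprintf(
    "# Effect scores: %d feature(s), %d observation(s), model '%s'\n",
    nrow(x), attr(x, "n_obs"), attr(x, "model_label")
  ))
  NextMethod()
}

#' Summaries of a ranking comparison
#'
#' @param x A [compare_rankings()] result.
#' @param ... Ignored.
#' @return A one-row tibble with `spearman`, `kendall`, `n_features` and
#'   `max_displacement`.
#' @method glance ranking_comparison
#' @export
glance.ranking_comparison <- function(x, ...) {
  tibble(
    spearman = attr(x, "spearman"),
    kendall = attr(x, "kendall"),
    n_features = nrow(x),
    max_displacement = max(abs(x$displacement))
  )
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf(
    "# Ranking comparison: Spearman %.3f, Kendall %.3f\n",
    attr(x, "spearman"), attr(x, "kendall")
  ))
  NextMethod()
}

#' Per-model report of a model selection
#'
#' @param x A [fit_and_select()] result.
#' @param ... Ignored.
#' @return The AUC report tibble (`model`, `auc`, `n_train`, `n_test`).
#' @method tidy model_selection
#' @export
tidy.model_selection <- function(x, ...) x$report

#' @rdname tidy.model_selection
#' @method glance model_selection
#' @export
glance.model_selection <- function(x, ...) {
  tibble(
    best = x$best,
    best_auc = x$report$auc[x$report$model == x$best],
    n_models = nrow(x$report),
    n_failed = sum(is.na(x$report$auc))
  )
}
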