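#' LOWESS trend through per-observation effect values
#'
#' Locally weighted scatterplot smoothing (local linear regression) of effect
#' values against a continuous feature, evaluated at the sorted distinct
#' observed values. This is the population-level trendline drawn through the
#' per-patient effect scatter (e.g. effect of age on the logit of risk,
#' relative to the youngest reference age). Deterministic for fixed inputs.
#'
#' @param x Numeric vector of observed continuous feature values (>= 10).
#' @param es Effect values of the same length (logit units).
#' @param frac Smoothing fraction in `(0, 1]`: the share of points that enters
#'   each local fit. Default `2/3`.
#' @return A tibble with columns `x` (sorted distinct values) and `trend`.
#' @export
lowess_trend <- function(x, es, frac = 2 / 3) {
  if (length(x) != length(es)) abort("`x` and `es` must have equal length.")
  if (length(x) < 10) abort("LOWESS trend requires at least 10 points.")
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac > 1) {
    abort("`frac` must be a single number in (0, 1].")
  }
  sm <- stats::lowess(x, es, f = frac)
  tibble(x = sm$x, trend = sm$y) %>% dplyr::distinct(x, .keep_all = TRUE)
}

#' Effect profile of a continuous feature
#'
#' Computes per-observation effect values for one continuous feature and the
#' LOWESS trend through them — the scatter-plus-trendline view of how the
#' feature shifts the logit of risk across its observed range, relative to
#' its reference value.
#'
#' @inheritParams effect_values
#' @param frac LOWESS smoothing fraction, see [lowess_trend()].
#' @return A tibble of class `effect_profile` with columns `value` and
#'   `effect`, and attributes `trend` (the LOWESS tibble), `feature`,
#'   `reference`. Plot it with [ggplot2::autoplot()].
#' @export
effect_profile <- function(data, model, feature, spec, eps = 1e-7, frac = 2 / 3) {
  row <- spec_row(spec, feature)
  if (row$kind[[1]] != "continuous") {
    abort(sprintf("Effect profiles are for continuous features; '%s' is %s.",
                  feature, row$kind[[1]]))
  }
  ev <- effect_values(data, model, feature, spec, eps = eps)
  out <- tibble(value = ev$value, effect = ev$effect)
  structure(
    out,
    trend = lowess_trend(ev$value, ev$effect, frac = frac),
    feature = feature, reference = attr(ev, "reference"),
    class = c("effect_profile", class(out))
  )
}

#' @rdname effect_profile
#' @param object,x An `effect_profile`.
#' @param ... Ignored.
#' @method autoplot effect_profile
#' @export
autoplot.effect_profile <- function(object, ...) {
  trend <- attr(object, "trend")
  feature <- attr(object, "feature")
  ref <- attr(object, "reference")
  ggplot2::ggplot(object, ggplot2::aes(x = value, y = effect)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.9) +
    ggplot2::geom_line(
      data = trend, ggplot2::aes(x = x, y = trend),
      colour = "#b2182b", linewidth = 1
    ) +
    ggplot2::labs(
      x = feature,
      y = sprintf("effect on logit of risk (vs %s = %s)", feature, format(ref)),
      title = sprintf("Effect profile of %s", feature),
      subtitle = "points: per-patient logit differences; line: LOWESS trend"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname effect_profile
#' @export
plot.effect_profile <- function(x, ...) print(autoplot.effect_profile(x, ...))

#' Bar chart of effect scores
#'
#' @param object An `effect_scores` tibble.
#' @param kind Which kind group to show (default categorical-like features).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot effect_scores
#' @export
autoplot.effect_scores <- function(object, kind = "categorical", ...) {
  ranked <- rank_features(object, kind = kind)
  ggplot2::ggplot(
    ranked,
    ggplot2::aes(
      x = effect_score,
      y = stats::reorder(feature, effect_score)
    )
  ) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = "effect score (logit units)", y = NULL,
      title = sprintf("Effect scores (%s features)", kind)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.effect_scores <- function(x, ...) print(autoplot.effect_scores(x, ...))
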