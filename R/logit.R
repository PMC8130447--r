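#' Clipped log-odds transform
#'
#' Maps probabilities to logit units, clamping to `[eps, 1 - eps]` first so
#' that predictions of exactly 0 or 1 (common for tree ensembles) give large
#' finite values instead of infinities.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param eps Clipping bound, a single number in `(0, 0.5)`. Default `1e-7`.
#'
#' @return Numeric vector `log(p' / (1 - p'))` with `p' = clamp(p, eps, 1 - eps)`.
#'   All values are finite.
#'
#' @examples
#' logit(0.5)            # 0
#' logit(plogis(1.75))   # 1.75
#' logit(0)              # large negative but finite
#' @export
logit <- function(p, eps = 1e-7) {
  if (!is.numeric(eps) || length(eps) != 1 || is.na(eps) || eps <= 0 || eps >= 0.5) {
    abort("`eps` must be a single number strictly between 0 and 0.5.")
  }
  if (!is.numeric(p)) {
    abort("`p` must be numeric.")
  }
  bad <- !is.na(p) & (p < 0 | p > 1 | !is.finite(p))
  if (any(bad)) {
    abort(sprintf(
      "`p` must lie in [0, 1]; offending value(s): %s",
      paste(utils::head(format(p[bad]), 5), collapse = ", ")
    ))
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# number of predictions the clamp actually moved
n_clipped <- function(p, eps) {
  sum(!is.na(p) & (p < eps | p > 1 - eps))
}
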