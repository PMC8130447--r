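#' Build a feature specification for a cohort table
#'
#' A feature specification records, for every predictor column, its kind
#' (`"binary"`, `"categorical"` or `"continuous"`), its admissible levels, and
#' its reference value: the counterfactual value a patient's feature is set to
#' when computing effect values (e.g. comorbidity absent, or the cohort's
#' minimum age). Kinds are inferred from the data unless overridden:
#' 0/1 columns are binary, character/factor/logical columns and numeric
#' columns with few distinct values are categorical, the rest continuous.
#'
#' Default references follow the conventions of the method: absent (0) for a
#' binary comorbidity, the modal level for a categorical feature, and the
#' observed minimum for a continuous one (so that, e.g., age is compared
#' against the youngest patients in the cohort).
#'
#' @param data Patient-by-feature data frame.
#' @param outcome Name of the binary outcome column (excluded from the spec).
#' @param kinds Optional named character vector overriding inferred kinds.
#' @param references Optional named list/vector overriding default reference
#'   values, e.g. `list(age = 40)`.
#' @param levels Optional named list of admissible level sets for categorical
#'   features (default: the sorted distinct observed values).
#' @param max_categorical_levels Numeric columns with at most this many
#'   distinct values (and not 0/1) are treated as categorical. Default 10.
#'
#' @return A tibble of class `feature_spec` with columns `name`, `kind`,
#'   `levels` (list column; empty for continuous features) and `reference`
#'   (list column of scalars).
#'
#' @examples
#' cohort <- tibble::tibble(htn = c(0, 1, 1), age = c(44, 61, 73), hf = c(0, 0, 1))
#' feature_spec(cohort, outcome = "hf", references = list(age = 44))
#' @export
feature_spec <- function(data, outcome, kinds = NULL, references = NULL,
                         levels = NULL, max_categorical_levels = 10) {
  stopifnot(is.data.frame(data))
  if (!is.character(outcome) || length(outcome) != 1 || !outcome %in% names(data)) {
    abort("`outcome` must name a column of `data`.")
  }
  feats <- setdiff(names(data), outcome)
  if (length(feats) == 0) abort("No feature columns besides the outcome.")
  if (anyDuplicated(feats)) abort("Feature names must be unique.")

  spec <- purrr::map_dfr(feats, function(nm) {
    x <- data[[nm]]
    kind <- kinds[[nm]] %||% infer_kind(x, max_categorical_levels)
    if (!kind %in% c("binary", "categorical", "continuous")) {
      abort(sprintf("Unknown kind '%s' for feature '%s'.", kind, nm))
    }
    lev <- switch(kind,
      binary = if (is.logical(x)) c(FALSE, TRUE) else c(0, 1),
      categorical = levels[[nm]] %||% sort(unique(x)),
      continuous = NULL
    )
    ref <- references[[nm]] %||% default_reference(x, kind, lev)
    tibble(
      name = nm, kind = kind,
      levels = list(lev), reference = list(ref)
    )
  })
  class(spec) <- c("feature_spec", class(spec))
  validate_feature_spec(spec, data)
  spec
}

infer_kind <- function(x, max_categorical_levels) {
  if (is.character(x) || is.factor(x)) return("categorical")
  if (is.logical(x) || all(x %in% c(0, 1))) return("binary")
  if (length(unique(x)) <= max_categorical_levels) return("categorical")
  "continuous"
}

default_reference <- function(x, kind, levels) {
  switch(kind,
    binary = if (is.logical(x)) FALSE else 0,
    # modal level, ties to the first admissible level
    categorical = {
      tab <- table(factor(x, levels = as.character(levels)))
      lev <- names(tab)[which.max(tab)]
      if (is.numeric(levels)) as.numeric(lev) else lev
    },
    continuous = min(x)
  )
}

#' Validate a feature specification against a cohort
#'
#' Checks that feature names are unique and present, that references of
#' binary/categorical features are admissible levels, that observed
#' categorical values all lie in the declared levels, and that continuous
#' references fall inside the observed range.
#'
#' @param spec A `feature_spec` tibble.
#' @param data The cohort the spec is applied to.
#' @return `spec`, invisibly, or an error naming the offending feature.
#' @export
validate_feature_spec <- function(spec, data) {
  if (anyDuplicated(spec$name)) abort("Feature names in the spec must be unique.")
  missing <- setdiff(spec$name, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Feature(s) absent from data: %s", paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[[i]]
    kind <- spec$kind[[i]]
    ref <- spec$reference[[i]]
    x <- data[[nm]]
    if (anyNA(x)) abort(sprintf("Feature '%s' contains missing values.", nm))
    if (kind %in% c("binary", "categorical")) {
      lev <- spec$levels[[i]]
      extra <- setdiff(unique(x), lev)
      if (length(extra) > 0) {
        abort(sprintf(
          "Feature '%s' has value(s) outside its declared levels: %s",
          nm, paste(utils::head(extra, 5), collapse = ", ")
        ))
      }
      if (!ref %in% lev) {
        abort(sprintf("Reference '%s' of feature '%s' is not an admissible level.", ref, nm))
      }
    } else {
      # small tolerance so a reference equal to an observed extremum survives
      # text round-trips of the data
      tol <- 1e-8 * max(1, abs(ref))
      if (ref < min(x) - tol || ref > max(x) + tol) {
        abort(sprintf(
          "Reference %s of continuous feature '%s' lies outside the observed range [%s, %s].",
          format(ref), nm, format(min(x)), format(max(x))
        ))
      }
    }
  }
  invisible(spec)
}

spec_row <- function(spec, feature) {
  i <- match(feature, spec$name)
  if (is.na(i)) abort(sprintf("Feature '%s' is not in the spec.", feature))
  spec[i, ]
}
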