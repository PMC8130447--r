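#' Wrap a fitted model into the probability-prediction contract
#'
#' All explainers in this package interact with a model only through one
#' contract: given rows over the cohort's features, return the probability of
#' the positive class for each row, deterministically and inside `[0, 1]`.
#' `as_risk_model()` adapts the common fitted-model classes to that contract;
#' `risk_model()` wraps an arbitrary prediction function.
#'
#' @param object A fitted model: a `glm` (binomial family), `ranger`
#'   probability forest, `xgb.Booster`, `nnet`, or a function
#'   `f(newdata) -> probabilities`.
#' @param label Descriptive label used in reports.
#' @param features Character vector of feature column names the model
#'   consumes, in order (required for `xgb.Booster`; inferred otherwise when
#'   possible).
#' @param ... Passed on to methods.
#'
#' @return An object of class `risk_model`: a list with elements `predict`
#'   (the contract function), `label`, `features`, and `fit` (the wrapped
#'   object, or `NULL`).
#' @export
as_risk_model <- function(object, ...) UseMethod("as_risk_model")

#' @rdname as_risk_model
#' @export
risk_model <- function(object, label = "custom", features = NULL) {
  if (!is.function(object)) abort("`risk_model()` expects a prediction function.")
  structure(
    list(predict = object, label = label, features = features, fit = NULL),
    class = "risk_model"
  )
}

#' @rdname as_risk_model
#' @export
as_risk_model.risk_model <- function(object, ...) object

#' @rdname as_risk_model
#' @export
as_risk_model.function <- function(object, label = "custom", features = NULL, ...) {
  risk_model(object, label = label, features = features)
}

#' @rdname as_risk_model
#' @export
as_risk_model.glm <- function(object, label = "logistic", ...) {
  if (!identical(object$family$family, "binomial")) {
    abort("Only binomial-family glm fits satisfy the probability contract.")
  }
  feats <- attr(object$terms, "term.labels")
  structure(
    list(
      predict = function(newdata) {
        as.numeric(stats::predict(object, newdata = newdata, type = "response"))
      },
      label = label, features = feats, fit = object
    ),
    class = "risk_model"
  )
}

#' @rdname as_risk_model
#' @export
as_risk_model.ranger <- function(object, label = "random_forest", ...) {
  if (object$treetype != "Probability estimation") {
    abort("Fit ranger with `probability = TRUE` to obtain class probabilities.")
  }
  feats <- object$forest$independent.variable.names
  structure(
    list(
      predict = function(newdata) {
        pr <- stats::predict(object, data = as.data.frame(newdata))$predictions
        as.numeric(pr[, "1"])
      },
      label = label, features = feats, fit = object
    ),
    class = "risk_model"
  )
}

#' @rdname as_risk_model
#' @export
as_risk_model.xgb.Booster <- function(object, label = "xgboost", features = NULL, ...) {
  feats <- features %||% object$feature_names
  if (is.null(feats)) abort("Supply `features` for an xgb.Booster without stored names.")
  structure(
    list(
      predict = function(newdata) {
        m <- as.matrix(as.data.frame(newdata)[, feats, drop = FALSE])
        as.numeric(stats::predict(object, m))
      },
      label = label, features = feats, fit = object
    ),
    class = "risk_model"
  )
}

#' @rdname as_risk_model
#' @export
as_risk_model.nnet <- function(object, label = "neural_net", ...) {
  feats <- object$coefnames
  structure(
    list(
      predict = function(newdata) {
        as.numeric(stats::predict(object, newdata = as.data.frame(newdata), type = "raw"))
      },
      label = label, features = feats, fit = object
    ),
    class = "risk_model"
  )
}

#' Predict positive-class probabilities under the contract
#'
#' Calls the wrapped model and enforces the contract: every output must be a
#' probability in `[0, 1]`, one per input row.
#'
#' @param model A `risk_model`.
#' @param newdata Data frame of observation rows.
#' @return Numeric vector of probabilities, one per row of `newdata`.
#' @export
predict_risk <- function(model, newdata) {
  model <- as_risk_model(model)
  p <- model$predict(newdata)
  if (length(p) != nrow(newdata)) {
    abort(sprintf(
      "Model '%s' returned %d predictions for %d rows.",
      model$label, length(p), nrow(newdata)
    ))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf(
      "Model '%s' violated the probability contract: outputs outside [0, 1].",
      model$label
    ))
  }
  p
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "<risk_model> %s (%d features)\n", x$label,
    if (is.null(x$features)) NA_integer_ else length(x$features)
  ))
  invisible(x)
}
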