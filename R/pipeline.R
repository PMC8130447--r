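#' Bootstrap a cohort to a larger size
#'
#' Samples `target_n` rows uniformly with replacement from the cohort — the
#' augmentation step used when a source cohort is small (e.g. growing 723
#' patients to 10,723 rows before model fitting).
#'
#' @param data Cohort data frame.
#' @param target_n Number of rows to draw; must be at least `nrow(data)`.
#' @param seed Integer seed; resample is deterministic under it.
#' @return A tibble of `target_n` rows drawn from `data`.
#' @export
bootstrap_resample <- function(data, target_n, seed = NULL) {
  if (target_n < nrow(data)) {
    abort("`target_n` must be at least the source cohort size.")
  }
  draw <- function() sample.int(nrow(data), target_n, replace = TRUE)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  as_tibble(data[idx, , drop = FALSE])
}

#' Random train/test split
#'
#' Disjoint row partition with `round(train_fraction * n)` training rows,
#' deterministic under the seed. Requires both outcome classes to be present.
#'
#' @param data Cohort data frame.
#' @param outcome Name of the 0/1 outcome column.
#' @param train_fraction Proportion of rows assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, outcome, train_fraction = 0.8, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  if (length(unique(data[[outcome]])) < 2) {
    abort("Both outcome classes must be present to split for model fitting.")
  }
  n <- nrow(data)
  n_train <- round(train_fraction * n)
  draw <- function() sample.int(n, n_train)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(
    train = as_tibble(data[idx, , drop = FALSE]),
    test = as_tibble(data[-idx, , drop = FALSE])
  )
}

#' ROC-AUC of predicted probabilities
#'
#' @param y 0/1 outcomes.
#' @param p Predicted probabilities of the positive class.
#' @return AUC in `[0, 1]` (0.5 = no discrimination).
#' @export
auc_score <- function(y, p) {
  if (length(unique(y)) < 2) abort("AUC is undefined on a single-class outcome.")
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Fit one model family under the probability contract
#'
#' Families: `"logistic"` ([stats::glm]), `"random_forest"` ([ranger::ranger]
#' probability forest with impurity importance), `"xgboost"` (gradient-boosted
#' trees via [xgboost::xgb.train]) and `"neural_net"` (a single-hidden-layer
#' feed-forward network with weight decay via [nnet::nnet], sigmoid output).
#'
#' @param data Training data frame.
#' @param outcome Name of the 0/1 outcome column.
#' @param family One of the four family labels.
#' @param params Named list of hyperparameters (family-specific; see the
#'   defaults in the source of [default_model_zoo()]).
#' @param seed Integer seed for the stochastic fitters.
#' @return A [risk_model()].
#' @export
fit_risk_model <- function(data, outcome, family, params = list(), seed = 1) {
  feats <- setdiff(names(data), outcome)
  x <- as.data.frame(data[, feats, drop = FALSE])
  y <- data[[outcome]]
  switch(family,
    logistic = {
      fml <- stats::reformulate(feats, response = outcome)
      as_risk_model(glm(fml, data = as.data.frame(data), family = binomial()))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = x, y = factor(y, levels = c(0, 1)),
        probability = TRUE, importance = "impurity",
        num.trees = params$num.trees %||% 300,
        mtry = params$mtry %||% NULL,
        min.node.size = params$min.node.size %||% 10,
        seed = seed, num.threads = 1
      )
      as_risk_model(fit)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      fit <- withr::with_seed(seed, xgboost::xgb.train(
        params = list(
          objective = "binary:logistic",
          max_depth = params$max_depth %||% 3,
          eta = params$eta %||% 0.1,
          subsample = params$subsample %||% 1,
          nthread = 1
        ),
        data = dtrain,
        nrounds = params$nrounds %||% 100,
        verbose = 0
      ))
      as_risk_model(fit, features = feats)
    },
    neural_net = {
      fml <- stats::reformulate(feats, response = outcome)
      fit <- withr::with_seed(seed, nnet::nnet(
        fml, data = as.data.frame(data),
        size = params$size %||% 8,
        decay = params$decay %||% 0.01,
        maxit = params$maxit %||% 300,
        entropy = TRUE, trace = FALSE
      ))
      as_risk_model(fit)
    },
    abort(sprintf("Unknown model family '%s'.", family))
  )
}

#' Default model zoo with small tuning grids
#'
#' The four families of the model-building workflow, each with a small fixed
#' hyperparameter grid explored by cross-validation. Order matters: AUC ties
#' during selection are broken in favour of the earlier-listed family.
#'
#' @return A named list of `list(family, grid)` entries; `grid` is a data
#'   frame with one row per hyperparameter combination.
#' @export
default_model_zoo <- function() {
  list(
    logistic = list(family = "logistic", grid = tibble()),
    neural_net = list(
      family = "neural_net",
      grid = tidyr::expand_grid(size = c(5, 10), decay = c(0.01, 0.1))
    ),
    random_forest = list(
      family = "random_forest",
      grid = tibble(min.node.size = c(1, 10))
    ),
    xgboost = list(
      family = "xgboost",
      grid = tidyr::expand_grid(max_depth = c(2, 4), nrounds = c(50, 150))
    )
  )
}

cv_tune <- function(data, outcome, family, grid, cv_folds, seed) {
  if (nrow(grid) <= 1) {
    return(if (nrow(grid) == 1) as.list(grid[1, ]) else list())
  }
  n <- nrow(data)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_auc <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    aucs <- purrr::map_dbl(seq_len(cv_folds), function(k) {
      tr <- data[folds != k, , drop = FALSE]
      va <- data[folds == k, , drop = FALSE]
      if (length(unique(va[[outcome]])) < 2) return(NA_real_)
      m <- fit_risk_model(tr, outcome, family, params, seed = seed + k)
      auc_score(va[[outcome]], predict_risk(m, va[, setdiff(names(va), outcome)]))
    })
    mean(aucs, na.rm = TRUE)
  })
  as.list(grid[which.max(cv_auc), ])
}

#' Fit a model zoo and select the best by test ROC-AUC
#'
#' For each family: tune hyperparameters over its grid by `cv_folds`-fold
#' cross-validation on the training set, refit on the full training set, and
#' evaluate ROC-AUC on the held-out test set. The model with the highest test
#' AUC is selected; ties are broken by zoo order. A family whose fit fails is
#' recorded in the report and skipped.
#'
#' @param train,test Training and test cohorts.
#' @param outcome Name of the 0/1 outcome column.
#' @param model_zoo See [default_model_zoo()].
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed driving tuning folds and stochastic fitters.
#' @return A list of class `model_selection`: `model` (the selected
#'   [risk_model()]), `report` (tibble with columns `model`, `auc`, `n_train`,
#'   `n_test`), and `fits` (all fitted models by family).
#' @export
fit_and_select <- function(train, test, outcome, model_zoo = default_model_zoo(),
                           cv_folds = 5, seed = 1) {
  if (length(model_zoo) == 0) abort("`model_zoo` must be nonempty.")
  feats <- setdiff(names(train), outcome)
  fits <- list()
  report <- purrr::imap_dfr(model_zoo, function(entry, nm) {
    res <- tryCatch({
      params <- cv_tune(train, outcome, entry$family, entry$grid, cv_folds, seed)
      fit <- fit_risk_model(train, outcome, entry$family, params, seed = seed)
      auc <- auc_score(test[[outcome]], predict_risk(fit, test[, feats, drop = FALSE]))
      fits[[nm]] <<- fit
      tibble(model = nm, auc = auc, n_train = nrow(train), n_test = nrow(test))
    }, error = function(e) {
      tibble(model = nm, auc = NA_real_, n_train = nrow(train), n_test = nrow(test))
    })
    res
  })
  if (all(is.na(report$auc))) abort("Every model family failed to fit.")
  best <- report$model[which.max(report$auc)]
  structure(
    list(model = fits[[best]], report = report, best = best),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> best: %s\n", x$best))
  print(x$report)
  invisible(x)
}

#' Full model-building pipeline
#'
#' Reproduces the bootstrap / split / tune / select workflow at configurable
#' scale. With `leakage_safe = TRUE` (default) the cohort is split first and
#' only the training set is bootstrapped, so no row appears on both sides of
#' the split. With `leakage_safe = FALSE` the cohort is bootstrapped to
#' `bootstrap_target_n` and then split — the workflow order that duplicates
#' rows across the split and can inflate test AUC of flexible models.
#'
#' @param data Source cohort.
#' @param outcome Name of the 0/1 outcome column.
#' @param bootstrap_target_n Size after bootstrap augmentation (default:
#'   source size + 10,000). Set to `NULL` to skip bootstrapping.
#' @param train_fraction Train share of the split (default 0.8).
#' @param leakage_safe Split before bootstrapping? Default `TRUE`.
#' @inheritParams fit_and_select
#' @return A `model_selection` (see [fit_and_select()]) with the `train` and
#'   `test` sets attached as elements.
#' @export
run_pipeline <- function(data, outcome,
                         bootstrap_target_n = nrow(data) + 10000,
                         train_fraction = 0.8,
                         model_zoo = default_model_zoo(),
                         cv_folds = 5,
                         leakage_safe = TRUE,
                         seed = 1) {
  if (is.null(bootstrap_target_n)) {
    parts <- split_train_test(data, outcome, train_fraction, seed = seed)
  } else if (leakage_safe) {
    parts <- split_train_test(data, outcome, train_fraction, seed = seed)
    n_tr <- round(train_fraction * bootstrap_target_n)
    parts$train <- bootstrap_resample(parts$train, n_tr, seed = seed + 1)
  } else {
    boot <- bootstrap_resample(data, bootstrap_target_n, seed = seed + 1)
    parts <- split_train_test(boot, outcome, train_fraction, seed = seed)
  }
  sel <- fit_and_select(parts$train, parts$test, outcome,
    model_zoo = model_zoo, cv_folds = cv_folds, seed = seed
  )
  sel$train <- parts$train
  sel$test <- parts$test
  sel
}
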