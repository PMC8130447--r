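#' Read and validate a cohort CSV
#'
#' Reads a comma-separated, header-first patient-by-feature table and
#' validates it against a feature configuration: no missing values anywhere,
#' every categorical value inside its declared levels, outcome column present
#' and 0/1. Failures are reported with the offending row/column.
#'
#' @param path Path to the CSV file.
#' @param config Either a path to a JSON configuration (as written by
#'   [write_cohort_config()]) or a list with elements `outcome` and
#'   optionally `features` (each with `name`, `kind`, `levels`, `reference`).
#' @return A list with elements `data` (tibble), `spec` (a [feature_spec()])
#'   and `outcome`.
#' @export
read_cohort <- function(path, config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  outcome <- config$outcome
  if (is.null(outcome)) abort("Cohort config must name the outcome column.")
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column '%s' is absent from %s.", outcome, path))
  }
  na_cells <- which(is.na(as.matrix(data)), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    first <- na_cells[1, ]
    abort(sprintf(
      "Missing value at row %d, column '%s' (%d missing cell(s) in total).",
      first["row"], names(data)[first["col"]], nrow(na_cells)
    ))
  }
  if (!all(data[[outcome]] %in% c(0, 1))) {
    abort(sprintf("Outcome column '%s' must be 0/1.", outcome))
  }

  spec <- cohort_spec_from_config(data, outcome, config)
  validate_feature_spec(spec, data)
  list(data = data, spec = spec, outcome = outcome)
}

cohort_spec_from_config <- function(data, outcome, config) {
  feats <- config$features
  if (is.null(feats) || length(feats) == 0) {
    return(feature_spec(data, outcome))
  }
  if (is.data.frame(feats)) feats <- purrr::transpose(feats)
  kinds <- purrr::set_names(
    purrr::map_chr(feats, "kind"),
    purrr::map_chr(feats, "name")
  )
  refs <- purrr::set_names(
    purrr::map(feats, ~ .x$reference %||% NULL),
    purrr::map_chr(feats, "name")
  )
  refs <- purrr::compact(refs)
  levs <- purrr::set_names(
    purrr::map(feats, ~ unlist(.x$levels) %||% NULL),
    purrr::map_chr(feats, "name")
  )
  levs <- purrr::compact(levs)
  feature_spec(data, outcome, kinds = kinds, references = refs, levels = levs)
}

#' Write a cohort CSV (and optionally its configuration)
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Write a cohort configuration JSON
#'
#' Serializes the outcome name and the feature spec (kinds, levels,
#' references) so that [read_cohort()] can re-validate the CSV.
#'
#' @param spec A [feature_spec()].
#' @param outcome Outcome column name.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(spec, outcome, path) {
  cfg <- list(
    outcome = outcome,
    features = purrr::map(seq_len(nrow(spec)), function(i) {
      list(
        name = spec$name[[i]], kind = spec$kind[[i]],
        levels = spec$levels[[i]], reference = spec$reference[[i]]
      )
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write an effect-score report as CSV
#'
#' Columns: `feature`, `kind`, `effect_score`, `rank`, `n_levels`,
#' `clipped_predictions`.
#'
#' @param scores An [effect_scores()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_scores <- function(scores, path) {
  readr::write_csv(as_tibble(scores), path, progress = FALSE)
  invisible(path)
}

#' Write per-observation effects as CSV
#'
#' Columns: `observation_id`, `feature`, `observed_value`, `effect_value`.
#'
#' @param scores An [effect_scores()] result (its per-observation detail is
#'   carried in the `values` attribute).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_values <- function(scores, path) {
  values <- attr(scores, "values")
  out <- tibble(
    observation_id = values$.row,
    feature = values$feature,
    observed_value = values$value,
    effect_value = values$effect
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A small provenance record for a tool run: package version, seed(s), input
#' and output paths, and a configuration digest, written as JSON so that
#' every output file can be traced to the run that produced it.
#'
#' @param stage Label of the pipeline stage (e.g. `"simulate"`).
#' @param seed Integer seed(s) the stage used.
#' @param inputs,outputs Character vectors of file paths.
#' @param config Optional configuration list, stored verbatim.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(stage, seed, inputs = character(), outputs = character(),
                         config = NULL) {
  structure(
    list(
      tool = "effectscore",
      version = as.character(utils::packageVersion("effectscore")),
      stage = stage,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      inputs = as.character(inputs),
      outputs = as.character(outputs),
      config = config
    ),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
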