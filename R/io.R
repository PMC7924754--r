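#' Read and write feature tables as delimited text
#'
#' Feature tables are stored as a wide CSV (rows = features, columns =
#' `feature_id`, `mz`, `rt`, then one column per sample) with sample
#' metadata in a sidecar CSV (`sample_id`, `root_type`, `genotype`,
#' `replicate`).
#'
#' @param path Path to the feature CSV.
#' @param samples_path Path to the sample-metadata CSV (default: `path`
#'   with a `_samples.csv` suffix).
#' @return A list with `features` and `samples` tibbles.
#' @export
read_feature_table <- function(path,
                               samples_path = sub("\\.csv$", "_samples.csv", path)) {
  features <- readr::read_csv(path, show_col_types = FALSE)
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  check_feature_table(features)
  missing <- setdiff(sample_cols(features), samples$sample_id)
  if (length(missing)) {
    abort(paste("sample columns without metadata:", paste(missing, collapse = ", ")))
  }
  list(features = features, samples = samples)
}

#' @rdname read_feature_table
#' @param features,samples Tibbles to write.
#' @param truth Optional ground-truth list, written as JSON next to the
#'   features.
#' @export
write_feature_table <- function(features, samples, path,
                                samples_path = sub("\\.csv$", "_samples.csv", path),
                                truth = NULL) {
  readr::write_csv(features, path)
  readr::write_csv(samples, samples_path)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, sub("\\.csv$", "_truth.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "rootcue", mustWork = TRUE)
}

#' Packaged reference tables for cue cross-referencing
#'
#' Three small plain-text tables ship with the package:
#' * `load_activity_table()`: root metabolites reported to elicit
#'   behavioral responses in western corn rootworm larvae (attractants,
#'   feeding stimulants, host-recognition cues). Rows whose `source_tag`
#'   starts with `"placeholder"` are stand-ins completing the table to its
#'   documented length where the underlying supplementary listing is not
#'   redistributable; the behaviorally decisive entries are transcribed
#'   from the primary literature.
#' * `load_identified_metabolites()`: putatively identified root
#'   metabolites with their root-type enrichment class.
#' * `load_synonyms()`: explicit compound-name synonym map used by
#'   [normalize_compound()].
#'
#' @return A tibble.
#' @export
load_activity_table <- function() {
  readr::read_csv(fixture_path("behavioral_activity.csv"),
                  show_col_types = FALSE)
}

#' @rdname load_activity_table
#' @export
load_identified_metabolites <- function() {
  readr::read_csv(fixture_path("identified_metabolites.csv"),
                  show_col_types = FALSE)
}

#' @rdname load_activity_table
#' @export
load_synonyms <- function() {
  readr::read_csv(fixture_path("compound_synonyms.csv"),
                  show_col_types = FALSE)
}
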