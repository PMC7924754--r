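# Internal helpers shared across modules.

#' Derive a stage-specific random seed from one global seed
#'
#' All generators in the package are driven by a single integer seed. When
#' several generators run inside one pipeline, each stage receives its own
#' sub-seed so that adding or removing a stage never perturbs the draws of
#' the others. The rule is deliberately simple and documented: stage `k`
#' (1-based, in the fixed stage order of [run_pipeline()]) uses
#' `(seed + 7919 * k) mod (2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed below 2^31.
#' @export
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((as.numeric(seed) + 7919 * as.numeric(stage)) %% (2^31 - 1))
}

# Column names of a feature table that hold per-sample intensities.
sample_cols <- function(features) {
  setdiff(names(features), c("feature_id", "mz", "rt", "compound_id"))
}

# Extract the intensity matrix (features x samples) from a feature tibble.
intensity_matrix <- function(features) {
  cols <- sample_cols(features)
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$feature_id
  m
}

check_feature_table <- function(features) {
  if (!all(c("feature_id", "mz", "rt") %in% names(features))) {
    abort("`features` must have columns feature_id, mz and rt plus one column per sample.")
  }
  if (anyDuplicated(features$feature_id)) abort("feature_id values must be unique.")
  if (any(features$rt < 0)) abort("retention times must be >= 0.")
  x <- intensity_matrix(features)
  if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
    abort("intensities must be finite and >= 0.")
  }
  invisible(features)
}

check_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(paste0("`", name, "` must be a positive integer."))
  }
  invisible(as.integer(x))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must lie in [0, 1]."))
  }
  invisible(x)
}
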