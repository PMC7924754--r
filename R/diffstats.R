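#' Inverse hyperbolic sine intensity normalization
#'
#' `arcsinh(x) = ln(x + sqrt(x^2 + 1))`: a variance-stabilizing transform
#' for positive, right-skewed peak-area data that, unlike the logarithm, is
#' defined (and zero) at zero. For large x it approaches `ln(2x)`.
#'
#' @param x Non-negative numeric vector of raw intensities.
#' @return Transformed values, same length as `x`.
#' @examples
#' arcsinh(c(0, 1, 1e6))
#' @export
arcsinh <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("`arcsinh()` requires non-negative intensities.")
  asinh(x)
}

#' Two-sample Student t test on transformed intensities
#'
#' Pooled-variance (Student) two-sided t test by default; `welch = TRUE`
#' drops the equal-variance assumption. Degenerate inputs are handled
#' explicitly: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means gives `p = 0` with a warning.
#'
#' @param a,b Numeric vectors (each length >= 2, finite).
#' @param welch Use the Welch unequal-variance test instead of pooled.
#' @return Named list with `statistic` and `p_value`.
#' @export
feature_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    abort("each group needs >= 2 finite observations.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1))
    warn("zero variance with unequal means: p = 0.")
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0))
  }
  fit <- t.test(a, b, var.equal = !welch)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up BH adjusted p-values, clipped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Fold change between two group means
#'
#' Ratio of the larger to the smaller raw-intensity mean (always >= 1),
#' with a direction label naming the higher group. A zero mean in one group
#' gives an infinite ratio; two zero means give ratio 1 with direction
#' `"undefined"`.
#'
#' @param mean_a,mean_b Non-negative group means (vectorized).
#' @param labels Length-2 character vector naming the groups.
#' @return Tibble with `ratio` and `direction`.
#' @export
fold_change <- function(mean_a, mean_b, labels = c("A", "B")) {
  if (any(mean_a < 0 | mean_b < 0)) abort("means must be >= 0.")
  both_zero <- mean_a == 0 & mean_b == 0
  ratio <- pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
  ratio[both_zero] <- 1
  direction <- dplyr::case_when(
    both_zero ~ "undefined",
    mean_a == mean_b ~ "none",
    mean_a > mean_b ~ labels[1],
    .default = labels[2]
  )
  tibble::tibble(ratio = ratio, direction = direction)
}

#' Classify differential features (volcano classification)
#'
#' Assigns each feature to `"<group>_enriched"` or `"not_significant"`
#' according to a significance threshold on the (adjusted or raw) p-value
#' and a fold-change cut-off on raw means. Infinite fold changes (one group
#' mean zero) pass the fold-change criterion.
#'
#' @param results Tibble with columns `fold_change`, `direction`, `p_value`
#'   and (when `use = "q"`) `q_value`, as produced by [diff_features()].
#' @param alpha Significance level (default 0.05).
#' @param fc_cut Fold-change cut-off (default 2).
#' @param use Threshold the BH-adjusted `"q"` (default) or raw `"p"` value.
#' @return `results` with a `class` column added or replaced.
#' @export
volcano_classify <- function(results, alpha = 0.05, fc_cut = 2,
                             use = c("q", "p")) {
  use <- match.arg(use)
  pv <- if (use == "q") results$q_value else results$p_value
  sig <- pv < alpha & results$fold_change > fc_cut &
    !results$direction %in% c("none", "undefined")
  results$class <- ifelse(sig, paste0(results$direction, "_enriched"),
                          "not_significant")
  results
}

#' Differential abundance screen between two sample groups
#'
#' For every feature: ArcSinH-transforms the raw intensities, compares the
#' two groups with a two-sided Student t test (pooled variance; Welch
#' optional), adjusts p-values across features by Benjamini-Hochberg, and
#' classifies features by significance and a fold-change cut-off computed on
#' the *raw* (untransformed) group means. Both the transformed-scale test
#' and the raw-scale fold change are reported.
#'
#' @param features Feature tibble (`feature_id`, `mz`, `rt`, intensities).
#' @param samples Sample metadata tibble with `sample_id` and the grouping
#'   column.
#' @param group Name of the metadata column holding the two-level factor
#'   (default `"root_type"`).
#' @param levels Optional length-2 character vector selecting and ordering
#'   the two groups; defaults to the sorted unique values.
#' @param alpha,fc_cut,use Classification thresholds; see
#'   [volcano_classify()].
#' @param welch Use Welch instead of pooled-variance t tests.
#' @return A tibble of class `"diff_result"`: one row per feature with
#'   `feature_id`, `mz`, `rt`, `mean_<level>` raw means, `fold_change`,
#'   `direction`, `statistic`, `p_value`, `q_value`, `class`.
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 200, n_per_cell = 4,
#'                               n_diff_features = 10, diff_fold = 8)
#' wt <- dplyr::filter(sim$samples, genotype == "WT")
#' res <- diff_features(curate(sim$features)$features, wt)
#' dplyr::count(res, class)
#' @export
diff_features <- function(features, samples, group = "root_type",
                          levels = NULL, alpha = 0.05, fc_cut = 2,
                          use = c("q", "p"), welch = FALSE) {
  check_feature_table(features)
  use <- match.arg(use)
  if (!group %in% names(samples)) abort(paste0("column '", group, "' not in `samples`."))
  levels <- levels %||% sort(unique(samples[[group]]))
  if (length(levels) != 2) abort("the grouping column must have exactly 2 levels.")

  x <- intensity_matrix(features)
  ids_a <- samples$sample_id[samples[[group]] == levels[1]]
  ids_b <- samples$sample_id[samples[[group]] == levels[2]]
  missing <- setdiff(c(ids_a, ids_b), colnames(x))
  if (length(missing)) abort(paste("samples absent from feature table:",
                                   paste(missing, collapse = ", ")))
  xa <- x[, ids_a, drop = FALSE]
  xb <- x[, ids_b, drop = FALSE]
  ta <- asinh(xa)
  tb <- asinh(xb)

  tests <- purrr::map(seq_len(nrow(x)), function(i) {
    feature_t_test(ta[i, ], tb[i, ], welch = welch)
  })
  fc <- fold_change(rowMeans(xa), rowMeans(xb), labels = levels)

  out <- tibble::tibble(
    feature_id = features$feature_id,
    mz = features$mz,
    rt = features$rt,
    !!paste0("mean_", levels[1]) := rowMeans(xa),
    !!paste0("mean_", levels[2]) := rowMeans(xb),
    fold_change = fc$ratio,
    direction = fc$direction,
    statistic = purrr::map_dbl(tests, "statistic"),
    p_value = purrr::map_dbl(tests, "p_value"),
    q_value = bh_fdr(purrr::map_dbl(tests, "p_value"))
  )
  out <- volcano_classify(out, alpha = alpha, fc_cut = fc_cut, use = use)
  class(out) <- c("diff_result", class(out))
  attr(out, "levels") <- levels
  attr(out, "alpha") <- alpha
  attr(out, "fc_cut") <- fc_cut
  attr(out, "use") <- use
  out
}

#' @importFrom rlang :=
NULL
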