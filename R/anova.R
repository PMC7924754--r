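#' Per-feature two-way ANOVA with interaction
#'
#' Fits a fixed-effects two-way ANOVA (`arcsinh(intensity) ~ A * B`) for
#' every feature of a 2 x 2 design, reporting F and p for both main effects
#' and their interaction, with Benjamini-Hochberg adjustment across features
#' applied separately per term. Unbalanced designs use Type II sums of
#' squares (via [car::Anova()]); on balanced data this coincides with the
#' classical sequential decomposition.
#'
#' @param features Feature tibble (`feature_id`, `mz`, `rt`, intensities).
#' @param samples Sample metadata with `sample_id` and the two factor
#'   columns.
#' @param factors Length-2 character vector naming the factor columns
#'   (default `c("root_type", "genotype")`).
#' @return Tibble of class `"anova_result"`: one row per feature x term
#'   (`term` in the factor names plus `"interaction"`) with `F_value`,
#'   `p_value`, `q_value`.
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 60, n_per_cell = 3,
#'                               n_diff_features = 5, n_knockout = 2)
#' head(anova_features(curate(sim$features)$features, sim$samples))
#' @export
anova_features <- function(features, samples,
                           factors = c("root_type", "genotype")) {
  check_feature_table(features)
  if (!all(factors %in% names(samples))) {
    abort("both factor columns must be present in `samples`.")
  }
  cells <- table(samples[[factors[1]]], samples[[factors[2]]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(paste0("design cell '", rownames(cells)[empty[1]], "' x '",
                 colnames(cells)[empty[2]], "' is empty."))
  }
  if (any(cells < 2)) {
    warn("cells with < 2 replicates: the interaction term is not estimable per cell.")
  }

  x <- asinh(intensity_matrix(features))
  x <- x[, samples$sample_id, drop = FALSE]
  f1 <- factor(samples[[factors[1]]])
  f2 <- factor(samples[[factors[2]]])
  terms_out <- c(factors, "interaction")

  per_feature <- purrr::map(seq_len(nrow(x)), function(i) {
    y <- x[i, ]
    if (sd(y) == 0) {
      return(tibble::tibble(term = terms_out, F_value = 0, p_value = 1))
    }
    fit <- lm(y ~ f1 * f2)
    a <- car::Anova(fit, type = 2)
    tibble::tibble(
      term = terms_out,
      F_value = a[1:3, "F value"],
      p_value = a[1:3, "Pr(>F)"]
    )
  })

  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = rep(features$feature_id, each = 3)),
    dplyr::bind_rows(per_feature)
  ) |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(q_value = bh_fdr(.data$p_value)) |>
    dplyr::ungroup()
  class(out) <- c("anova_result", class(out))
  attr(out, "factors") <- factors
  out
}

#' Screen for genotype-by-root-type interaction features
#'
#' From per-feature two-way ANOVA results, reports (a) features with a
#' significant interaction after FDR correction, excluding features mapped
#' to identified compounds, and (b) additional features (not already in the
#' interaction set) with a significant genotype main effect.
#'
#' @param anova_results Output of [anova_features()].
#' @param identified_ids Character vector of feature ids mapped to
#'   identified compounds (excluded from the interaction list).
#' @param alpha FDR threshold (default 0.05).
#' @param genotype_term Name of the genotype term in `anova_results`
#'   (default `"genotype"`).
#' @return List with `interaction_features`, `genotype_features` (character
#'   vectors) and counts `n_interaction`, `n_genotype`.
#' @export
interaction_screen <- function(anova_results, identified_ids = character(),
                               alpha = 0.05, genotype_term = "genotype") {
  inter <- anova_results |>
    dplyr::filter(.data$term == "interaction", .data$q_value < alpha,
                  !.data$feature_id %in% identified_ids)
  geno <- anova_results |>
    dplyr::filter(.data$term == genotype_term, .data$q_value < alpha,
                  !.data$feature_id %in% inter$feature_id)
  list(
    interaction_features = inter$feature_id,
    genotype_features = geno$feature_id,
    n_interaction = nrow(inter),
    n_genotype = nrow(geno)
  )
}
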