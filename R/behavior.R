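#' Per-cell preference tests for two-choice assay counts
#'
#' For each treatment x timepoint cell, fits an intercept-only binomial
#' model to the dish counts on option A out of the deciding larvae
#' (undecided larvae are excluded from the denominator), estimates the
#' Pearson dispersion, inflates the Wald standard error by `sqrt(phi)` when
#' `phi > 1` (quasi-binomial correction), and tests the logit against 0
#' (no preference) two-sidedly. P-values are Benjamini-Hochberg-adjusted
#' across all cells of the experiment, realizing FDR-corrected per-cell
#' post hoc comparisons. When every deciding larva of a cell sits on one
#' option the Wald statistic degenerates, and an exact binomial p-value is
#' used for that cell instead.
#'
#' @param records Choice tibble with `count_a`, `count_b` and the grouping
#'   columns.
#' @param by Character vector of grouping columns defining the cells
#'   (default `c("treatment", "timepoint")`; missing columns are ignored).
#' @return Tibble with one row per cell: totals, `estimate` (proportion on
#'   option A), `dispersion`, `statistic`, `p_value`, `q_value`.
#' @examples
#' ch <- simulate_choice_assay(seed = 1, p_pref = 0.8)
#' preference_test(ch)
#' @export
preference_test <- function(records, by = c("treatment", "timepoint")) {
  by <- intersect(by, names(records))
  cells <- if (length(by)) dplyr::group_by(records, dplyr::across(dplyr::all_of(by)))
           else dplyr::group_by(records, .dummy = 1)

  out <- cells |>
    dplyr::group_modify(function(d, key) {
      tot <- d$count_a + d$count_b
      if (all(tot == 0)) {
        warn("cell skipped: no deciding larvae in any dish.")
        return(tibble::tibble(n_dishes = nrow(d), n_a = 0, n_b = 0,
                              estimate = NA_real_, dispersion = NA_real_,
                              statistic = NA_real_, p_value = NA_real_))
      }
      d <- d[tot > 0, , drop = FALSE]
      if (nrow(d) < 2) warn("cell has < 2 informative dishes; dispersion is not estimable.")
      fit <- glm(cbind(count_a, count_b) ~ 1, family = binomial(), data = d)
      phi <- if (df.residual(fit) > 0) {
        sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
      } else 1
      n_a <- sum(d$count_a); n_b <- sum(d$count_b)
      if (n_a == 0 || n_b == 0) {
        # complete separation: Wald degenerates, use the exact binomial test
        p <- binom.test(n_a, n_a + n_b, p = 0.5)$p.value
        z <- NA_real_
      } else {
        se <- sqrt(diag(stats::vcov(fit)))[1] * sqrt(max(phi, 1))
        z <- unname(coef(fit)[1] / se)
        p <- 2 * pnorm(-abs(z))
      }
      tibble::tibble(n_dishes = nrow(d), n_a = n_a, n_b = n_b,
                     estimate = n_a / (n_a + n_b),
                     dispersion = phi, statistic = z, p_value = p)
    }) |>
    dplyr::ungroup()
  if (".dummy" %in% names(out)) out$.dummy <- NULL
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (the convention of standard desktop
#' statistics software); the remaining absolute differences are mid-ranked
#' and `V` is the sum of ranks of positive differences. For `n <= 15`
#' nonzero pairs the two-sided p-value is computed from the exact null
#' distribution by enumerating all `2^n` sign assignments (valid under
#' ties); for larger `n` a normal approximation with continuity and tie
#' correction is used. The two-sided p-value is twice the smaller tail,
#' capped at 1.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest `n` for which the exact distribution is
#'   enumerated (default 15).
#' @return List with `statistic` (V), `p_value`, `n` (nonzero pairs),
#'   `n_zero` (dropped), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 15) {
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                n_zero = n_zero, method = "undefined (< 2 nonzero pairs)"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri) # all 2^n signed-rank sums
    p <- min(1, 2 * min(mean(sums <= v + 1e-9), mean(sums >= v - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, n_zero = n_zero, method = method)
}

#' Paired root-type comparison of damage scores
#'
#' Averages the ordinal damage scores per plant within each root type, then
#' applies the Wilcoxon signed-rank test to the paired per-plant means
#' (postembryonic minus embryonic).
#'
#' @param damage Damage tibble with `plant_id`, `root_type`, `score`.
#' @param levels Length-2 root-type levels, difference = second minus first
#'   (default `c("embryonic", "postembryonic")`).
#' @return List of class `"damage_roottype_test"`: `plant_means` (wide
#'   tibble with a `difference` column), `statistic`, `p_value`, `n`,
#'   `n_zero`, `method`. All-zero differences give a `"no difference"`
#'   method with `p_value = NA`.
#' @examples
#' dmg <- simulate_damage_scores(seed = 1, effect = 2)
#' tidy(damage_roottype_test(dmg))
#' @export
damage_roottype_test <- function(damage,
                                 levels = c("embryonic", "postembryonic")) {
  means <- damage |>
    dplyr::group_by(.data$plant_id, .data$root_type) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "root_type", values_from = "mean_score")
  if (!all(levels %in% names(means)) || anyNA(means[levels])) {
    abort("every plant needs scores for both root types.")
  }
  means$difference <- means[[levels[2]]] - means[[levels[1]]]
  if (all(means$difference == 0)) {
    res <- list(statistic = NA_real_, p_value = NA_real_,
                n = 0, n_zero = nrow(means), method = "no difference")
  } else {
    res <- wilcoxon_signed_rank(means$difference)
  }
  structure(c(list(plant_means = means), res), class = "damage_roottype_test")
}

#' @export
print.damage_roottype_test <- function(x, ...) {
  cat("Wilcoxon signed-rank on per-plant root-type means\n")
  cat(sprintf("  V = %s, p = %s (%s; n = %d pairs, %d zero dropped)\n",
              format(x$statistic), format.pval(x$p_value), x$method,
              x$n, x$n_zero))
  invisible(x)
}

#' @export
tidy.damage_roottype_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                 n_zero = x$n_zero, method = x$method)
}

# Compact letter display: treatments not significantly different share a
# letter. Maximal cliques of the non-significance graph each get a letter.
compact_letters <- function(groups, pairs, alpha = 0.05) {
  ns <- pairs[pairs$p_adj >= alpha, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ns[, c("group1", "group2")], directed = FALSE,
    vertices = data.frame(name = groups)
  )
  cl <- igraph::max_cliques(g)
  cl <- cl[order(-lengths(cl))]
  letter_of <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(cl)) {
    members <- names(cl[[k]])
    letter_of[members] <- paste0(letter_of[members], letters[k])
  }
  tibble::tibble(group = groups, letters = unname(letter_of[groups]))
}

#' Kruskal-Wallis comparison of damage between treatments
#'
#' Tie-corrected Kruskal-Wallis ANOVA on ranks of the per-plant mean damage
#' scores, followed by Tukey HSD post hoc comparisons on the
#' rank-transformed values (a rank approximation of the named Tukey
#' procedure) and a compact letter display.
#'
#' @param plant_means Tibble with one row per plant: a `treatment` column
#'   and the response column.
#' @param response Name of the response column (default `"mean_score"`).
#' @return List of class `"damage_treatment_test"`: `statistic` (H), `df`,
#'   `p_value`, `posthoc` (pairwise tibble with `p_adj`), `letters`.
#' @export
damage_treatment_test <- function(plant_means, response = "mean_score") {
  y <- plant_means[[response]]
  trt <- factor(plant_means$treatment)
  if (nlevels(trt) < 2) abort("need >= 2 treatments.")
  if (any(table(trt) < 2)) abort("need >= 2 plants per treatment.")
  if (sd(y) == 0) {
    lv <- levels(trt)
    return(structure(list(
      statistic = 0, df = nlevels(trt) - 1, p_value = 1,
      posthoc = tibble::tibble(group1 = character(), group2 = character(),
                               diff_mean_rank = numeric(), p_adj = numeric()),
      letters = tibble::tibble(group = lv, letters = "a")
    ), class = "damage_treatment_test"))
  }
  kw <- kruskal.test(y ~ trt)
  rk <- rank(y)
  hsd <- TukeyHSD(aov(rk ~ trt))$trt
  cmp <- strsplit(rownames(hsd), "-", fixed = TRUE)
  posthoc <- tibble::tibble(
    group1 = vapply(cmp, `[`, "", 1),
    group2 = vapply(cmp, `[`, "", 2),
    diff_mean_rank = hsd[, "diff"],
    p_adj = hsd[, "p adj"]
  )
  structure(list(
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value, posthoc = posthoc,
    letters = compact_letters(levels(trt), posthoc)
  ), class = "damage_treatment_test")
}

#' @export
print.damage_treatment_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on ranks: H = %.3f, df = %d, p = %s\n",
              x$statistic, x$df, format.pval(x$p_value)))
  print(x$letters)
  invisible(x)
}

# All permutations of 1..n as an n! x n matrix (exact Spearman null).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(p) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(p[, seq_len(pos - 1), drop = FALSE], n,
                   p[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row + seq_len(nrow(p)), ] <- block
    row <- row + nrow(p)
  }
  out
}

#' Spearman rank correlation between damage and performance
#'
#' Spearman's rho via rank transform with mid-ranks for ties. For `n <= 9`
#' paired observations the two-sided p-value is exact, computed by full
#' enumeration of all `n!` permutations; otherwise the usual t
#' approximation on `n - 2` degrees of freedom is used.
#'
#' @param x,y Paired numeric vectors (`n >= 4`).
#' @param exact_max Largest `n` for exact enumeration (default 9).
#' @return List of class `"spearman_cor"`: `rho`, `p_value`, `n`, `method`.
#' @examples
#' performance_correlation(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
performance_correlation <- function(x, y, exact_max = 9) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need >= 4 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman rho undefined.")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "undefined"), class = "spearman_cor"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %s (%s, n = %d)\n",
              x$rho, format.pval(x$p_value), x$method, x$n))
  invisible(x)
}

#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n = x$n, method = x$method)
}
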