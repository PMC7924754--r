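test_that("preference test is symmetric and agrees with the exact mid-p binomial", {
  even <- tibble::tibble(treatment = "t", timepoint = 1,
                         count_a = rep(3, 10), count_b = rep(3, 10),
                         dish_total = 6)
  out <- preference_test(even)
  expect_equal(out$estimate, 0.5)
  expect_gt(out$p_value, 0.99)

  # swapping the options negates the statistic and preserves p exactly
  skew <- tibble::tibble(treatment = "t", timepoint = 1,
                         count_a = c(5, 6, 4, 5, 6), count_b = c(1, 0, 2, 1, 0),
                         dish_total = 6)
  fwd <- preference_test(skew)
  rev <- preference_test(dplyr::rename(skew, count_a = count_b,
                                       count_b = count_a))
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$estimate, 1 - rev$estimate)

  # pooled 55/100 with negligible dispersion: close to the exact mid-p value
  rec <- tibble::tibble(treatment = "t", timepoint = 1,
                        count_a = c(rep(6, 5), rep(5, 5)),
                        count_b = c(rep(4, 5), rep(5, 5)), dish_total = 10)
  p_wald <- preference_test(rec)$p_value
  p_midp <- 2 * (pbinom(44, 100, 0.5) + 0.5 * dbinom(55, 100, 0.5))
  expect_equal(p_wald, p_midp, tolerance = 0.02)

  # complete separation falls back to the exact binomial test
  all_a <- tibble::tibble(treatment = "t", timepoint = 1,
                          count_a = rep(6, 4), count_b = 0, dish_total = 6)
  out_a <- preference_test(all_a)
  expect_equal(out_a$p_value, binom.test(24, 24)$p.value)

  empty <- tibble::tibble(treatment = "t", timepoint = 1,
                          count_a = c(0, 0), count_b = c(0, 0), dish_total = 6)
  expect_warning(skipped <- preference_test(empty), "skipped")
  expect_true(is.na(skipped$p_value))
})

test_that("preference q-values adjust across cells of one experiment", {
  ch <- dplyr::bind_rows(
    simulate_choice_assay(seed = 1, p_pref = 0.9, treatment = "wt", timepoint = 1),
    simulate_choice_assay(seed = 2, p_pref = 0.5, treatment = "ko", timepoint = 1),
    simulate_choice_assay(seed = 3, p_pref = 0.9, treatment = "wt", timepoint = 2)
  )
  out <- preference_test(ch)
  expect_equal(nrow(out), 3)
  expect_equal(out$q_value, bh_fdr(out$p_value))
})

test_that("Wilcoxon signed-rank matches enumeration, stats::wilcox.test and hand cases", {
  # six positive differences: one-sided 1/64, two-sided 2/64
  res6 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(res6$statistic, 21)
  expect_equal(res6$p_value, 2 / 64)

  set.seed(5)
  for (n in 3:8) {
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, wilcox_enum_oracle(d), info = paste("n =", n))
    if (!any(duplicated(abs(d)))) {
      ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, info = paste("wilcox.test n =", n))
    }
  }
  # ties handled by enumeration over mid-ranks
  d_tie <- c(1, 1, -1, 2, 2)
  expect_equal(wilcoxon_signed_rank(d_tie)$p_value, wilcox_enum_oracle(d_tie))

  # zeros dropped; too few nonzero pairs is flagged
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, -2, 3))$n_zero, 2)
  expect_true(is.na(wilcoxon_signed_rank(c(0, 0, 1))$p_value))
})

test_that("root-type damage comparison pairs per-plant means", {
  dmg <- simulate_damage_scores(seed = 2, n_plants = 12, effect = 2)
  res <- damage_roottype_test(dmg)
  expect_lt(res$p_value, 0.01)
  expect_equal(nrow(res$plant_means), 12)
  expect_s3_class(tidy(res), "tbl_df")

  flat <- simulate_damage_scores(seed = 3, n_plants = 6, effect = 0,
                                 baseline = -10) # all scores clamp to 0
  expect_true(all(flat$score == 0))
  res0 <- damage_roottype_test(flat)
  expect_equal(res0$method, "no difference")
  expect_true(is.na(res0$p_value))
})

test_that("null damage generator does not inflate the signed-rank test", {
  set.seed(11)
  n_rep <- 200
  rej <- 0
  for (i in seq_len(n_rep)) {
    dmg <- simulate_damage_scores(seed = 10000 + i, n_plants = 10, effect = 0)
    p <- damage_roottype_test(dmg)$p_value
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  # at most nominal: upper 99% binomial bound around 0.05 for 200 reps
  expect_lte(rej / n_rep, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("treatment damage test matches the tie-corrected H formula", {
  pm <- dplyr::bind_rows(
    simulate_damage_scores(1, effect = 2, treatment = "A"),
    simulate_damage_scores(2, effect = 1, treatment = "B"),
    simulate_damage_scores(3, effect = 0, treatment = "C")
  ) |>
    dplyr::group_by(treatment, plant_id) |>
    dplyr::summarise(mean_score = mean(score), .groups = "drop")
  res <- damage_treatment_test(pm)
  expect_equal(res$statistic, kruskal_h_oracle(pm$mean_score, pm$treatment),
               tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)
  expect_equal(sort(res$letters$group), c("A", "B", "C"))
  # planted ordered shift: monotone mean ranks
  mean_ranks <- tapply(rank(pm$mean_score), pm$treatment, mean)
  expect_true(all(diff(mean_ranks[c("C", "B", "A")]) > 0))

  tied <- tibble::tibble(treatment = rep(c("A", "B"), each = 3), mean_score = 2)
  res_t <- damage_treatment_test(tied)
  expect_equal(res_t$statistic, 0)
  expect_equal(res_t$p_value, 1)
  expect_error(damage_treatment_test(pm[pm$treatment == "A", ]), ">= 2 treatments")
})

test_that("Spearman correlation hits the exact permutation null for small n", {
  mono <- performance_correlation(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(mono$rho, 1)
  expect_equal(performance_correlation(1:6, seq(12, 2, by = -2))$rho, -1)

  set.seed(6)
  x <- rnorm(5); y <- rnorm(5)
  got <- performance_correlation(x, y)
  expect_equal(got$method, "exact permutation")
  expect_equal(got$p_value, spearman_perm_oracle(x, y))

  # t approximation for larger n agrees with stats::cor.test
  x2 <- rnorm(20); y2 <- x2 + rnorm(20)
  got2 <- performance_correlation(x2, y2)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(got2$rho, unname(ref$estimate))

  expect_warning(und <- performance_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(und$rho))
  expect_error(performance_correlation(1:3, 1:3), ">= 4")
})
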