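make_tiny <- function(rt, mz = NULL, intens = NULL, n_samples = 4) {
  n <- length(rt)
  mz <- mz %||% seq(100.1, by = 1, length.out = n)
  if (is.null(intens)) {
    set.seed(42)
    intens <- matrix(rlnorm(n * n_samples, log(1e4), 1), n, n_samples)
  }
  colnames(intens) <- paste0("s", seq_len(ncol(intens)))
  dplyr::bind_cols(
    tibble::tibble(feature_id = paste0("f", seq_len(n)), mz = mz, rt = rt),
    tibble::as_tibble(intens)
  )
}

test_that("retention-time filter drops void-volume features with exact bookkeeping", {
  tbl <- make_tiny(rt = c(0, 0.1, 0.29, 0.3, 0.31, 5))
  out <- filter_retention_time(tbl)
  expect_equal(out$feature_id, c("f4", "f5", "f6")) # rt = 0.3 retained
  expect_equal(attr(out, "removed"), 3)
  expect_equal(nrow(filter_retention_time(tbl[0, ])), 0)
  all5 <- make_tiny(rt = rep(5, 4))
  expect_equal(nrow(filter_retention_time(all5)), 4)
})

test_that("mass-decimal filter excludes artifact masses above the threshold", {
  tbl <- make_tiny(rt = rep(1, 4), mz = c(250.85, 250.80, 100.0, 300.81))
  out <- filter_mass_decimal(tbl)
  expect_setequal(out$mz, c(250.80, 100.0)) # boundary 0.80 retained
  # planted bad-decimal fraction is removed at its known rate
  sim <- simulate_feature_table(seed = 2, n_features = 1000, n_per_cell = 3,
                                frac_bad_decimal = 0.1, frac_unretained = 0,
                                n_diff_features = 0, n_knockout = 0)
  removed <- attr(filter_mass_decimal(sim$features), "removed")
  expect_equal(removed, sum(sim$features$mz - floor(sim$features$mz) > 0.8))
  expect_equal(removed, 100) # round(0.1 * 1000) planted exactly
})

test_that("chain-wise grouping links A-B-C through shared neighbors", {
  set.seed(1)
  latent <- rlnorm(6, log(1e4), 0.5)
  intens <- rbind(latent * exp(rnorm(6, 0, 0.02)),
                  latent * exp(rnorm(6, 0, 0.02)),
                  latent * exp(rnorm(6, 0, 0.02)))
  tbl <- make_tiny(rt = c(1.00, 1.03, 1.06), intens = intens)
  # A-B and B-C are within 0.04 min; A-C is not
  g <- group_fragments(tbl)
  expect_equal(dplyr::n_distinct(g$group_id), 1)
  # clique mode cannot hold A and C together
  gc <- group_fragments(tbl, group_mode = "clique")
  expect_equal(dplyr::n_distinct(gc$group_id), 2)
})

test_that("grouping respects both the RT window and the correlation threshold", {
  set.seed(2)
  latent <- rlnorm(6, log(1e4), 0.5)
  close_cor <- rbind(latent, latent * exp(rnorm(6, 0, 0.01)))
  far <- make_tiny(rt = c(1, 1.5), intens = close_cor)
  expect_equal(dplyr::n_distinct(group_fragments(far)$group_id), 2)

  dup <- make_tiny(rt = c(1, 1), intens = rbind(latent, latent))
  expect_equal(dplyr::n_distinct(group_fragments(dup)$group_id), 1)

  flat <- make_tiny(rt = c(1, 1.01), intens = rbind(rep(5, 6), latent))
  expect_equal(dplyr::n_distinct(group_fragments(flat)$group_id), 2)
})

test_that("grouping equals a brute-force union-find oracle on random tables", {
  for (s in 1:25) {
    tbl <- random_feature_table(seed = s)
    g <- group_fragments(tbl)
    e <- naive_edges(tbl)
    oracle <- uf_components(tbl$feature_id, e$from, e$to)
    expect_equal(
      as.vector(table(table(g$group_id))),
      as.vector(table(table(oracle))),
      info = paste("seed", s)
    )
    # identical partitions, not just identical size spectra
    expect_equal(partition_canon(split(g$feature_id, g$group_id)),
                 partition_canon(split(names(oracle), oracle)))
  }
})

test_that("grouping is invariant to row order and monotone in its thresholds", {
  tbl <- random_feature_table(seed = 99)
  g0 <- group_fragments(tbl)
  perm <- sample(nrow(tbl))
  g1 <- group_fragments(tbl[perm, ])
  expect_equal(partition_canon(split(g0$feature_id, g0$group_id)),
               partition_canon(split(g1$feature_id, g1$group_id)))
  n_groups <- function(...) dplyr::n_distinct(group_fragments(...)$group_id)
  expect_lte(n_groups(tbl, r_min = 0.8), n_groups(tbl, r_min = 0.95))
  expect_lte(n_groups(tbl, rt_window = 0.04), n_groups(tbl, rt_window = 0.01))
})

test_that("representative selection prefers the identified [M-H]- feature", {
  set.seed(3)
  latent <- rlnorm(6, log(1e4), 0.5)
  intens <- rbind(latent, latent * 10 * exp(rnorm(6, 0, 0.01)))
  tbl <- make_tiny(rt = c(1, 1.01), mz = c(300.2, 150.1), intens = intens)
  groups <- group_fragments(tbl)
  ids <- tibble::tibble(feature_id = "f1", compound = "DIMBOA", adduct = "[M-H]-")

  rep_id <- select_representative(tbl, groups, ids)
  expect_equal(rep_id$representative_id, "f1") # beats the 10x more abundant f2
  expect_equal(rep_id$rule, "identified")

  rep_ab <- select_representative(tbl, groups)
  expect_equal(rep_ab$representative_id, "f2")
  expect_equal(rep_ab$rule, "most_abundant")

  # identified but no [M-H]- member: fall back with a warning
  ids_frag <- tibble::tibble(feature_id = "f1", compound = "DIMBOA",
                             adduct = "fragment")
  expect_warning(rep_fb <- select_representative(tbl, groups, ids_frag),
                 "no \\[M-H\\]-")
  expect_equal(rep_fb$representative_id, "f2")

  # two identified compounds in one group: lowest-m/z [M-H]- with a warning
  ids2 <- tibble::tibble(feature_id = c("f1", "f2"),
                         compound = c("DIMBOA", "HMBOA"),
                         adduct = "[M-H]-")
  expect_warning(rep2 <- select_representative(tbl, groups, ids2),
                 "several identified")
  expect_equal(rep2$representative_id, "f2") # mz 150.1 < 300.2

  single <- make_tiny(rt = 1)
  expect_equal(select_representative(single, group_fragments(single))$representative_id,
               "f1")
})

test_that("curation collapses constructed fragment groups to one feature each", {
  tbl <- make_grouped_table(n_compounds = 10, frags = 3)
  cur <- curate(tbl)
  expect_equal(cur$report$n_informative, 10)
  expect_equal(cur$report$n_groups, 10)
  # partition property
  expect_equal(sum(table(cur$groups$group_id)), cur$report$n_after_decimal)
  expect_equal(anyDuplicated(cur$groups$feature_id), 0)
})

test_that("a no-op configuration returns the input features unchanged", {
  tbl <- make_tiny(rt = c(0.1, 0.5, 3), mz = c(100.9, 200.5, 300.1))
  cur <- curate(tbl, min_rt = 0, max_frac = 1, r_min = 1.01)
  expect_setequal(cur$features$feature_id, tbl$feature_id)
  expect_equal(cur$report$n_informative, nrow(tbl))
})

test_that("most synthetic compounds come back as exactly one pure group", {
  sim <- simulate_feature_table(seed = 11, n_features = 1500, n_per_cell = 10,
                                n_diff_features = 60)
  kept <- filter_mass_decimal(filter_retention_time(sim$features))
  g <- group_fragments(kept)
  gm <- dplyr::inner_join(g, sim$truth$membership, by = "feature_id")
  groups_per_cmp <- tapply(gm$group_id, gm$compound_id,
                           function(x) length(unique(x)))
  cmps_per_group <- tapply(gm$compound_id, gm$group_id,
                           function(x) length(unique(x)))
  own_group <- tapply(gm$group_id, gm$compound_id, function(x) x[1])
  exact_one <- groups_per_cmp == 1 & cmps_per_group[own_group] == 1
  expect_gte(mean(exact_one), 0.95)
})
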