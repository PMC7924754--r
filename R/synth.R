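#' Simulate an untargeted LC-MS root feature table with known ground truth
#'
#' Generates a features-by-samples peak-area table with the statistical
#' structure that the curation and differential-screening stages assume, so
#' that every stage of the pipeline can be exercised and scored against a
#' known truth without any real instrument data.
#'
#' The generative model works at the level of synthetic *compounds*: each
#' compound has a latent abundance per sample (log-normal biological noise
#' around a compound base level, `noise_sigma` on the natural-log scale), and
#' each of its fragments observes that latent abundance times a
#' fragment-specific yield times small independent analytical noise
#' (`fragment_sigma`). Fragments of one compound therefore co-elute (pairwise
#' retention-time differences at most 0.04 min by construction) and are
#' strongly Pearson-correlated across samples. Differential compounds have
#' their latent mean multiplied by `diff_fold` in one root type; knockout
#' compounds are scaled to `knockout_fraction` of their wild-type level in
#' the mutant genotype (both root types). Uninformative features are planted
#' on top: a fraction eluting before 0.3 min, and a fraction with an m/z
#' fractional part above 0.8 (instrument-artifact masses).
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_features Total number of mass features to emit (default 4956,
#'   the size of a typical curated negative-mode root dataset).
#' @param n_per_cell Samples per root-type x genotype cell (>= 2; default 10).
#' @param rt_range Elution window in minutes (default 0 to 8.5).
#' @param mz_range Acquired m/z range in Da (default 100 to 1200).
#' @param frac_unretained Fraction of features eluting before 0.3 min
#'   (default 444/4956).
#' @param frac_bad_decimal Fraction of features with m/z fractional part
#'   above 0.8 (default 0.05).
#' @param mean_group_size Mean number of fragments per compound (default 2.9;
#'   sizes are 1 + Poisson, capped at 8).
#' @param noise_sigma Biological log-scale SD of the shared latent abundance
#'   (default 0.3).
#' @param fragment_sigma Analytical log-scale SD of fragment-specific noise
#'   (default 0.05).
#' @param n_diff_features Number of root-type-differential compounds to plant
#'   (default 200). All fragments of a differential compound shift together;
#'   the emitted truth lists both compound and feature ids.
#' @param diff_fold Fold effect (>= 2) applied to the latent mean of planted
#'   differential compounds (default 4).
#' @param n_knockout Number of knockout-class compounds (default 6, the size
#'   of a benzoxazinoid panel).
#' @param knockout_fraction Residual fraction of knockout compounds in the
#'   mutant genotype (default 0.03).
#' @param root_types,genotypes Factor levels for the 2 x 2 design. The second
#'   root type receives the "up" direction label; the second genotype is the
#'   mutant.
#'
#' @return A list of class `"feature_sim"` with elements
#'   * `features`: tibble with `feature_id`, `mz`, `rt` and one intensity
#'     column per sample;
#'   * `samples`: tibble with `sample_id`, `root_type`, `genotype`,
#'     `replicate`;
#'   * `truth`: list with `membership` (feature -> compound),
#'     `diff_compounds` (compound, direction, fold), `diff_feature_ids`,
#'     `knockout_compound_ids`, `knockout_feature_ids`, `junk_feature_ids`.
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 300, n_per_cell = 4,
#'                               n_diff_features = 10)
#' dim(sim$features)
#' @export
simulate_feature_table <- function(seed = 1,
                                   n_features = 4956,
                                   n_per_cell = 10,
                                   rt_range = c(0, 8.5),
                                   mz_range = c(100, 1200),
                                   frac_unretained = 444 / 4956,
                                   frac_bad_decimal = 0.05,
                                   mean_group_size = 2.9,
                                   noise_sigma = 0.3,
                                   fragment_sigma = 0.05,
                                   n_diff_features = 200,
                                   diff_fold = 4,
                                   n_knockout = 6,
                                   knockout_fraction = 0.03,
                                   root_types = c("embryonic", "postembryonic"),
                                   genotypes = c("WT", "bx1")) {
  check_positive_count(n_features, "n_features")
  check_positive_count(n_per_cell, "n_per_cell")
  if (n_per_cell < 2) abort("`n_per_cell` must be >= 2.")
  check_proportion(frac_unretained, "frac_unretained")
  check_proportion(frac_bad_decimal, "frac_bad_decimal")
  check_proportion(knockout_fraction, "knockout_fraction")
  if (n_diff_features > 0 && diff_fold < 2) abort("`diff_fold` must be >= 2.")
  set.seed(seed)

  design <- tidyr::expand_grid(
    genotype = genotypes, root_type = root_types, replicate = seq_len(n_per_cell)
  ) |>
    dplyr::mutate(sample_id = paste(.data$genotype, .data$root_type,
                                    .data$replicate, sep = "_")) |>
    dplyr::select("sample_id", "root_type", "genotype", "replicate")
  n_samples <- nrow(design)

  n_junk_rt <- round(frac_unretained * n_features)
  n_junk_dec <- round(frac_bad_decimal * n_features)
  n_frag <- n_features - n_junk_rt - n_junk_dec
  if (n_frag < 1) abort("junk fractions leave no informative features.")

  # Fragments-per-compound sizes: 1 + Poisson, capped, trimmed to n_frag.
  sizes <- integer(0)
  while (sum(sizes) < n_frag) {
    sizes <- c(sizes, pmin(1L + stats::rpois(n_frag, mean_group_size - 1), 8L))
  }
  sizes <- sizes[cumsum(sizes) <= n_frag]
  if (sum(sizes) < n_frag) sizes <- c(sizes, n_frag - sum(sizes))
  n_compounds <- length(sizes)

  if (n_diff_features > n_compounds) {
    abort("`n_diff_features` exceeds the number of synthetic compounds.")
  }
  compound_id <- sprintf("C%04d", seq_len(n_compounds))
  compound_rt <- runif(n_compounds, 0.32, rt_range[2] - 0.02)
  base_log <- rnorm(n_compounds, mean = log(1e5), sd = 1.5)

  diff_idx <- if (n_diff_features > 0) sample.int(n_compounds, n_diff_features) else integer(0)
  direction <- sample(root_types, n_diff_features, replace = TRUE)
  pool <- setdiff(seq_len(n_compounds), diff_idx)
  n_ko <- min(n_knockout, length(pool))
  ko_idx <- if (n_ko > 0) sample(pool, n_ko) else integer(0)

  # Per-compound x sample latent multiplier from the planted design effects.
  fold_mat <- matrix(1, n_compounds, n_samples)
  for (k in seq_along(diff_idx)) {
    up <- design$root_type == direction[k]
    fold_mat[diff_idx[k], up] <- diff_fold
  }
  if (n_ko > 0) {
    mut <- design$genotype == genotypes[2]
    fold_mat[ko_idx, mut] <- fold_mat[ko_idx, mut] * knockout_fraction
  }

  latent <- exp(base_log + log(fold_mat) +
                  matrix(rnorm(n_compounds * n_samples, sd = noise_sigma),
                         n_compounds, n_samples))

  frag_compound <- rep(seq_len(n_compounds), sizes)
  yield <- exp(rnorm(n_frag, mean = 0, sd = 0.8))
  frag_rt <- compound_rt[frag_compound] + runif(n_frag, -0.02, 0.02)
  frag_rt <- pmin(pmax(frag_rt, 0.301), rt_range[2])
  frag_mz <- floor(runif(n_frag, mz_range[1], mz_range[2] - 1)) + runif(n_frag, 0, 0.8)
  frag_int <- latent[frag_compound, , drop = FALSE] * yield *
    exp(matrix(rnorm(n_frag * n_samples, sd = fragment_sigma), n_frag, n_samples))

  junk_int <- function(n) {
    if (n == 0) return(matrix(numeric(0), 0, n_samples))
    exp(rnorm(n, log(5e3), 1) +
          matrix(rnorm(n * n_samples, sd = 0.6), n, n_samples))
  }
  rt_junk_rt <- runif(n_junk_rt, 0, 0.299)
  mz_junk_rt <- floor(runif(n_junk_rt, mz_range[1], mz_range[2] - 1)) +
    runif(n_junk_rt, 0, 0.8)
  rt_junk_dec <- runif(n_junk_dec, 0.32, rt_range[2])
  mz_junk_dec <- floor(runif(n_junk_dec, mz_range[1], mz_range[2] - 1)) +
    runif(n_junk_dec, 0.8001, 0.9999)

  feature_id <- sprintf("F%05d", seq_len(n_features))
  mz <- c(frag_mz, mz_junk_rt, mz_junk_dec)
  rt <- c(frag_rt, rt_junk_rt, rt_junk_dec)
  intens <- rbind(frag_int, junk_int(n_junk_rt), junk_int(n_junk_dec))
  colnames(intens) <- design$sample_id

  features <- dplyr::bind_cols(
    tibble::tibble(feature_id = feature_id, mz = mz, rt = rt),
    tibble::as_tibble(intens)
  )

  frag_ids <- feature_id[seq_len(n_frag)]
  membership <- tibble::tibble(feature_id = frag_ids,
                               compound_id = compound_id[frag_compound])
  diff_compounds <- tibble::tibble(
    compound_id = compound_id[diff_idx],
    direction = direction,
    fold = rep(diff_fold, length(diff_idx))
  )
  truth <- list(
    membership = membership,
    diff_compounds = diff_compounds,
    diff_feature_ids = membership$feature_id[
      membership$compound_id %in% diff_compounds$compound_id],
    knockout_compound_ids = compound_id[ko_idx],
    knockout_feature_ids = membership$feature_id[
      membership$compound_id %in% compound_id[ko_idx]],
    junk_feature_ids = feature_id[seq_len(n_junk_rt + n_junk_dec) + n_frag]
  )

  structure(list(features = features, samples = design, truth = truth,
                 seed = seed),
            class = "feature_sim")
}

#' @export
print.feature_sim <- function(x, ...) {
  cat("Synthetic feature table:", nrow(x$features), "features x",
      nrow(x$samples), "samples\n")
  cat("  compounds:", dplyr::n_distinct(x$truth$membership$compound_id),
      "| differential:", nrow(x$truth$diff_compounds),
      "| knockout-class:", length(x$truth$knockout_compound_ids), "\n")
  invisible(x)
}

# Default wild-type benzoxazinoid panel (ug per g fresh weight) used by the
# targeted-panel generator: postembryonic roots carry about 4-fold more
# DIMBOA and 2- to 3-fold more DIMBOA-Glc and DIM2BOA-Glc, but less
# HDMBOA-Glc, than embryonic roots.
default_bx_panel <- function() {
  tibble::tribble(
    ~compound,      ~embryonic, ~postembryonic,
    "DIMBOA-Glc",        320,            800,
    "DIMBOA",             50,            200,
    "HDMBOA-Glc",        300,            150,
    "DIM2BOA-Glc",        50,            120,
    "HMBOA",              20,             30,
    "MBOA",               10,             15
  )
}

#' Simulate a targeted benzoxazinoid quantification panel
#'
#' Emulates a UHPLC-UV/MS benzoxazinoid panel across wild-type and
#' biosynthesis-knockout roots: per-compound tissue concentrations with
#' log-normal noise, paired UV (265 nm) and single-ion-recording MS peak
#' areas linked by a known per-compound signal ratio, additive instrument
#' baseline on both channels, and external-standard calibration points.
#' Mutant concentrations are the wild-type means scaled by `1 - reduction`.
#'
#' @param seed Integer seed.
#' @param reduction Proportional knockout of the compound class in the mutant
#'   (default 0.975, i.e. levels reduced by more than 97%).
#' @param n_per_cell Replicates per genotype x root-type cell (default 12).
#' @param noise_sigma Log-scale SD of biological concentration noise
#'   (default 0.15).
#' @param meas_sigma Log-scale SD of the multiplicative measurement noise on
#'   each signal channel (default 0.05).
#' @param wt_means Tibble with columns `compound`, `embryonic`,
#'   `postembryonic` giving wild-type mean concentrations (ug/g fresh
#'   weight); defaults to a six-compound benzoxazinoid panel.
#' @param tissue_mass_mg Tissue fresh weight extracted per sample (default
#'   100 mg into 1 mL, so extract concentration = 0.1 x tissue concentration).
#' @param extract_volume_ml Extraction volume (default 1 mL).
#' @param genotypes Genotype labels; the second is the mutant.
#'
#' @return A list of class `"targeted_sim"`: `panel` (compound, sample_id,
#'   genotype, root_type, tissue_mass_mg, uv_area, ms_area, true
#'   concentration), `standards` (compound, concentration in ug/mL extract,
#'   uv_area), and `truth` (reduction, per-compound UV slope and MS-to-UV
#'   factor, suggested UV reliability floor = 3 x median blank signal).
#' @export
simulate_targeted_panel <- function(seed = 1,
                                    reduction = 0.975,
                                    n_per_cell = 12,
                                    noise_sigma = 0.15,
                                    meas_sigma = 0.05,
                                    wt_means = default_bx_panel(),
                                    tissue_mass_mg = 100,
                                    extract_volume_ml = 1,
                                    genotypes = c("WT", "bx1")) {
  check_proportion(reduction, "reduction")
  check_positive_count(n_per_cell, "n_per_cell")
  set.seed(seed)

  compounds <- wt_means$compound
  uv_slope <- setNames(runif(length(compounds), 30, 80), compounds)
  ms_uv_factor <- setNames(runif(length(compounds), 0.02, 0.2), compounds)
  blank_sd <- 8 # additive UV baseline, arbitrary units

  grid <- tidyr::expand_grid(
    compound = compounds,
    genotype = genotypes,
    root_type = c("embryonic", "postembryonic"),
    replicate = seq_len(n_per_cell)
  ) |>
    dplyr::left_join(
      tidyr::pivot_longer(wt_means, -"compound",
                          names_to = "root_type", values_to = "wt_mean"),
      by = c("compound", "root_type")
    ) |>
    dplyr::mutate(
      sample_id = paste(.data$genotype, .data$root_type, .data$replicate, sep = "_"),
      scale = ifelse(.data$genotype == genotypes[2], 1 - reduction, 1),
      concentration_true = .data$wt_mean * .data$scale *
        exp(rnorm(dplyr::n(), sd = noise_sigma)),
      tissue_mass_mg = tissue_mass_mg,
      conc_extract = .data$concentration_true *
        (tissue_mass_mg / 1000) / extract_volume_ml,
      uv_area = uv_slope[.data$compound] * .data$conc_extract *
        exp(rnorm(dplyr::n(), sd = meas_sigma)) + abs(rnorm(dplyr::n(), sd = blank_sd)),
      ms_area = (uv_slope[.data$compound] / ms_uv_factor[.data$compound]) *
        .data$conc_extract * exp(rnorm(dplyr::n(), sd = meas_sigma)) +
        abs(rnorm(dplyr::n(), sd = blank_sd / 100))
    ) |>
    dplyr::select("compound", "sample_id", "genotype", "root_type",
                  "tissue_mass_mg", "uv_area", "ms_area", "concentration_true")

  standards <- tidyr::expand_grid(
    compound = compounds,
    concentration = c(0.5, 1, 5, 20, 50, 100)
  ) |>
    dplyr::mutate(uv_area = uv_slope[.data$compound] * .data$concentration *
                    exp(rnorm(dplyr::n(), sd = 0.02)))

  structure(list(
    panel = grid,
    standards = standards,
    truth = list(reduction = reduction,
                 uv_slope = uv_slope,
                 ms_uv_factor = ms_uv_factor,
                 uv_floor_suggest = 3 * blank_sd * sqrt(2 / pi), # 3 x E|blank|
                 tissue_mass_mg = tissue_mass_mg,
                 extract_volume_ml = extract_volume_ml)
  ), class = "targeted_sim")
}

#' Simulate larval two-choice assay counts
#'
#' Per-dish counts of larvae found on option A versus option B, with an
#' optional per-larva probability of being undecided (on neither option) and
#' optional beta-binomial overdispersion across dishes.
#'
#' @param seed Integer seed.
#' @param n_dishes Number of dishes (default 15).
#' @param larvae_per_dish Larvae released per dish (default 6).
#' @param p_pref Probability that a deciding larva chooses option A.
#' @param p_undecided Per-larva probability of settling on neither option
#'   (default 0).
#' @param overdispersion Between-dish heterogeneity in `[0, 1)`: 0 gives
#'   i.i.d. binomial dishes; larger values draw each dish's preference from a
#'   beta distribution with mean `p_pref` and intra-class correlation equal
#'   to `overdispersion`.
#' @param treatment,timepoint Labels copied into the output.
#' @return Tibble with `dish_id`, `treatment`, `timepoint`, `count_a`,
#'   `count_b`, `dish_total`.
#' @export
simulate_choice_assay <- function(seed = 1,
                                  n_dishes = 15,
                                  larvae_per_dish = 6,
                                  p_pref = 0.5,
                                  p_undecided = 0,
                                  overdispersion = 0,
                                  treatment = "control",
                                  timepoint = 1) {
  check_positive_count(n_dishes, "n_dishes")
  check_positive_count(larvae_per_dish, "larvae_per_dish")
  check_proportion(p_pref, "p_pref")
  check_proportion(p_undecided, "p_undecided")
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("`overdispersion` must lie in [0, 1).")
  }
  set.seed(seed)
  p_dish <- if (overdispersion > 0) {
    theta <- (1 - overdispersion) / overdispersion
    stats::rbeta(n_dishes, p_pref * theta, (1 - p_pref) * theta)
  } else {
    rep(p_pref, n_dishes)
  }
  counts <- vapply(p_dish, function(p) {
    probs <- c(p * (1 - p_undecided), (1 - p) * (1 - p_undecided), p_undecided)
    stats::rmultinom(1, larvae_per_dish, probs)[1:2, 1]
  }, numeric(2))
  tibble::tibble(
    dish_id = sprintf("dish_%02d", seq_len(n_dishes)),
    treatment = treatment,
    timepoint = timepoint,
    count_a = counts[1, ],
    count_b = counts[2, ],
    dish_total = larvae_per_dish
  )
}

#' Simulate ordinal root-damage scores
#'
#' Each plant carries 2 embryonic and 6 postembryonic roots scored on the
#' ordinal 0-5 feeding-damage scale (0 = no visual damage ... 5 = root fully
#' removed). Scores are a rounded, clamped Gaussian latent with root-type
#' means `baseline` (embryonic) and `baseline + effect` (postembryonic);
#' `effect = 0` gives exchangeable root types.
#'
#' @param seed Integer seed.
#' @param n_plants Number of plants (default 20).
#' @param effect Latent mean shift of postembryonic roots (default 2).
#' @param baseline Latent mean of embryonic roots (default 1).
#' @param sdev Latent SD (default 1).
#' @param n_embryonic,n_postembryonic Roots per plant of each type.
#' @param treatment Optional treatment label copied into the output.
#' @return Tibble with `plant_id`, `root_id`, `root_type`, `score` (and
#'   `treatment` when given).
#' @export
simulate_damage_scores <- function(seed = 1,
                                   n_plants = 20,
                                   effect = 2,
                                   baseline = 1,
                                   sdev = 1,
                                   n_embryonic = 2,
                                   n_postembryonic = 6,
                                   treatment = NULL) {
  check_positive_count(n_plants, "n_plants")
  set.seed(seed)
  per_plant <- tibble::tibble(
    root_type = rep(c("embryonic", "postembryonic"), c(n_embryonic, n_postembryonic)),
    root_id = c(paste0("E", seq_len(n_embryonic)), paste0("PE", seq_len(n_postembryonic)))
  )
  out <- tidyr::expand_grid(plant_id = sprintf("plant_%02d", seq_len(n_plants)),
                            per_plant) |>
    dplyr::mutate(
      mu = baseline + ifelse(.data$root_type == "postembryonic", effect, 0),
      score = pmin(pmax(round(rnorm(dplyr::n(), .data$mu, sdev)), 0), 5)
    ) |>
    dplyr::select(-"mu")
  if (!is.null(treatment)) out$treatment <- treatment
  out
}

#' Simulate a qPCR cycle-threshold table for a silencing experiment
#'
#' Control and treatment groups with target and reference-gene Ct values.
#' The treatment group's target gene is knocked down by `knockdown`, i.e.
#' its mean delta-Ct is shifted up by `-log2(1 - knockdown)` cycles.
#'
#' @param seed Integer seed.
#' @param n_per_group Samples per group (default 11).
#' @param knockdown True proportional reduction of target transcript in the
#'   treatment group (default 0.75).
#' @param base_dct Mean control delta-Ct (target minus reference; default 5).
#' @param sd_dct Between-sample SD of delta-Ct (default 0.3).
#' @param ref_mean,ref_sd Reference-gene Ct mean and SD (defaults 18, 0.5).
#' @return Tibble with `sample_id`, `group`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(seed = 1,
                          n_per_group = 11,
                          knockdown = 0.75,
                          base_dct = 5,
                          sd_dct = 0.3,
                          ref_mean = 18,
                          ref_sd = 0.5) {
  check_positive_count(n_per_group, "n_per_group")
  check_proportion(knockdown, "knockdown")
  if (knockdown == 1) abort("`knockdown` must be < 1 (Ct would be infinite).")
  set.seed(seed)
  shift <- -log2(1 - knockdown)
  tidyr::expand_grid(group = c("control", "treatment"),
                     replicate = seq_len(n_per_group)) |>
    dplyr::mutate(
      sample_id = paste(.data$group, .data$replicate, sep = "_"),
      ct_reference = rnorm(dplyr::n(), ref_mean, ref_sd),
      dct = base_dct + ifelse(.data$group == "treatment", shift, 0) +
        rnorm(dplyr::n(), sd = sd_dct),
      ct_target = .data$ct_reference + .data$dct
    ) |>
    dplyr::select("sample_id", "group", "ct_target", "ct_reference")
}
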