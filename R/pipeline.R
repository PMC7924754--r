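#' Attach metabolite identities to planted synthetic compounds
#'
#' Maps the packaged identified-metabolite list onto a simulated feature
#' table so the cue cross-reference can be exercised end to end: each
#' differential metabolite is assigned to an unused planted compound with
#' the matching enrichment direction, each non-differential metabolite to an
#' unused null compound. The heaviest fragment of an assigned compound is
#' labelled as its deprotonated molecular ion (`[M-H]-`); remaining
#' fragments are labelled `"fragment"`.
#'
#' @param sim A `"feature_sim"` object from [simulate_feature_table()].
#' @param metabolites Tibble with `compound`, `differential`, `direction`
#'   (defaults to the packaged list).
#' @return Identification-map tibble (`feature_id`, `compound`, `adduct`)
#'   with an attribute `"assignments"` (compound name -> synthetic compound
#'   id and direction).
#' @export
make_identification_map <- function(sim, metabolites = load_identified_metabolites()) {
  truth <- sim$truth
  diff_pool <- split(truth$diff_compounds$compound_id, truth$diff_compounds$direction)
  null_pool <- setdiff(unique(truth$membership$compound_id),
                       c(truth$diff_compounds$compound_id, truth$knockout_compound_ids))

  rows <- list()
  for (i in seq_len(nrow(metabolites))) {
    m <- metabolites[i, ]
    if (isTRUE(m$differential)) {
      pool <- diff_pool[[m$direction]] %||% character()
      if (!length(pool)) {
        warn(paste0("no unused planted compound left for '", m$compound, "'; skipped."))
        next
      }
      cid <- pool[1]
      diff_pool[[m$direction]] <- pool[-1]
    } else {
      if (!length(null_pool)) {
        warn(paste0("no unused null compound left for '", m$compound, "'; skipped."))
        next
      }
      cid <- null_pool[1]
      null_pool <- null_pool[-1]
    }
    rows[[length(rows) + 1]] <- tibble::tibble(compound = m$compound,
                                               compound_id = cid,
                                               direction = m$direction)
  }
  assignments <- dplyr::bind_rows(rows)

  mz <- setNames(sim$features$mz, sim$features$feature_id)
  ids <- assignments |>
    dplyr::inner_join(truth$membership, by = "compound_id") |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::mutate(adduct = ifelse(mz[.data$feature_id] ==
                                    max(mz[.data$feature_id]),
                                  "[M-H]-", "fragment")) |>
    dplyr::ungroup() |>
    dplyr::select("feature_id", "compound", "adduct")
  attr(ids, "assignments") <- assignments
  ids
}

#' Run the full foraging-cue pipeline on synthetic data
#'
#' Orchestrates every stage end to end: feature-table simulation, curation,
#' root-type differential screen (wild-type samples), per-feature two-way
#' ANOVA with interaction screen, targeted-panel quantification and
#' knockout percent reduction, qPCR relative expression, behavioral choice
#' and damage statistics, and the candidate-cue cross-reference. One global
#' `seed` drives all generators through [split_seed()] (stage order:
#' features, targeted, qPCR, choice, damage), so identical configurations
#' give identical reports up to the timestamp field.
#'
#' @param seed Integer global seed.
#' @param feature_args,targeted_args,qpcr_args,choice_args,damage_args
#'   Named lists of overrides passed to the respective generators.
#' @param behavior Run the behavioral stage (default `TRUE`); when
#'   `FALSE`, the report marks it `"skipped"`.
#' @param activity,metabolites Reference tables for the cue stage.
#' @param alpha,fc_cut Differential-screen thresholds.
#' @return List of class `"rootcue_report"`: `report` (plain, JSON-ready
#'   per-stage summaries) and `data` (the full stage objects).
#' @examples
#' \donttest{
#' res <- run_pipeline(seed = 1,
#'                     feature_args = list(n_features = 500,
#'                                         n_diff_features = 40))
#' res$report$cues$candidates
#' }
#' @export
run_pipeline <- function(seed = 1,
                         feature_args = list(),
                         targeted_args = list(),
                         qpcr_args = list(),
                         choice_args = list(),
                         damage_args = list(),
                         behavior = TRUE,
                         activity = load_activity_table(),
                         metabolites = load_identified_metabolites(),
                         alpha = 0.05, fc_cut = 2) {
  sim <- do.call(simulate_feature_table,
                 c(list(seed = split_seed(seed, 1)), feature_args))
  ids <- make_identification_map(sim, metabolites)
  cur <- curate(sim$features, ids)

  wt <- sim$samples[sim$samples$genotype == unique(sim$samples$genotype)[1], ]
  diff <- diff_features(cur$features, wt, group = "root_type",
                        alpha = alpha, fc_cut = fc_cut)
  identified <- cur$representatives |>
    dplyr::filter(!is.na(.data$compound)) |>
    dplyr::inner_join(diff[, c("feature_id", "class")],
                      by = c(representative_id = "feature_id"))
  av <- anova_features(cur$features, sim$samples)
  screen <- interaction_screen(av, identified_ids = identified$representative_id,
                               alpha = alpha)
  candidates <- cross_reference(identified[, c("compound", "class")], activity)

  tp <- do.call(simulate_targeted_panel,
                c(list(seed = split_seed(seed, 2)), targeted_args))
  quant <- quantify_panel(tp$panel, tp$standards,
                          uv_floor = tp$truth$uv_floor_suggest,
                          extract_volume_ml = tp$truth$extract_volume_ml)
  red <- percent_reduction(quant)

  qs <- do.call(simulate_qpcr, c(list(seed = split_seed(seed, 3)), qpcr_args))
  dd <- ddct(qs)
  kd <- knockdown_percent(dd)

  if (behavior) {
    choice <- do.call(simulate_choice_assay,
                      c(list(seed = split_seed(seed, 4)), choice_args))
    pref <- preference_test(choice)
    dmg <- do.call(simulate_damage_scores,
                   c(list(seed = split_seed(seed, 5)), damage_args))
    drt <- damage_roottype_test(dmg)
    behavior_report <- list(
      preference = as.list(pref[1, c("estimate", "dispersion", "p_value")]),
      damage = list(statistic = drt$statistic, p_value = drt$p_value,
                    n_pairs = drt$n)
    )
  } else {
    choice <- pref <- dmg <- drt <- NULL
    behavior_report <- "skipped"
  }

  report <- list(
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    curation = cur$report[c("n_raw", "n_removed_rt", "n_after_rt",
                            "n_removed_decimal", "n_after_decimal",
                            "n_groups", "n_informative")],
    differential = as.list(table(diff$class)),
    interaction_screen = screen[c("n_interaction", "n_genotype")],
    cues = list(n_candidates = nrow(candidates),
                candidates = candidates$compound),
    targeted = list(percent_reduction_total = red$overall),
    qpcr = list(knockdown_percent = kd),
    behavior = behavior_report
  )
  structure(list(report = report,
                 data = list(sim = sim, ids = ids, curation = cur,
                             differential = diff, anova = av,
                             screen = screen, candidates = candidates,
                             targeted = list(sim = tp, quant = quant,
                                             reduction = red),
                             qpcr = dd, choice = choice, preference = pref,
                             damage = dmg, damage_test = drt)),
            class = "rootcue_report")
}

#' @export
print.rootcue_report <- function(x, ...) {
  r <- x$report
  cat("rootcue pipeline report (seed", r$seed, ")\n")
  cat("  curation:", r$curation$n_raw, "->", r$curation$n_informative,
      "informative features\n")
  cls <- unlist(r$differential)
  cat("  differential:", paste(names(cls), cls, sep = " = ", collapse = ", "), "\n")
  cat("  interaction screen:", r$interaction_screen$n_interaction,
      "interaction /", r$interaction_screen$n_genotype, "genotype features\n")
  cat("  candidate cues:", paste(r$cues$candidates, collapse = ", "), "\n")
  cat(sprintf("  knockout reduction: %.1f%% | transcript knockdown: %.1f%%\n",
              r$targeted$percent_reduction_total, r$qpcr$knockdown_percent))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param x A `"rootcue_report"` object.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "rootcue_report"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
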