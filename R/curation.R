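#' Discard unretained mass features
#'
#' Removes features that elute in the void volume, where lack of retention
#' and excessive co-elution make identification unreliable. Features with
#' `rt < min_rt` are discarded; a feature at exactly `rt == min_rt` is
#' retained (the boundary convention is recorded in the attached counts).
#'
#' @param features Feature tibble (`feature_id`, `mz`, `rt`, one intensity
#'   column per sample).
#' @param min_rt Retention-time cut-off in minutes (default 0.3).
#' @return The filtered tibble, with an attribute `"removed"` giving the
#'   number of discarded features.
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 200, n_per_cell = 3,
#'                               n_diff_features = 10)
#' nrow(filter_retention_time(sim$features))
#' @export
filter_retention_time <- function(features, min_rt = 0.3) {
  check_feature_table(features)
  keep <- features$rt >= min_rt
  out <- features[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Discard features with implausible mass decimals
#'
#' Masses whose fractional part exceeds `max_frac` do not correspond to
#' feasible compounds of biological origin in the 100-1200 Da range and are
#' treated as instrument artifacts. The boundary is strict: a fractional
#' part equal to `max_frac` is retained.
#'
#' @inheritParams filter_retention_time
#' @param max_frac Largest admissible m/z fractional part (default 0.8).
#' @return The filtered tibble with attribute `"removed"`.
#' @export
filter_mass_decimal <- function(features, max_frac = 0.8) {
  check_feature_table(features)
  # tolerance absorbs binary representation error at the boundary
  # (e.g. 250.80 must be retained at max_frac = 0.8)
  keep <- (features$mz - floor(features$mz)) <= max_frac + 1e-9
  out <- features[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

# Enumerate candidate co-elution edges: pairs with |rt_i - rt_j| <= rt_window
# and Pearson r of raw intensities > r_min. Zero-variance features have
# undefined correlation and receive no edges.
coelution_edges <- function(features, rt_window = 0.04, r_min = 0.8) {
  n <- nrow(features)
  if (n < 2) return(tibble::tibble(from = character(), to = character()))
  x <- intensity_matrix(features)
  if (ncol(x) < 3) {
    warn("fewer than 3 samples: co-elution correlations are unstable.")
  }
  ord <- order(features$rt)
  rt <- features$rt[ord]
  ids <- features$feature_id[ord]
  x <- x[ord, , drop = FALSE]

  sds <- apply(x, 1, sd)
  z <- x - rowMeans(x)
  denom <- sqrt(rowSums(z^2))
  z <- z / ifelse(denom > 0, denom, 1)

  from <- to <- vector("list", n)
  j_hi <- 1L
  for (i in seq_len(n - 1L)) {
    while (j_hi < n && rt[j_hi + 1L] - rt[i] <= rt_window) j_hi <- j_hi + 1L
    if (j_hi <= i) next
    js <- (i + 1L):j_hi
    ok <- sds[i] > 0 & sds[js] > 0
    if (!any(ok)) next
    js <- js[ok]
    r <- as.vector(z[js, , drop = FALSE] %*% z[i, ])
    hit <- js[r > r_min]
    if (length(hit)) {
      from[[i]] <- rep(ids[i], length(hit))
      to[[i]] <- ids[hit]
    }
  }
  tibble::tibble(from = unlist(from) %||% character(),
                 to = unlist(to) %||% character())
}

#' Group co-eluting, correlated mass features into fragment groups
#'
#' Two features are linked when they elute within `rt_window` minutes of
#' each other and their raw intensities are Pearson-correlated with
#' `r > r_min` across all samples. Linked features are considered fragments
#' of the same compound. With `group_mode = "component"` (default) groups
#' are the connected components of this graph, the usual behavior of
#' co-elution grouping tools; `"clique"` additionally requires every pair
#' within a group to be linked, assigning features greedily (in decreasing
#' mean-abundance order) to the first clique they are fully linked to.
#' Features with zero intensity variance have undefined correlation and are
#' never linked.
#'
#' @inheritParams filter_retention_time
#' @param rt_window Co-elution window in minutes (default 0.04).
#' @param r_min Pearson correlation threshold; edges require `r > r_min`
#'   (default 0.8).
#' @param group_mode `"component"` (chain-wise) or `"clique"` (pairwise).
#' @return Tibble with `feature_id` and `group_id`. Groups partition the
#'   input: every feature belongs to exactly one group; unlinked features
#'   form singletons.
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 150, n_per_cell = 3,
#'                               n_diff_features = 10)
#' groups <- group_fragments(sim$features)
#' dplyr::count(groups, group_id)
#' @export
group_fragments <- function(features, rt_window = 0.04, r_min = 0.8,
                            group_mode = c("component", "clique")) {
  check_feature_table(features)
  group_mode <- match.arg(group_mode)
  edges <- coelution_edges(features, rt_window, r_min)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = features$feature_id)
  )
  comp <- igraph::components(g)$membership[features$feature_id]

  if (group_mode == "clique") {
    adj <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    mean_int <- rowMeans(intensity_matrix(features))
    clique_of <- setNames(rep(NA_integer_, nrow(features)), features$feature_id)
    next_id <- 0L
    cliques <- list()
    for (id in features$feature_id[order(-mean_int)]) {
      placed <- FALSE
      cand <- which(vapply(cliques, function(members) {
        all(paste(pmin(id, members), pmax(id, members)) %in% adj)
      }, logical(1)))
      if (length(cand)) {
        clique_of[id] <- cand[1]
        cliques[[cand[1]]] <- c(cliques[[cand[1]]], id)
        placed <- TRUE
      }
      if (!placed) {
        next_id <- next_id + 1L
        cliques[[next_id]] <- id
        clique_of[id] <- next_id
      }
    }
    comp <- clique_of[features$feature_id]
  }

  tibble::tibble(
    feature_id = features$feature_id,
    group_id = sprintf("G%05d", match(comp, unique(comp)))
  )
}

#' Select one representative feature per fragment group
#'
#' If a group contains a feature mapped to an identified compound, that
#' compound's deprotonated molecular ion (`[M-H]-`) feature is retained;
#' otherwise the member with the highest mean raw intensity across all
#' samples is retained. Two documented fall-backs: an identified compound
#' without an `[M-H]-` member falls back to the most abundant member (with a
#' warning), and a group containing two identified compounds is represented
#' by the one whose `[M-H]-` feature has the lowest m/z (with a warning).
#'
#' @inheritParams filter_retention_time
#' @param groups Tibble from [group_fragments()] (`feature_id`, `group_id`).
#' @param ids Optional identification map: tibble with `feature_id`,
#'   `compound`, `adduct` (adduct label `"[M-H]-"` marks the deprotonated
#'   molecular ion).
#' @return Tibble with `group_id`, `representative_id`, `rule` (one of
#'   `"identified"`, `"most_abundant"`), and `compound` (NA when
#'   unidentified).
#' @export
select_representative <- function(features, groups, ids = NULL) {
  check_feature_table(features)
  mean_int <- setNames(rowMeans(intensity_matrix(features)), features$feature_id)
  mz <- setNames(features$mz, features$feature_id)
  if (is.null(ids)) {
    ids <- tibble::tibble(feature_id = character(), compound = character(),
                          adduct = character())
  }

  pick_rep <- function(members) {
    hit <- ids[ids$feature_id %in% members, , drop = FALSE]
    if (nrow(hit)) {
      mh <- hit[hit$adduct == "[M-H]-", , drop = FALSE]
      if (nrow(mh) == 0) {
        warn(paste0("group with identified compound '", hit$compound[1],
                    "' has no [M-H]- member; falling back to most abundant."))
      } else {
        if (dplyr::n_distinct(mh$compound) > 1) {
          warn("group contains several identified compounds; keeping the lowest-m/z [M-H]- feature.")
          mh <- mh[order(mz[mh$feature_id]), , drop = FALSE]
        }
        return(list(id = mh$feature_id[1], rule = "identified",
                    compound = mh$compound[1]))
      }
      best <- members[which.max(mean_int[members])]
      return(list(id = best, rule = "most_abundant", compound = hit$compound[1]))
    }
    best <- members[which.max(mean_int[members])]
    list(id = best, rule = "most_abundant", compound = NA_character_)
  }

  groups |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(res = list(pick_rep(.data$feature_id)), .groups = "drop") |>
    dplyr::mutate(
      representative_id = purrr::map_chr(.data$res, "id"),
      rule = purrr::map_chr(.data$res, "rule"),
      compound = purrr::map_chr(.data$res, "compound")
    ) |>
    dplyr::select(-"res")
}

#' Curate an untargeted feature table down to informative features
#'
#' Runs the full curation cascade: retention-time exclusion, mass-decimal
#' exclusion, co-elution fragment grouping, and representative selection,
#' returning one informative feature per fragment group together with a
#' stage-by-stage bookkeeping report.
#'
#' @inheritParams group_fragments
#' @inheritParams select_representative
#' @param min_rt,max_frac,rt_window,r_min,group_mode Stage thresholds; see
#'   [filter_retention_time()], [filter_mass_decimal()], [group_fragments()].
#' @return A list of class `"curation"`:
#'   * `features`: tibble of informative (representative) features;
#'   * `groups`: feature -> group membership after filtering;
#'   * `representatives`: output of [select_representative()];
#'   * `report`: named list of counts (`n_raw`, `n_removed_rt`,
#'     `n_after_rt`, `n_removed_decimal`, `n_after_decimal`, `n_groups`,
#'     `n_informative`, plus boundary counts at the two filter thresholds).
#' @examples
#' sim <- simulate_feature_table(seed = 1, n_features = 300, n_per_cell = 4,
#'                               n_diff_features = 10)
#' cur <- curate(sim$features)
#' cur$report$n_informative
#' @export
curate <- function(features, ids = NULL, min_rt = 0.3, max_frac = 0.8,
                   rt_window = 0.04, r_min = 0.8,
                   group_mode = c("component", "clique")) {
  check_feature_table(features)
  group_mode <- match.arg(group_mode)
  n_raw <- nrow(features)
  f1 <- filter_retention_time(features, min_rt)
  f2 <- filter_mass_decimal(f1, max_frac)
  groups <- group_fragments(f2, rt_window, r_min, group_mode)
  reps <- select_representative(f2, groups, ids)
  informative <- f2[match(reps$representative_id, f2$feature_id), , drop = FALSE]

  report <- list(
    n_raw = n_raw,
    n_removed_rt = attr(f1, "removed"),
    n_after_rt = nrow(f1),
    n_at_rt_boundary = sum(features$rt == min_rt),
    n_removed_decimal = attr(f2, "removed"),
    n_after_decimal = nrow(f2),
    n_at_decimal_boundary = sum(f1$mz - floor(f1$mz) == max_frac),
    n_groups = dplyr::n_distinct(groups$group_id),
    n_informative = nrow(informative),
    thresholds = list(min_rt = min_rt, max_frac = max_frac,
                      rt_window = rt_window, r_min = r_min,
                      group_mode = group_mode)
  )
  structure(list(features = informative, groups = groups,
                 representatives = reps, report = report),
            class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  r <- x$report
  cat("Feature curation\n")
  cat(sprintf("  raw features:        %d\n", r$n_raw))
  cat(sprintf("  removed (rt < %.2f): %d -> %d retained\n",
              r$thresholds$min_rt, r$n_removed_rt, r$n_after_rt))
  cat(sprintf("  removed (decimal > %.1f): %d -> %d retained\n",
              r$thresholds$max_frac, r$n_removed_decimal, r$n_after_decimal))
  cat(sprintf("  fragment groups:     %d\n", r$n_groups))
  cat(sprintf("  informative features: %d\n", r$n_informative))
  invisible(x)
}
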