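#' Normalize compound names for cross-referencing
#'
#' Case-folds, trims and collapses whitespace, unifies unicode dashes, and
#' applies an explicit synonym map. No fuzzy matching is ever applied.
#'
#' @param x Character vector of compound names.
#' @param synonyms Optional tibble with columns `name` and `canonical`
#'   (matched after case-folding); defaults to the packaged synonym table.
#' @return Normalized names, same length as `x`.
#' @examples
#' normalize_compound(c("Glucose ", "DIMBOA-glucoside"))
#' @export
normalize_compound <- function(x, synonyms = load_synonyms()) {
  out <- stringr::str_to_lower(stringr::str_squish(x))
  out <- stringr::str_replace_all(out, "[‐-―]", "-")
  if (!is.null(synonyms) && nrow(synonyms)) {
    key <- stringr::str_to_lower(stringr::str_squish(synonyms$name))
    hit <- match(out, key)
    out[!is.na(hit)] <- stringr::str_to_lower(synonyms$canonical[hit[!is.na(hit)]])
  }
  out
}

#' Cross-reference enriched metabolites with known behaviorally active compounds
#'
#' Intersects the identified metabolites classified as enriched in the
#' preferred tissue with a literature-derived table of compounds known to
#' elicit behavioral responses, yielding candidate foraging cues. Compound
#' names are normalized on both sides via [normalize_compound()]. Unmatched
#' enriched names within edit distance 2 of an activity-table entry are
#' reported as warnings but never auto-matched.
#'
#' @param differential Tibble of identified metabolites with columns
#'   `compound` and `class` (as produced by the differential screen, e.g.
#'   `"postembryonic_enriched"`).
#' @param activity Activity table with columns `compound` and `activity`;
#'   defaults to the packaged table.
#' @param enriched_class Class label that qualifies a metabolite as a
#'   candidate (default `"postembryonic_enriched"`).
#' @param synonyms Synonym map passed to [normalize_compound()].
#' @return Tibble of candidate cues: `compound`, `class`, `activity`.
#' @examples
#' diffs <- tibble::tibble(
#'   compound = c("Glucose", "fructose", "DIMBOA", "DIMBOA-Glc", "leucine"),
#'   class = "postembryonic_enriched"
#' )
#' cross_reference(diffs)
#' @export
cross_reference <- function(differential,
                            activity = load_activity_table(),
                            enriched_class = "postembryonic_enriched",
                            synonyms = load_synonyms()) {
  if (nrow(activity) == 0) {
    warn("empty activity table: no candidates can be found.")
    return(tibble::tibble(compound = character(), class = character(),
                          activity = character()))
  }
  act <- activity |>
    dplyr::mutate(.norm = normalize_compound(.data$compound, synonyms)) |>
    dplyr::distinct(.data$.norm, .keep_all = TRUE)
  enr <- differential |>
    dplyr::filter(.data$class == enriched_class) |>
    dplyr::mutate(.norm = normalize_compound(.data$compound, synonyms)) |>
    dplyr::distinct(.data$.norm, .keep_all = TRUE)

  unmatched <- enr$.norm[!enr$.norm %in% act$.norm]
  if (length(unmatched)) {
    dist <- utils::adist(unmatched, act$.norm)
    near <- which(apply(dist, 1, min) <= 2 & apply(dist, 1, min) > 0)
    for (i in near) {
      warn(paste0("near-miss (not matched): '", unmatched[i], "' vs '",
                  act$.norm[which.min(dist[i, ])], "'"))
    }
  }
  enr[, c("compound", "class", ".norm")] |>
    dplyr::inner_join(act[, c(".norm", "activity")], by = ".norm") |>
    dplyr::select("compound", "class", "activity")
}
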