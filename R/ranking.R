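#' Intercellular centrality of each drug
#'
#' A drug's intercellular centrality is the sum of MCDM cell-type
#' centralities over the cell types that selected the drug as a candidate;
#' 0 for drugs selected nowhere.
#'
#' @param candidates Tibble with columns `cell_type`, `drug_id` (post
#'   pharmacology filtering).
#' @param centrality Tibble with columns `cell_type`, `centrality` (from
#'   [celltype_centrality()]).
#' @param drug_ids Optional character vector of drugs to cover (zeros for
#'   non-candidates).
#' @return A tibble with columns `drug_id`, `intercellular`,
#'   `n_selecting_cell_types`.
#' @export
drug_intercellular <- function(candidates, centrality, drug_ids = NULL) {
  scored <- candidates |>
    dplyr::left_join(centrality, by = "cell_type") |>
    dplyr::mutate(centrality = dplyr::coalesce(.data$centrality, 0)) |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(intercellular = sum(.data$centrality),
                     n_selecting_cell_types = dplyr::n(), .groups = "drop")
  if (!is.null(drug_ids)) {
    scored <- tibble::tibble(drug_id = unique(drug_ids)) |>
      dplyr::left_join(scored, by = "drug_id") |>
      dplyr::mutate(
        intercellular = dplyr::coalesce(.data$intercellular, 0),
        n_selecting_cell_types =
          dplyr::coalesce(.data$n_selecting_cell_types, 0L)
      )
  }
  scored
}

#' Centrality compound score
#'
#' `compound = intercellular + 0.1 x combined intracellular`: intercellular
#' centrality dominates the ranking and intracellular centrality acts as a
#' tie-breaker among drugs selected by the same cell types.
#'
#' @param intercellular Non-negative numeric vector.
#' @param combined_intracellular Non-negative numeric vector.
#' @param weight Weight on the intracellular term (default 0.1).
#' @return Numeric vector of compound scores.
#' @export
compound_score <- function(intercellular, combined_intracellular,
                           weight = 0.1) {
  stopifnot(all(intercellular >= 0), all(combined_intracellular >= 0))
  intercellular + weight * combined_intracellular
}

# signature identifying drugs with identical target sets and identical
# per-target actions ("mechanism of action")
tie_group_of <- function(drugs) {
  tbl <- tibble::as_tibble(drugs) |>
    dplyr::arrange(.data$drug_id, .data$target) |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(
      tie_group = paste(.data$target, .data$action, sep = ":",
                        collapse = "|"),
      .groups = "drop"
    )
  stats::setNames(tbl$tie_group, tbl$drug_id)
}

#' Rank the full drug library by compound centrality score
#'
#' Drugs selected as a candidate by at least one cell type are ranked first,
#' in descending compound-score order; the remaining library follows,
#' ordered by the intracellular term alone and then alphabetically by drug
#' ID (so every screened drug receives a rank). Before ranking, drugs with
#' identical target sets and identical per-target actions (biosimilars and
#' other same-mechanism entries) are forced into one tie group carrying the
#' group's best score and candidacy. Equal positions receive the average
#' rank, so ranks always sum to N(N+1)/2.
#'
#' @param drugs A `drug_table` covering the screened library.
#' @param candidates Tibble `cell_type`, `drug_id` of post-pharmacology
#'   candidates.
#' @param intra Tibble from [intracellular_scores()].
#' @param centrality Tibble from [celltype_centrality()].
#' @param weight Intracellular weight in the compound score (default 0.1).
#' @param relevant Optional character vector of relevant drug IDs; adds an
#'   `is_relevant` column.
#' @return A tibble of class `drug_ranking`, one row per drug, ordered by
#'   rank: `rank`, `drug_id`, `name`, `compound`, `intercellular`,
#'   `combined_intracellular`, `n_selecting_cell_types`, `is_candidate`,
#'   `tie_group` (and `is_relevant` when `relevant` is given).
#' @export
rank_drugs <- function(drugs, candidates, intra, centrality, weight = 0.1,
                       relevant = NULL) {
  ids <- sort(unique(drugs$drug_id))
  names_tbl <- tibble::as_tibble(drugs) |>
    dplyr::distinct(.data$drug_id, .data$name)
  inter <- drug_intercellular(candidates, centrality, drug_ids = ids)
  comb <- combined_intracellular(intra, drug_ids = ids)
  tg <- tie_group_of(drugs)

  tbl <- tibble::tibble(drug_id = ids) |>
    dplyr::left_join(names_tbl, by = "drug_id") |>
    dplyr::left_join(inter, by = "drug_id") |>
    dplyr::left_join(comb, by = "drug_id") |>
    dplyr::mutate(
      compound = compound_score(.data$intercellular,
                                .data$combined_intracellular, weight),
      is_candidate = .data$n_selecting_cell_types > 0L,
      tie_group = unname(tg[.data$drug_id])
    )

  # identical targets + mechanism of action => identical candidacy and score
  tbl <- tbl |>
    dplyr::group_by(.data$tie_group) |>
    dplyr::mutate(
      is_candidate = any(.data$is_candidate),
      compound = max(.data$compound),
      intercellular = max(.data$intercellular)
    ) |>
    dplyr::ungroup()

  # candidates first by compound; rest by the intracellular term; average
  # ranks within equal (candidacy, score) keys
  key_primary <- ifelse(tbl$is_candidate, 1, 0)
  ord_score <- key_primary * (max(tbl$compound) + 1) + tbl$compound
  tbl$rank <- rank(-ord_score, ties.method = "average")
  tbl <- tbl |>
    dplyr::arrange(.data$rank, .data$drug_id) |>
    dplyr::select("rank", "drug_id", "name", "compound", "intercellular",
                  "combined_intracellular", "n_selecting_cell_types",
                  "is_candidate", "tie_group")
  if (!is.null(relevant)) {
    tbl$is_relevant <- tbl$drug_id %in% relevant
  }
  class(tbl) <- c("drug_ranking", class(tbl))
  tbl
}

#' Precision and recall of a drug selection
#'
#' `precision = |relevant ∩ selection| / |selection|` and
#' `recall = |relevant ∩ selection| / |relevant|`.
#'
#' @param selection Character vector of selected drug IDs (non-empty).
#' @param relevant Character vector of relevant drug IDs (non-empty).
#' @return A tibble with columns `precision`, `recall`, `n_selected`,
#'   `n_relevant`, `n_hit`.
#' @export
precision_recall <- function(selection, relevant) {
  selection <- unique(selection)
  relevant <- unique(relevant)
  if (length(selection) == 0L) {
    stop("precision_recall: empty selection; precision undefined",
         call. = FALSE)
  }
  if (length(relevant) == 0L) {
    stop("precision_recall: empty relevant set; recall undefined",
         call. = FALSE)
  }
  hit <- length(intersect(selection, relevant))
  tibble::tibble(
    precision = hit / length(selection),
    recall = hit / length(relevant),
    n_selected = length(selection),
    n_relevant = length(relevant),
    n_hit = hit
  )
}

#' Precision among the top-ranked candidates
#'
#' Evaluates precision over all drugs with `rank <= k`. Because tied drugs
#' share an averaged rank, the evaluated set can be larger or smaller than
#' `k`.
#'
#' @param ranking A `drug_ranking` tibble from [rank_drugs()].
#' @param relevant Character vector of relevant drug IDs.
#' @param k Rank cut-off (default 100).
#' @return A scalar precision, or `NA` when no drug has `rank <= k`.
#' @export
precision_at_rank <- function(ranking, relevant, k = 100) {
  top <- ranking$drug_id[ranking$rank <= k]
  if (length(top) == 0L) return(NA_real_)
  precision_recall(top, relevant)$precision
}

#' Plot precision against rank cut-off for a drug ranking
#'
#' @param object A `drug_ranking` with an `is_relevant` column (rank with
#'   `relevant =` to get one).
#' @param ... Unused.
#' @return A ggplot object showing precision among drugs with rank <= k as k
#'   sweeps the ranked library.
#' @method autoplot drug_ranking
#' @export
autoplot.drug_ranking <- function(object, ...) {
  if (is.null(object$is_relevant)) {
    stop("autoplot.drug_ranking: ranking lacks an is_relevant column",
         call. = FALSE)
  }
  ks <- sort(unique(ceiling(object$rank)))
  curve <- tibble::tibble(
    k = ks,
    precision = vapply(ks, function(k) {
      mean(object$is_relevant[object$rank <= k])
    }, numeric(1))
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank cut-off k", y = "precision among rank <= k") +
    ggplot2::theme_minimal()
}
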