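#' Does a drug's action on a target counteract its fold change?
#'
#' A drug counteracts a differentially expressed target when it inhibits an
#' upregulated gene or activates a downregulated one. Targets whose
#' pharmacological action is unknown are assumed not to counteract.
#'
#' @param action Character vector in `{"activate", "inhibit", "unknown"}`.
#' @param logfc Signed log fold changes (non-zero).
#' @return Logical vector.
#' @export
counteracts <- function(action, logfc) {
  stopifnot(length(action) == length(logfc))
  if (any(logfc == 0)) {
    stop("counteracts: zero log fold change carries no direction",
         call. = FALSE)
  }
  bad <- !action %in% c("activate", "inhibit", "unknown")
  if (any(bad)) {
    stop("counteracts: invalid action value(s): ",
         paste(unique(action[bad]), collapse = ", "), call. = FALSE)
  }
  (action == "inhibit" & logfc > 0) | (action == "activate" & logfc < 0)
}

#' Per-target action calls for candidate drugs
#'
#' Joins each candidate (cell type, drug) pair with the drug's targets that
#' are DEGs of that cell type and evaluates counteraction per target.
#'
#' @param candidates Tibble with columns `cell_type`, `drug_id` (e.g. from
#'   [select_candidates()]).
#' @param drugs A `drug_table`.
#' @param degs A DEG tibble.
#' @return A tibble with columns `cell_type`, `drug_id`, `gene`, `action`,
#'   `logfc`, `counteracts` — one row per (candidate pair, targeted DEG).
#' @export
action_calls <- function(candidates, drugs, degs) {
  missing_drugs <- setdiff(candidates$drug_id, drugs$drug_id)
  if (length(missing_drugs) > 0L) {
    stop("action_calls: candidate drug(s) absent from drug table: ",
         paste(utils::head(missing_drugs, 5L), collapse = ", "),
         call. = FALSE)
  }
  candidates |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(drugs), "drug_id",
                    gene = "target", "action"),
      by = "drug_id", relationship = "many-to-many"
    ) |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(degs), "cell_type", "gene", "logfc"),
      by = c("cell_type", "gene")
    ) |>
    dplyr::mutate(counteracts = counteracts(.data$action, .data$logfc))
}

#' Filter candidates by pharmacological counteraction
#'
#' A drug survives in a cell type iff at least one of its targets is a DEG of
#' that cell type whose fold change the drug counteracts (inhibiting an
#' upregulated DEG or activating a downregulated one). Drugs whose targeted
#' DEGs all have unknown or aggravating actions are removed — this is what
#' excludes, e.g., an agonist of an upregulated cytokine that network
#' proximity alone would keep.
#'
#' @inheritParams action_calls
#' @return A tibble with columns `cell_type`, `drug_id` of surviving pairs
#'   (a subset of `candidates`).
#' @export
filter_by_action <- function(candidates, drugs, degs) {
  calls <- action_calls(candidates, drugs, degs)
  kept <- calls |>
    dplyr::group_by(.data$cell_type, .data$drug_id) |>
    dplyr::summarise(any_counter = any(.data$counteracts),
                     .groups = "drop") |>
    dplyr::filter(.data$any_counter) |>
    dplyr::select("cell_type", "drug_id")
  # preserve the candidate table's row order
  dplyr::semi_join(candidates, kept, by = c("cell_type", "drug_id"))
}
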