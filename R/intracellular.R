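#' Disease modules: largest connected DEG component per cell type
#'
#' For each cell type, induces the subgraph of the interactome on that cell
#' type's in-network DEGs and keeps its largest connected component — the
#' cell type's disease module. Ties between equal-sized components are broken
#' towards the component containing the smallest gene ID. Within each module,
#' eigenvector centralities are computed on the module subgraph and
#' max-normalised to 1; a single-gene module has centrality 1.
#'
#' Cell types whose DEGs form no connected pair (or that have no in-network
#' DEG) have an empty module and are absent from the output; every drug's
#' intracellular score for such a cell type is 0.
#'
#' @param degs A DEG tibble (see [read_degs()]).
#' @param interactome An `interactome`.
#' @return A tibble of class `disease_modules` with columns `cell_type`,
#'   `gene`, `centrality` (in (0, 1], max 1 within each cell type).
#' @export
deg_lcc <- function(degs, interactome) {
  sets <- deg_sets(degs)
  out <- purrr::imap(sets, function(genes, ct) {
    module <- lcc_genes(genes, interactome)
    if (length(module) == 0L) return(NULL)
    cen <- module_centrality(module, interactome)
    tibble::tibble(cell_type = ct, gene = module, centrality = unname(cen))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(cell_type = character(), gene = integer(),
                          centrality = double())
  }
  class(res) <- c("disease_modules", class(res))
  res
}

# largest connected component of the induced DEG subgraph; empty if no edge
lcc_genes <- function(genes, interactome) {
  genes <- unique(as.integer(genes))
  genes <- genes[in_interactome(genes, interactome)]
  if (length(genes) == 0L) return(integer(0))
  sub <- igraph::induced_subgraph(interactome$graph, as.character(genes))
  comp <- igraph::components(sub)
  ids <- as.integer(igraph::V(sub)$name)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    min_id <- vapply(best, function(ci) min(ids[comp$membership == ci]),
                     numeric(1))
    best <- best[which.min(min_id)]
  }
  module <- sort(ids[comp$membership == best])
  if (length(module) < 2L) return(integer(0))  # all DEGs isolated
  module
}

# max-normalised eigenvector centrality of the connected module subgraph
module_centrality <- function(module, interactome) {
  sub <- igraph::induced_subgraph(interactome$graph, as.character(module))
  if (length(module) == 1L) {
    return(stats::setNames(1, as.character(module)))
  }
  # igraph >= 2.1 always max-normalises (scale = TRUE behaviour)
  ec <- igraph::eigen_centrality(sub, directed = FALSE)$vector
  if (any(ec <= 0)) {
    stop("module_centrality: non-positive eigenvector entry on a connected ",
         "module; eigensolver did not converge", call. = FALSE)
  }
  stats::setNames(ec[as.character(sort(module))], as.character(sort(module)))
}

#' Geometric mean of one drug's in-module target centralities
#'
#' @param targets Integer gene IDs of the drug's targets.
#' @param centrality Named numeric vector of module centralities (names =
#'   gene IDs).
#' @return The geometric mean of the centralities of `targets` that lie in
#'   the module; 0 if none does.
#' @export
drug_intracellular <- function(targets, centrality) {
  hit <- centrality[as.character(targets)]
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) return(0)
  exp(mean(log(hit)))
}

#' Intracellular centrality scores of all drugs across cell types
#'
#' Scores each drug in each cell type by the geometric mean of the
#' eigenvector centralities of its targets inside that cell type's disease
#' module; 0 when the drug targets no module gene. The combined intracellular
#' centrality of a drug is the sum of its per-cell-type scores.
#'
#' @param drugs A `drug_table`.
#' @param modules A `disease_modules` tibble from [deg_lcc()].
#' @return A tibble with columns `drug_id`, `cell_type`, `intracellular`,
#'   covering every drug x module cell type combination (zeros included).
#' @export
intracellular_scores <- function(drugs, modules) {
  recs <- drug_records(drugs)
  cts <- unique(modules$cell_type)
  if (length(cts) == 0L || length(recs) == 0L) {
    return(tibble::tibble(drug_id = character(), cell_type = character(),
                          intracellular = double()))
  }
  cen_by_ct <- modules |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_map(~ stats::setNames(.x$centrality,
                                       as.character(.x$gene))) |>
    stats::setNames(sort(cts))
  tidyr::expand_grid(drug_id = names(recs), cell_type = sort(cts)) |>
    dplyr::mutate(intracellular = purrr::map2_dbl(
      .data$drug_id, .data$cell_type,
      function(d, ct) drug_intracellular(recs[[d]]$targets, cen_by_ct[[ct]])
    ))
}

#' Combined (summed) intracellular centrality per drug
#'
#' @param intra A tibble from [intracellular_scores()].
#' @param drug_ids Optional character vector of drugs to cover; drugs with no
#'   module hit anywhere get 0.
#' @return A tibble with columns `drug_id`, `combined_intracellular`.
#' @export
combined_intracellular <- function(intra, drug_ids = NULL) {
  out <- intra |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(combined_intracellular = sum(.data$intracellular),
                     .groups = "drop")
  if (!is.null(drug_ids)) {
    out <- tibble::tibble(drug_id = unique(drug_ids)) |>
      dplyr::left_join(out, by = "drug_id") |>
      dplyr::mutate(combined_intracellular =
                      dplyr::coalesce(.data$combined_intracellular, 0))
  }
  out
}
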