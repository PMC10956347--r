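#' Run the full cell-type-resolved drug prioritisation pipeline
#'
#' Executes, in order: optional per-cell-type DEG capping, the
#' network-proximity permutation screen ([proximity_screen()] +
#' [select_candidates()]), the pharmacological-action filter
#' ([filter_by_action()]), disease-module construction and intracellular
#' scoring ([deg_lcc()], [intracellular_scores()]), multicellular disease
#' model construction ([build_mcdm()]), and compound-score ranking
#' ([rank_drugs()]) with optional precision/recall evaluation.
#'
#' All thresholds default to the published screening conventions: 1000
#' permutation iterations, minimal degree-bin size 100, `z_c < -1.64`
#' (one-sided P < 0.05) and `d_c < 1` for candidate selection, background
#' cut-off `Ea >= 0.2`, intracellular weight 0.1, top-100 evaluation.
#'
#' @param data A list with elements `interactome`, `drugs`, `degs`, `expr`,
#'   `prior` and optionally `relevant` — e.g. a `fixture_bundle` from
#'   [generate_fixture()] or the result of [read_fixture()].
#' @param n_iter Permutation iterations for the proximity null.
#' @param seed Global integer seed.
#' @param min_bin Minimal degree-bin size for randomisation.
#' @param z_thresh,d_thresh Strict selection cut-offs on `z_c` and `d_c`.
#' @param ea_cutoff Background-gene cut-off on mean aggregate expression.
#' @param max_degs Optional cap on DEGs per cell type (most significant
#'   first).
#' @param intracellular_weight Weight of combined intracellular centrality in
#'   the compound score.
#' @param top_k Rank cut-off for the evaluation stage.
#' @param out_dir Optional directory; when given, every stage table plus a
#'   run manifest is written there as TSV.
#' @return An object of class `drug_screen`: a list with the stage tables
#'   `proximity`, `proximity_candidates`, `candidates` (post-pharmacology),
#'   `modules`, `intracellular`, `mcdm`, `celltype_centrality`, `ranking`,
#'   `evaluation` (`NULL` without a relevant list) and `config`.
#' @export
run_pipeline <- function(data, n_iter = 1000, seed = 1L, min_bin = 100,
                         z_thresh = -1.64, d_thresh = 1.0, ea_cutoff = 0.2,
                         max_degs = NULL, intracellular_weight = 0.1,
                         top_k = 100, out_dir = NULL) {
  needed <- c("interactome", "drugs", "degs", "expr", "prior")
  missing_in <- setdiff(needed, names(data))
  if (length(missing_in) > 0L) {
    stop("run_pipeline: missing input(s): ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  config <- list(n_iter = n_iter, seed = seed, min_bin = min_bin,
                 z_thresh = z_thresh, d_thresh = d_thresh,
                 ea_cutoff = ea_cutoff, max_degs = max_degs,
                 intracellular_weight = intracellular_weight, top_k = top_k)

  degs <- cap_degs(data$degs, max_degs)

  prox <- proximity_screen(data$drugs, degs, data$interactome,
                           n_iter = n_iter, seed = seed, min_bin = min_bin)
  prox_cand <- select_candidates(prox, z_thresh = z_thresh,
                                 d_thresh = d_thresh)
  cand <- filter_by_action(prox_cand, data$drugs, degs)

  modules <- deg_lcc(degs, data$interactome)
  intra <- intracellular_scores(data$drugs, modules)

  mcdm <- build_mcdm(degs, data$prior, data$expr, ea_cutoff = ea_cutoff)
  centrality <- celltype_centrality(mcdm)

  ranking <- rank_drugs(data$drugs, cand, intra, centrality,
                        weight = intracellular_weight,
                        relevant = data$relevant)

  evaluation <- NULL
  if (!is.null(data$relevant)) {
    evaluation <- tibble::tibble(
      k = top_k,
      precision = precision_at_rank(ranking, data$relevant, k = top_k),
      recall = length(intersect(ranking$drug_id[ranking$rank <= top_k],
                                data$relevant)) /
        length(unique(data$relevant))
    )
  }

  res <- structure(
    list(proximity = prox, proximity_candidates = prox_cand,
         candidates = cand, modules = modules, intracellular = intra,
         mcdm = mcdm, celltype_centrality = centrality, ranking = ranking,
         evaluation = evaluation, config = config),
    class = "drug_screen"
  )
  if (!is.null(out_dir)) write_drug_screen(res, out_dir)
  res
}

#' @export
print.drug_screen <- function(x, ...) {
  cat("<drug_screen>\n",
      "  drugs screened:      ", dplyr::n_distinct(x$ranking$drug_id), "\n",
      "  cell types screened: ",
      dplyr::n_distinct(x$proximity$cell_type), "\n",
      "  candidate pairs:     ", nrow(x$candidates), "\n",
      "  candidate drugs:     ", dplyr::n_distinct(x$candidates$drug_id),
      "\n", sep = "")
  if (!is.null(x$evaluation)) {
    cat("  precision at rank <= ", x$evaluation$k, ": ",
        round(100 * x$evaluation$precision, 1), "%\n", sep = "")
  }
  invisible(x)
}

#' Tidy a drug screen into its final ranking table
#'
#' @param x A `drug_screen`.
#' @param ... Unused.
#' @return The `drug_ranking` tibble.
#' @method tidy drug_screen
#' @export
tidy.drug_screen <- function(x, ...) {
  x$ranking
}

#' One-row summary of a drug screen
#'
#' @param x A `drug_screen`.
#' @param ... Unused.
#' @return A one-row tibble: `n_drugs`, `n_cell_types`, `n_candidate_drugs`,
#'   `n_candidate_pairs`, `top_k`, `precision_top_k`, `recall_top_k` (the
#'   last two `NA` without a relevant-drug list).
#' @method glance drug_screen
#' @export
glance.drug_screen <- function(x, ...) {
  tibble::tibble(
    n_drugs = dplyr::n_distinct(x$ranking$drug_id),
    n_cell_types = dplyr::n_distinct(x$proximity$cell_type),
    n_candidate_drugs = dplyr::n_distinct(x$candidates$drug_id),
    n_candidate_pairs = nrow(x$candidates),
    top_k = x$config$top_k,
    precision_top_k = if (is.null(x$evaluation)) NA_real_ else
      x$evaluation$precision,
    recall_top_k = if (is.null(x$evaluation)) NA_real_ else
      x$evaluation$recall
  )
}

#' Plot a drug screen
#'
#' Dispatches to the precision-rank curve of the final ranking when a
#' relevant list was supplied, otherwise to the MCDM graph.
#'
#' @param object A `drug_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drug_screen
#' @export
autoplot.drug_screen <- function(object, ...) {
  if (!is.null(object$ranking$is_relevant)) {
    autoplot.drug_ranking(object$ranking)
  } else {
    autoplot.mcdm(object$mcdm)
  }
}

#' Write every stage table of a drug screen to a directory
#'
#' Writes `proximity.tsv`, `proximity_candidates.tsv`, `candidates.tsv`,
#' `modules.tsv`, `intracellular.tsv`, `mcdm_interactions.tsv`,
#' `mcdm_edges.tsv`, `celltype_centrality.tsv`, `ranking.tsv`,
#' `evaluation.tsv` (when computed) and a `manifest.tsv` with the config
#' echo and MD5 checksums of every written table.
#'
#' @param x A `drug_screen`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_drug_screen <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    proximity = x$proximity,
    proximity_candidates = x$proximity_candidates,
    candidates = x$candidates,
    modules = x$modules,
    intracellular = x$intracellular,
    mcdm_interactions = x$mcdm$interactions,
    mcdm_edges = x$mcdm$edges,
    celltype_centrality = x$celltype_centrality,
    ranking = x$ranking
  )
  if (!is.null(x$evaluation)) tables$evaluation <- x$evaluation
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tables[[nm]]), p, progress = FALSE)
    paths[nm] <- p
  }
  cfg <- x$config
  cfg$max_degs <- if (is.null(cfg$max_degs)) NA else cfg$max_degs
  manifest <- tibble::tibble(
    key = c(names(cfg), paste0("md5_", names(paths))),
    value = c(vapply(cfg, function(v) as.character(v), character(1)),
              unname(tools::md5sum(paths)))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}
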