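#' Mean aggregate expression Ea per gene within a cell type
#'
#' For a denoised log10-scale expression matrix D over the k cells of one
#' cell type, the mean aggregate expression of gene i is
#' `Ea(i) = log2( sum_j 10^D_ij / k )`, i.e. the log2 of the arithmetic mean
#' of the de-logged expression values.
#'
#' @param expr An `expression_matrix`.
#' @param cell_type Cell-type label present in `expr`.
#' @param genes Optional integer gene IDs to evaluate (default: all genes in
#'   the matrix).
#' @return A tibble with columns `gene` and `ea`.
#' @export
aggregate_expression <- function(expr, cell_type, genes = NULL) {
  cells <- names(expr$cell_type_of)[expr$cell_type_of == cell_type]
  if (length(cells) == 0L) {
    stop("aggregate_expression: unknown cell type '", cell_type, "'",
         call. = FALSE)
  }
  vals <- expr$values[, cells, drop = FALSE]
  if (!is.null(genes)) {
    vals <- vals[as.character(genes), , drop = FALSE]
  }
  ea <- log2(rowMeans(10^vals))
  tibble::tibble(gene = as.integer(rownames(vals)), ea = unname(ea))
}

#' Background genes of a cell type
#'
#' Background genes are those whose mean aggregate expression passes the
#' cut-off, `Ea(i) >= cutoff` (inclusive, default 0.2). They form the
#' evaluation universe against which ligand activities are scored for that
#' cell type as a receiver.
#'
#' @inheritParams aggregate_expression
#' @param cutoff Inclusive lower bound on `Ea` (default 0.2).
#' @return An integer vector of background gene IDs.
#' @export
background_genes <- function(expr, cell_type, cutoff = 0.2) {
  ea <- aggregate_expression(expr, cell_type)
  bg <- ea$gene[ea$ea >= cutoff]
  if (length(bg) == 0L) {
    stop("background_genes: no gene passes Ea >= ", cutoff,
         " in cell type '", cell_type, "'", call. = FALSE)
  }
  bg
}

#' Ligand activity as Pearson correlation against a regulatory prior
#'
#' Scores how well a ligand's regulatory-potential profile predicts
#' membership in a gene set of interest (the receiver's DEGs) relative to
#' background genes: the Pearson correlation, over the evaluation universe
#' `(background U gene_set) ∩ prior genes`, between the ligand's potentials
#' and the binary gene-set indicator. Positive values mean the ligand's
#' predicted targets are enriched among the receiver's DEGs.
#'
#' @param ligand Integer gene ID of the ligand; must be a row of `prior`.
#' @param prior A `ligand_prior` matrix.
#' @param gene_set Integer gene IDs of the receiver's gene set of interest.
#' @param background Integer gene IDs of the receiver's background genes.
#' @return A scalar Pearson correlation in [-1, 1]; 0 with a warning when
#'   either vector has zero variance over the universe.
#' @export
ligand_activity <- function(ligand, prior, gene_set, background) {
  ligand <- as.character(ligand)
  if (!ligand %in% rownames(prior)) {
    stop("ligand_activity: ligand ", ligand, " absent from the prior",
         call. = FALSE)
  }
  universe <- union(as.integer(background), as.integer(gene_set))
  universe <- intersect(universe, as.integer(colnames(prior)))
  if (length(universe) < 3L) {
    stop("ligand_activity: evaluation universe has fewer than 3 genes",
         call. = FALSE)
  }
  pot <- prior[ligand, as.character(universe)]
  ind <- as.numeric(universe %in% as.integer(gene_set))
  if (stats::sd(pot) == 0 || stats::sd(ind) == 0) {
    warning("ligand_activity: zero variance over the evaluation universe; ",
            "activity set to 0", call. = FALSE)
    return(0)
  }
  stats::cor(pot, ind)
}

#' Build the multicellular disease model (MCDM)
#'
#' For every ordered (sender, receiver) pair of DEG-bearing cell types —
#' including self-pairs — the candidate ligands are the sender's DEGs that
#' appear as ligands of the prior; each is scored by [ligand_activity()]
#' against the receiver's DEG set over the receiver's background genes. Only
#' ligand interactions with a strictly positive Pearson coefficient enter the
#' model; the directed edge weight between two cell types is the sum of its
#' kept ligands' coefficients. Cell-type eigenvector centralities are
#' computed on the weighted directed graph.
#'
#' @param degs A DEG tibble (see [read_degs()]).
#' @param prior A `ligand_prior` matrix.
#' @param expr An `expression_matrix`.
#' @param ea_cutoff Background-gene cut-off on mean aggregate expression.
#' @return An object of class `mcdm`: list with `interactions` (tibble
#'   `sender`, `receiver`, `ligand`, `pearson` of kept positive
#'   interactions), `edges` (tibble `sender`, `receiver`, `weight`),
#'   `cell_types` (DEG-bearing cell types), and `centrality` (tibble
#'   `cell_type`, `centrality`, max-normalised to 1).
#' @export
build_mcdm <- function(degs, prior, expr, ea_cutoff = 0.2) {
  sets_all <- split(degs$gene, degs$cell_type)  # DEG status, in-network or not
  cts <- names(sets_all)[lengths(sets_all) > 0L]
  if (length(cts) == 0L) {
    stop("build_mcdm: no cell type carries DEGs", call. = FALSE)
  }
  prior_ligands <- as.integer(rownames(prior))
  backgrounds <- lapply(stats::setNames(cts, cts), function(ct) {
    background_genes(expr, ct, cutoff = ea_cutoff)
  })

  inter <- purrr::map(cts, function(sender) {
    ligands <- intersect(sets_all[[sender]], prior_ligands)
    if (length(ligands) == 0L) return(NULL)
    purrr::map(cts, function(receiver) {
      r <- vapply(ligands, function(lg) {
        ligand_activity(lg, prior, sets_all[[receiver]],
                        backgrounds[[receiver]])
      }, numeric(1))
      keep <- r > 0
      if (!any(keep)) return(NULL)
      tibble::tibble(sender = sender, receiver = receiver,
                     ligand = ligands[keep], pearson = r[keep])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  if (nrow(inter) == 0L) {
    inter <- tibble::tibble(sender = character(), receiver = character(),
                            ligand = integer(), pearson = double())
  }
  edges <- inter |>
    dplyr::group_by(.data$sender, .data$receiver) |>
    dplyr::summarise(weight = sum(.data$pearson), .groups = "drop")

  structure(
    list(interactions = inter, edges = edges, cell_types = cts,
         centrality = celltype_centrality_impl(edges, cts)),
    class = "mcdm"
  )
}

#' @export
print.mcdm <- function(x, ...) {
  cat("<mcdm> ", length(x$cell_types), " cell types, ", nrow(x$edges),
      " directed edges, ", nrow(x$interactions), " ligand interactions\n",
      sep = "")
  invisible(x)
}

#' Cell-type eigenvector centralities of an MCDM
#'
#' Eigenvector centrality on the weighted directed cell-type graph: a cell
#' type's score is proportional to the weighted sum of the scores of cell
#' types signalling *to* it (receiver-importance convention), max-normalised
#' to 1. When the directed spectrum is degenerate — e.g. the graph is
#' reducible and the principal eigenvector is supported on a strict subset of
#' the connected cell types — the computation falls back to the symmetrised
#' graph with a message. Cell types touching no edge score 0.
#'
#' @param m An `mcdm` object.
#' @return A tibble with columns `cell_type`, `centrality`.
#' @export
celltype_centrality <- function(m) {
  m$centrality
}

celltype_centrality_impl <- function(edges, cell_types) {
  n <- length(cell_types)
  if (nrow(edges) == 0L) {
    warning("celltype_centrality: MCDM has no edges; all centralities 0",
            call. = FALSE)
    return(tibble::tibble(cell_type = cell_types, centrality = 0))
  }
  A <- matrix(0, n, n, dimnames = list(cell_types, cell_types))
  A[cbind(edges$sender, edges$receiver)] <- edges$weight
  connected <- rowSums(A) > 0 | colSums(A) > 0

  x <- directed_principal_vector(t(A))  # in-edge convention: x = A' x / lambda
  degenerate <- is.null(x) || any(x[connected] <= 1e-8 * max(x))
  if (degenerate) {
    message("celltype_centrality: degenerate directed spectrum; ",
            "falling back to the symmetrised graph")
    x <- power_iteration(A + t(A))
    if (is.null(x)) x <- stats::setNames(rep(0, n), cell_types)
  }
  x[!connected] <- 0
  if (max(x) > 0) x <- x / max(x)
  tibble::tibble(cell_type = cell_types, centrality = unname(x[cell_types]))
}

# principal eigenvector of a small non-negative matrix via dense
# eigendecomposition; NULL when the Perron root vanishes or the dominant
# eigenvalue is not attained by a real non-negative direction (reducible or
# purely rotational spectra), in which case the caller falls back
directed_principal_vector <- function(M, tol = 1e-9) {
  ev <- eigen(M)
  mods <- Mod(ev$values)
  top <- max(mods)
  if (top <= tol) return(NULL)
  # among eigenvalues tied at the Perron modulus, require a real one
  cand <- which(mods >= top - tol * max(1, top))
  real_cand <- cand[abs(Im(ev$values[cand])) <= tol * max(1, top) &
                      Re(ev$values[cand]) > 0]
  if (length(real_cand) == 0L) return(NULL)
  i <- real_cand[1L]
  v <- ev$vectors[, i]
  if (max(abs(Im(v))) > 1e-8 * max(Mod(v))) return(NULL)
  v <- Re(v)
  if (max(abs(v)) <= 0) return(NULL)
  v <- v * sign(v[which.max(abs(v))])
  if (min(v) < -1e-8 * max(abs(v))) return(NULL)  # mixed signs: degenerate
  v <- pmax(v, 0)
  stats::setNames(v / max(v), rownames(M))
}

# dominant eigenvector of a non-negative matrix, max-normalised; a diagonal
# shift (which leaves eigenvectors unchanged) makes the leading eigenvalue
# strictly dominant, so bipartite and cyclic structures cannot oscillate.
# NULL when the dominant direction degenerates to zero (e.g. a nilpotent
# directed adjacency, where the iteration collapses onto a strict subset).
power_iteration <- function(M, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(M)
  shift <- max(rowSums(M))
  if (shift <= 0) return(NULL)
  Ms <- M + diag(shift, n)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    y <- as.vector(Ms %*% x)
    nm <- max(y)
    if (nm <= tol) return(NULL)
    y <- y / nm
    if (max(abs(y - x)) < tol) {
      return(stats::setNames(y, rownames(M)))
    }
    x <- y
  }
  stats::setNames(x, rownames(M))
}

#' Tidy an MCDM into its aggregate edge table
#'
#' @param x An `mcdm`.
#' @param ... Unused.
#' @return A tibble with columns `sender`, `receiver`, `weight`.
#' @method tidy mcdm
#' @export
tidy.mcdm <- function(x, ...) {
  x$edges
}

#' Plot an MCDM as a weighted directed cell-type graph
#'
#' Nodes are placed on a circle; edge width is proportional to the summed
#' positive ligand-activity weight, node size to the cell type's eigenvector
#' centrality.
#'
#' @param object An `mcdm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcdm
#' @export
autoplot.mcdm <- function(object, ...) {
  cts <- object$cell_types
  theta <- seq(0, 2 * pi, length.out = length(cts) + 1L)[seq_along(cts)]
  layout <- tibble::tibble(cell_type = cts, x = cos(theta), y = sin(theta)) |>
    dplyr::left_join(object$centrality, by = "cell_type")
  seg <- object$edges |>
    dplyr::left_join(layout, by = c("sender" = "cell_type")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(dplyr::select(layout, "cell_type", "x", "y"),
                     by = c("receiver" = "cell_type"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linewidth = .data$weight),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$centrality),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x * 1.15, y = .data$y * 1.15,
                   label = .data$cell_type)
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(size = "centrality", linewidth = "weight")
}
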