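#' Read a protein-protein interaction network and keep its largest connected
#' component
#'
#' Reads a headerless two-column TSV of integer gene IDs, one undirected
#' interaction per row. Self-loops and duplicate edges are dropped, and only
#' the largest connected component (LCC) of the remaining graph is retained,
#' since network distances are only meaningful within one component. Ties
#' between equal-sized components are broken towards the component containing
#' the smallest gene ID.
#'
#' @param path Path to a headerless 2-column TSV edge list of integer gene IDs.
#' @param quiet Suppress the message reporting dropped nodes/edges.
#' @return An object of class `interactome`: a list with elements
#'   `graph` (an undirected [igraph::igraph] whose vertex names are the gene
#'   IDs), `nodes` (sorted integer gene IDs), and `degree` (named integer
#'   vector of node degrees).
#' @export
read_interactome <- function(path, quiet = FALSE) {
  edges <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = "integer", col.names = c("from", "to")),
    error = function(e) {
      stop("malformed interactome edge list '", path, "': ", conmsg(e),
           call. = FALSE)
    }
  )
  if (nrow(edges) < 1L) stop("interactome edge list is empty", call. = FALSE)
  bad <- which(is.na(edges$from) | is.na(edges$to))
  if (length(bad) > 0L) {
    stop("non-integer gene ID in interactome at line ", bad[1L], call. = FALSE)
  }
  as_interactome(edges, quiet = quiet)
}

conmsg <- function(e) conditionMessage(e)

#' Build an interactome object from an in-memory edge table
#'
#' @param edges A data frame with two integer columns (`from`, `to`).
#' @param quiet Suppress the dropped-count message.
#' @return An `interactome` object; see [read_interactome()].
#' @export
as_interactome <- function(edges, quiet = FALSE) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  from <- as.integer(edges[[1L]])
  to <- as.integer(edges[[2L]])
  keep <- from != to
  n_loops <- sum(!keep)
  from <- from[keep]
  to <- to[keep]
  # canonical unordered pairs for dedup
  key <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  from <- from[!dup]
  to <- to[!dup]
  if (length(from) == 0L) stop("interactome has no valid edges", call. = FALSE)

  all_nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(all_nodes))
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie-break: component containing the smallest gene ID
    min_id <- vapply(biggest, function(ci) {
      min(all_nodes[comp$membership == ci])
    }, numeric(1))
    biggest <- biggest[which.min(min_id)]
  }
  keep_v <- comp$membership == biggest
  n_drop_nodes <- sum(!keep_v)
  g <- igraph::induced_subgraph(g, which(keep_v))
  nodes <- sort(as.integer(igraph::V(g)$name))
  g <- igraph::permute(g, match(as.integer(igraph::V(g)$name), nodes))
  deg <- igraph::degree(g)
  if (!quiet && (n_loops + n_dup + n_drop_nodes) > 0L) {
    message("interactome: dropped ", n_loops, " self-loop(s), ", n_dup,
            " duplicate edge(s), ", n_drop_nodes,
            " node(s) outside the largest connected component")
  }
  structure(
    list(graph = g, nodes = nodes,
         degree = stats::setNames(as.integer(deg), igraph::V(g)$name)),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", length(x$nodes), " genes, ",
      igraph::ecount(x$graph), " interactions (largest connected component)\n",
      sep = "")
  invisible(x)
}

#' Tidy an interactome into its edge table
#'
#' @param x An `interactome`.
#' @param ... Unused.
#' @return A tibble with integer columns `from` and `to`, one row per
#'   undirected interaction.
#' @method tidy interactome
#' @export
tidy.interactome <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  tibble::tibble(from = as.integer(el[, 1L]), to = as.integer(el[, 2L]))
}

#' Write an interactome as an edge-list TSV
#'
#' @param x An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(x, path) {
  utils::write.table(tidy.interactome(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

in_interactome <- function(genes, interactome) {
  genes %in% interactome$nodes
}

#' Read a drug-target table and restrict it to the interactome
#'
#' Reads a TSV with header columns `drug_id`, `name`, `target`, `action` and
#' zero or more `flag_*` indication columns. Targets absent from the
#' interactome are removed; drugs left with no in-network target are excluded
#' from screening entirely (network-based selection cannot say anything about
#' them). Duplicate (drug, target) rows are deduplicated, keeping the last
#' action with a warning.
#'
#' @param path Path to the drug TSV.
#' @param interactome An `interactome` from [read_interactome()].
#' @param quiet Suppress the exclusion-count message.
#' @return A tibble of class `drug_table` with one row per retained
#'   (drug, target) pair: `drug_id`, `name`, `target` (integer gene ID),
#'   `action` (one of `"activate"`, `"inhibit"`, `"unknown"`), plus any
#'   `flag_*` columns. The IDs of excluded drugs are kept in
#'   `attr(, "excluded_drugs")`.
#' @export
read_drug_targets <- function(path, interactome, quiet = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("drug_id", "name", "target", "action")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("drug table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_drug_table(tbl, interactome, quiet = quiet)
}

#' Validate and restrict an in-memory drug-target table
#'
#' @inheritParams read_drug_targets
#' @param tbl Data frame with columns `drug_id`, `name`, `target`, `action`
#'   and optional `flag_*` columns.
#' @return A `drug_table` tibble; see [read_drug_targets()].
#' @export
as_drug_table <- function(tbl, interactome, quiet = FALSE) {
  tbl <- tibble::as_tibble(tbl)
  tbl$drug_id <- as.character(tbl$drug_id)
  tbl$name <- as.character(tbl$name)
  tbl$target <- as.integer(tbl$target)
  tbl$action <- as.character(tbl$action)
  bad <- which(!tbl$action %in% c("activate", "inhibit", "unknown"))
  if (length(bad) > 0L) {
    stop("invalid pharmacological action in drug table row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": must be activate/inhibit/unknown", call. = FALSE)
  }
  dup <- duplicated(paste(tbl$drug_id, tbl$target), fromLast = TRUE)
  if (any(dup)) {
    warning("drug table: ", sum(dup),
            " duplicate (drug, target) row(s) dropped; last action kept",
            call. = FALSE)
    tbl <- tbl[!dup, , drop = FALSE]
  }
  all_drugs <- unique(tbl$drug_id)
  tbl <- tbl[in_interactome(tbl$target, interactome), , drop = FALSE]
  excluded <- setdiff(all_drugs, unique(tbl$drug_id))
  if (!quiet && length(excluded) > 0L) {
    message("drug table: ", length(excluded),
            " drug(s) without any interactome target excluded")
  }
  tbl <- dplyr::arrange(tbl, .data$drug_id, .data$target)
  attr(tbl, "excluded_drugs") <- excluded
  class(tbl) <- c("drug_table", class(tbl))
  tbl
}

#' Split a drug table into per-drug records
#'
#' @param drugs A `drug_table`.
#' @return A named list (by `drug_id`) of lists with elements `drug_id`,
#'   `name`, `targets` (integer vector) and `action` (named character vector,
#'   one entry per target).
#' @export
drug_records <- function(drugs) {
  split_idx <- split(seq_len(nrow(drugs)), drugs$drug_id)
  lapply(split_idx, function(i) {
    list(
      drug_id = drugs$drug_id[i[1L]],
      name = drugs$name[i[1L]],
      targets = drugs$target[i],
      action = stats::setNames(drugs$action[i], drugs$target[i])
    )
  })
}

#' Read per-cell-type differential-expression tables
#'
#' Reads a TSV with header `cell_type`, `gene`, `logfc`, `padj`. Genes outside
#' the interactome are retained but flagged (`in_interactome = FALSE`);
#' network-based stages silently ignore them. Rows with a zero log fold change
#' carry no direction for the pharmacology filter and are rejected at load
#' with a warning. Optionally caps each cell type's signature at the
#' `max_degs` most significant genes.
#'
#' @param path Path to the DEG TSV.
#' @param interactome An `interactome`.
#' @param max_degs Optional positive integer: keep at most this many genes per
#'   cell type, smallest adjusted p first (ties broken by larger `|logfc|`,
#'   then smaller gene ID).
#' @return A tibble of class `deg_table` with columns `cell_type`, `gene`
#'   (integer), `logfc`, `padj`, `in_interactome`.
#' @export
read_degs <- function(path, interactome, max_degs = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_type", "gene", "logfc", "padj")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("DEG table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_deg_table(tbl, interactome, max_degs = max_degs)
}

#' Validate an in-memory DEG table
#'
#' @inheritParams read_degs
#' @param tbl Data frame with columns `cell_type`, `gene`, `logfc`, `padj`.
#' @return A `deg_table` tibble; see [read_degs()].
#' @export
as_deg_table <- function(tbl, interactome, max_degs = NULL) {
  tbl <- tibble::as_tibble(tbl)
  tbl$cell_type <- as.character(tbl$cell_type)
  tbl$gene <- as.integer(tbl$gene)
  tbl$logfc <- as.double(tbl$logfc)
  tbl$padj <- as.double(tbl$padj)
  if (any(tbl$padj < 0 | tbl$padj > 1 | is.na(tbl$padj))) {
    stop("DEG table: adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  zero <- tbl$logfc == 0
  if (any(zero)) {
    warning("DEG table: ", sum(zero),
            " row(s) with zero log fold change rejected", call. = FALSE)
    tbl <- tbl[!zero, , drop = FALSE]
  }
  dup <- duplicated(paste(tbl$cell_type, tbl$gene))
  if (any(dup)) {
    stop("DEG table: duplicate gene(s) within a cell type", call. = FALSE)
  }
  tbl$in_interactome <- in_interactome(tbl$gene, interactome)
  tbl <- cap_degs(tbl, max_degs)
  class(tbl) <- c("deg_table", class(tbl))
  tbl
}

#' Keep only the top significant genes per cell type
#'
#' @param degs A DEG tibble (see [read_degs()]).
#' @param max_degs Positive integer cap per cell type, or `NULL` for no cap.
#'   Genes are kept by smallest `padj`, breaking ties by larger `|logfc|` and
#'   then smaller gene ID.
#' @return The capped tibble, same columns.
#' @export
cap_degs <- function(degs, max_degs = NULL) {
  if (is.null(max_degs)) return(degs)
  stopifnot(is.numeric(max_degs), max_degs >= 1)
  degs |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::arrange(.data$padj, dplyr::desc(abs(.data$logfc)), .data$gene,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = as.integer(max_degs)) |>
    dplyr::ungroup()
}

deg_sets <- function(degs, interactome_only = TRUE) {
  if (interactome_only) degs <- degs[degs$in_interactome, , drop = FALSE]
  split(degs$gene, degs$cell_type)
}

#' Read a denoised expression matrix with cell-type labels
#'
#' Supports two layouts: MatrixMarket (`<prefix>.mtx` genes x cells, plus
#' `<prefix>_genes.tsv` with one gene ID per line and `<prefix>_cells.tsv`
#' with header `cell_id`, `cell_type`), or a single dense TSV whose first
#' column is the gene ID, whose remaining column names are cell IDs, given
#' together with the same `*_cells.tsv` label file. Values are interpreted as
#' denoised log10-scale expression; negative entries are clipped to the floor
#' (default 0) with a warning.
#'
#' @param prefix Path prefix for the MTX layout, or the dense TSV path when
#'   `dense = TRUE`.
#' @param cells_path Path to the cell-label TSV; defaults to
#'   `<prefix>_cells.tsv`.
#' @param dense Read the dense-TSV layout instead of MatrixMarket.
#' @param floor Lower clip bound for expression values.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (dense numeric genes x cells matrix, dimnames = gene IDs / cell IDs) and
#'   `cell_type_of` (named character vector over cells).
#' @export
read_expression <- function(prefix, cells_path = NULL, dense = FALSE,
                            floor = 0) {
  if (dense) {
    tbl <- readr::read_tsv(prefix, show_col_types = FALSE, progress = FALSE)
    genes <- as.integer(tbl[[1L]])
    values <- as.matrix(tbl[, -1L, drop = FALSE])
    rownames(values) <- genes
    if (is.null(cells_path)) {
      cells_path <- sub("\\.tsv$", "_cells.tsv", prefix)
    }
  } else {
    values <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
    genes <- as.integer(readLines(paste0(prefix, "_genes.tsv")))
    cells <- readr::read_tsv(paste0(prefix, "_cells.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    rownames(values) <- genes
    colnames(values) <- cells$cell_id
    if (is.null(cells_path)) cells_path <- paste0(prefix, "_cells.tsv")
  }
  labels <- readr::read_tsv(cells_path, show_col_types = FALSE,
                            progress = FALSE)
  as_expression_matrix(values,
                       stats::setNames(as.character(labels$cell_type),
                                       labels$cell_id),
                       floor = floor)
}

#' Build an expression-matrix object from a dense matrix and labels
#'
#' @param values Numeric genes x cells matrix, rownames = gene IDs,
#'   colnames = cell IDs.
#' @param cell_type_of Named character vector mapping every cell ID to a cell
#'   type.
#' @param floor Lower clip bound; values below it are clipped with a warning.
#' @return An `expression_matrix` object; see [read_expression()].
#' @export
as_expression_matrix <- function(values, cell_type_of, floor = 0) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  missing_lab <- setdiff(colnames(values), names(cell_type_of))
  if (length(missing_lab) > 0L) {
    stop("expression matrix: ", length(missing_lab),
         " cell(s) without a cell-type label, e.g. ", missing_lab[1L],
         call. = FALSE)
  }
  below <- values < floor
  if (any(below)) {
    warning("expression matrix: ", sum(below), " value(s) below ", floor,
            " clipped", call. = FALSE)
    values[below] <- floor
  }
  structure(
    list(values = values,
         cell_type_of = cell_type_of[colnames(values)]),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, ", length(unique(x$cell_type_of)), " cell types\n", sep = "")
  invisible(x)
}

#' Write an expression matrix in the MatrixMarket layout
#'
#' @param expr An `expression_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.mtx`,
#'   `<prefix>_genes.tsv`, `<prefix>_cells.tsv`).
#' @return `prefix`, invisibly.
#' @export
write_expression <- function(expr, prefix) {
  Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(expr$values), paste0(prefix, "_genes.tsv"))
  readr::write_tsv(
    tibble::tibble(cell_id = colnames(expr$values),
                   cell_type = unname(expr$cell_type_of)),
    paste0(prefix, "_cells.tsv"), progress = FALSE
  )
  invisible(prefix)
}

#' Read a ligand-to-target regulatory-potential prior
#'
#' The TSV's first column (`ligand`) holds ligand gene IDs; the remaining
#' column names are target gene IDs; entries are non-negative regulatory
#' potential scores. Ligand rows that are entirely missing are rejected.
#'
#' @param path Path to the prior TSV.
#' @return A numeric ligands x genes matrix of class `ligand_prior` with
#'   rownames = ligand gene IDs and colnames = target gene IDs.
#' @export
read_ligand_prior <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tbl[, -1L, drop = FALSE])
  rownames(m) <- as.integer(tbl[[1L]])
  as_ligand_prior(m)
}

#' Validate an in-memory ligand prior matrix
#'
#' @param m Numeric ligands x genes matrix; rownames = ligand gene IDs,
#'   colnames = target gene IDs.
#' @return The validated matrix with class `ligand_prior`.
#' @export
as_ligand_prior <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  all_missing <- apply(m, 1L, function(r) all(is.na(r)))
  if (any(all_missing)) {
    stop("ligand prior: ligand row(s) entirely missing: ",
         paste(rownames(m)[all_missing], collapse = ", "), call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("ligand prior: regulatory potentials must be non-negative",
         call. = FALSE)
  }
  class(m) <- c("ligand_prior", class(m))
  m
}

#' Write a ligand prior matrix as TSV
#'
#' @param prior A `ligand_prior` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_prior <- function(prior, path) {
  tbl <- tibble::as_tibble(unclass(prior), .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(ligand = rownames(prior)), tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
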