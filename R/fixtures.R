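#' Specification for a synthetic benchmark data set
#'
#' Describes a fully synthetic, seeded input bundle with planted structure:
#' a scale-free interactome, one connected differential-expression module
#' per cell type, "good" drugs whose targets sit inside a planted module
#' with counteracting actions, degree-matched or aggravating decoy drugs, an
#' expression matrix whose module genes clear the background cut-off, and a
#' ligand prior in which planted sender ligands mirror a receiver module.
#'
#' The defaults define the package's benchmark conditions: 400 genes and 5
#' cell types keep an end-to-end permutation screen fast while leaving the
#' degree distribution heterogeneous enough to exercise degree binning;
#' 25-gene modules and 2-4 targets per drug mirror the scale ratio between
#' disease modules and drug target sets seen in real screens.
#'
#' @param seed Integer seed; the same spec always yields a byte-identical
#'   bundle.
#' @param n_genes Number of interactome genes.
#' @param n_cell_types Number of cell types.
#' @param n_cells_per_type Cells per cell type in the expression matrix.
#' @param module_size Genes per planted DEG module.
#' @param n_drugs Library size (half good, half decoys).
#' @param n_ligands Ligand rows of the prior.
#' @param frac_counteracting Probability that a good drug's target action
#'   counteracts the planted fold change (1 = always; 0 = the pharmacology
#'   filter removes every good drug).
#' @param noise_sd Gaussian noise on log10 expression values.
#' @param min_bin Minimal degree-bin size used for decoy target matching
#'   (scaled to toy graphs; the screening default stays 100).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 400L, n_cell_types = 5L,
                         n_cells_per_type = 60L, module_size = 25L,
                         n_drugs = 80L, n_ligands = 30L,
                         frac_counteracting = 1, noise_sd = 0.05,
                         min_bin = 20L) {
  stopifnot(n_genes >= 20L, n_cell_types >= 1L, module_size >= 2L,
            n_drugs >= 2L, n_ligands >= 1L,
            frac_counteracting >= 0, frac_counteracting <= 1, noise_sd >= 0)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_cell_types = as.integer(n_cell_types),
         n_cells_per_type = as.integer(n_cells_per_type),
         module_size = as.integer(module_size),
         n_drugs = as.integer(n_drugs), n_ligands = as.integer(n_ligands),
         frac_counteracting = frac_counteracting, noise_sd = noise_sd,
         min_bin = as.integer(min_bin)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic input bundle with planted signal
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture_bundle` with elements `spec`,
#'   `interactome`, `degs` (a `deg_table`), `drugs` (a `drug_table`),
#'   `expr` (an `expression_matrix`), `prior` (a `ligand_prior`) and
#'   `relevant` (character IDs of the good drugs).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::local_seed(spec$seed)

  # scale-free connected interactome, gene IDs = 1..n_genes
  g <- igraph::sample_pa(spec$n_genes, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  interactome <- as_interactome(
    data.frame(from = as.integer(el[, 1L]), to = as.integer(el[, 2L])),
    quiet = TRUE
  )
  if (spec$module_size > length(interactome$nodes)) {
    stop("generate_fixture: module_size exceeds the interactome",
         call. = FALSE)
  }
  cts <- sprintf("CT%d", seq_len(spec$n_cell_types))

  # one connected module per cell type, grown by randomised frontier
  # expansion, preferring unused genes so modules stay mostly distinct
  used <- integer(0)
  modules <- lapply(cts, function(ct) {
    m <- grow_module(interactome, spec$module_size, avoid = used)
    used <<- union(used, m)
    m
  })
  names(modules) <- cts

  deg_rows <- purrr::imap(modules, function(genes, ct) {
    tibble::tibble(
      cell_type = ct, gene = genes,
      logfc = sample(c(-1, 1), length(genes), replace = TRUE) *
        stats::runif(length(genes), 1.5, 3.5),
      padj = 10^-stats::runif(length(genes), 3, 10)
    )
  }) |> dplyr::bind_rows()
  degs <- as_deg_table(deg_rows, interactome)

  drugs <- fixture_drugs(spec, interactome, modules, deg_rows, cts)
  expr <- fixture_expression(spec, interactome, modules, cts)
  prior <- fixture_prior(spec, interactome, modules, cts)

  structure(
    list(spec = spec, interactome = interactome, degs = degs,
         drugs = drugs$table, expr = expr, prior = prior,
         relevant = drugs$relevant),
    class = "fixture_bundle"
  )
}

grow_module <- function(interactome, size, avoid = integer(0)) {
  g <- interactome$graph
  fresh <- setdiff(interactome$nodes, avoid)
  start <- fresh[sample.int(length(fresh), 1L)]
  mod <- start
  repeat {
    if (length(mod) >= size) break
    nb <- setdiff(as.integer(igraph::V(g)$name[unique(unlist(
      igraph::ego(g, 1, as.character(mod))
    ))]), mod)
    cand <- setdiff(nb, avoid)
    if (length(cand) == 0L) cand <- nb  # allow overlap when boxed in
    if (length(cand) == 0L) {
      stop("generate_fixture: cannot grow a connected module of size ", size,
           call. = FALSE)
    }
    mod <- c(mod, cand[sample.int(length(cand), 1L)])
  }
  sort(mod)
}

fixture_drugs <- function(spec, interactome, modules, deg_rows, cts) {
  n_good <- spec$n_drugs %/% 2L
  n_decoy <- spec$n_drugs - n_good
  bins <- build_degree_bins(interactome, spec$min_bin)
  logfc_of <- stats::setNames(deg_rows$logfc,
                              paste(deg_rows$cell_type, deg_rows$gene))

  counter_action <- function(lfc) ifelse(lfc > 0, "inhibit", "activate")
  aggravate_action <- function(lfc) ifelse(lfc > 0, "activate", "inhibit")

  rows <- list()
  good_ids <- character(n_good)
  for (i in seq_len(n_good)) {
    ct <- cts[(i - 1L) %% length(cts) + 1L]
    mod <- modules[[ct]]
    k <- sample(2:4, 1L)
    targets <- sort(sample(mod, min(k, length(mod))))
    lfc <- logfc_of[paste(ct, targets)]
    counter <- stats::runif(length(targets)) < spec$frac_counteracting
    # a module gene can be differentially expressed elsewhere with the
    # opposite sign; "unknown" is the only action that aggravates everywhere
    safe_aggravate <- vapply(seq_along(targets), function(ti) {
      hits <- deg_rows$logfc[deg_rows$gene == targets[ti]]
      if (length(unique(sign(hits))) > 1L) "unknown"
      else aggravate_action(lfc[ti])
    }, character(1))
    action <- ifelse(counter, counter_action(lfc), safe_aggravate)
    id <- sprintf("D%03d", i)
    good_ids[i] <- id
    rows[[length(rows) + 1L]] <- tibble::tibble(
      drug_id = id, name = sprintf("gooddrug_%03d", i),
      target = targets, action = unname(action), flag_relevant = TRUE
    )
  }
  for (j in seq_len(n_decoy)) {
    id <- sprintf("D%03d", n_good + j)
    ct <- cts[(j - 1L) %% length(cts) + 1L]
    mod <- modules[[ct]]
    if (j %% 2L == 1L) {
      # degree-matched random targets; where a random target happens to be
      # a DEG somewhere, its action counteracts only with the configured
      # probability, so frac_counteracting = 0 silences decoys too
      k <- sample(2:4, 1L)
      proto <- sample(mod, min(k, length(mod)))
      targets <- sort(sample_degree_matched(proto, bins))
      action <- vapply(targets, function(tg) {
        hits <- deg_rows$logfc[deg_rows$gene == tg]
        if (length(hits) == 0L) {
          sample(c("activate", "inhibit", "unknown"), 1L)
        } else if (stats::runif(1) < spec$frac_counteracting) {
          counter_action(hits[1L])
        } else if (length(unique(sign(hits))) > 1L) {
          "unknown"  # opposite signs across cell types: no safe aggravator
        } else {
          sample(c(aggravate_action(hits[1L]), "unknown"), 1L)
        }
      }, character(1))
    } else {
      # in-module targets with aggravating actions (agonist-of-upregulated)
      k <- sample(2:4, 1L)
      targets <- sort(sample(mod, min(k, length(mod))))
      lfc <- logfc_of[paste(ct, targets)]
      action <- unname(aggravate_action(lfc))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      drug_id = id, name = sprintf("decoydrug_%03d", j),
      target = targets, action = action, flag_relevant = FALSE
    )
  }
  tbl <- as_drug_table(dplyr::bind_rows(rows), interactome, quiet = TRUE)
  list(table = tbl, relevant = good_ids)
}

fixture_expression <- function(spec, interactome, modules, cts) {
  genes <- interactome$nodes
  n_cells <- spec$n_cells_per_type * length(cts)
  cell_type_of <- rep(cts, each = spec$n_cells_per_type)
  cell_ids <- sprintf("%s_c%03d", cell_type_of,
                      rep(seq_len(spec$n_cells_per_type), length(cts)))
  # baseline per (gene, cell type): module genes express high, a fixed
  # random background slice moderately, the rest near zero
  base <- matrix(0, length(genes), length(cts),
                 dimnames = list(genes, cts))
  for (ct in cts) {
    bg_extra <- sample(genes, round(0.4 * length(genes)))
    base[as.character(bg_extra), ct] <- 0.3
    base[as.character(modules[[ct]]), ct] <- 0.8
  }
  values <- base[, cell_type_of, drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n_cells, 0, spec$noise_sd),
           length(genes), n_cells)
  values <- pmax(values, 0)
  rownames(values) <- genes
  colnames(values) <- cell_ids
  as_expression_matrix(values, stats::setNames(cell_type_of, cell_ids))
}

fixture_prior <- function(spec, interactome, modules, cts) {
  genes <- interactome$nodes
  n_planted_per_ct <- if (spec$n_ligands >= 2L * length(cts)) 2L else 1L
  ligands <- integer(0)
  rows <- list()
  for (i in seq_along(cts)) {
    ct <- cts[i]
    picks <- sample(modules[[ct]], n_planted_per_ct)
    receivers <- c(cts[i %% length(cts) + 1L], ct)[seq_len(n_planted_per_ct)]
    for (p in seq_along(picks)) {
      row <- stats::runif(length(genes), 0, 0.1)
      row[match(modules[[receivers[p]]], genes)] <-
        stats::runif(length(modules[[receivers[p]]]), 0.8, 1)
      ligands <- c(ligands, picks[p])
      rows[[length(rows) + 1L]] <- row
    }
  }
  n_rand <- spec$n_ligands - length(ligands)
  if (n_rand > 0L) {
    pool <- setdiff(genes, c(ligands, unlist(modules)))
    rand_lig <- sample(pool, min(n_rand, length(pool)))
    for (lg in rand_lig) {
      ligands <- c(ligands, lg)
      rows[[length(rows) + 1L]] <- stats::runif(length(genes), 0, 1)
    }
  }
  keep <- !duplicated(ligands)
  m <- do.call(rbind, rows[keep])
  dimnames(m) <- list(ligands[keep], genes)
  as_ligand_prior(m)
}

#' Write a fixture bundle in the on-disk input formats
#'
#' Writes `interactome.tsv` (headerless edge list), `drugs.tsv`, `degs.tsv`,
#' `expr.mtx` + `expr_genes.tsv` + `expr_cells.tsv`, `prior.tsv` and
#' `relevant.txt` into `dir`, exactly the formats the `read_*` loaders
#' consume.
#'
#' @param bundle A `fixture_bundle` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_interactome(bundle$interactome, file.path(dir, "interactome.tsv"))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(bundle$drugs), "drug_id", "name",
                  "target", "action", dplyr::starts_with("flag_")),
    file.path(dir, "drugs.tsv"), progress = FALSE
  )
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(bundle$degs), "cell_type", "gene",
                  "logfc", "padj"),
    file.path(dir, "degs.tsv"), progress = FALSE
  )
  write_expression(bundle$expr, file.path(dir, "expr"))
  write_ligand_prior(bundle$prior, file.path(dir, "prior.tsv"))
  writeLines(bundle$relevant, file.path(dir, "relevant.txt"))
  invisible(dir)
}

#' Read a fixture directory back through the standard loaders
#'
#' @param dir Directory written by [write_fixture()].
#' @param max_degs Optional per-cell-type DEG cap (see [read_degs()]).
#' @return A list with the same elements as [generate_fixture()] (minus
#'   `spec`).
#' @export
read_fixture <- function(dir, max_degs = NULL) {
  interactome <- read_interactome(file.path(dir, "interactome.tsv"),
                                  quiet = TRUE)
  list(
    interactome = interactome,
    drugs = read_drug_targets(file.path(dir, "drugs.tsv"), interactome,
                              quiet = TRUE),
    degs = read_degs(file.path(dir, "degs.tsv"), interactome,
                     max_degs = max_degs),
    expr = read_expression(file.path(dir, "expr")),
    prior = read_ligand_prior(file.path(dir, "prior.tsv")),
    relevant = readLines(file.path(dir, "relevant.txt"))
  )
}
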