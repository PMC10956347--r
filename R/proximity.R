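#' Mean closest network distance between drug targets and DEGs
#'
#' For each drug target, takes the shortest-path distance on the unweighted
#' interactome to the nearest differentially expressed gene, and averages
#' over targets. A value of 0 means every target is itself a DEG; values
#' below 1 mean targets hit DEGs directly more often than not.
#'
#' @param targets Integer gene IDs of the drug's targets; must all lie in the
#'   interactome.
#' @param degs Integer gene IDs of the cell type's DEGs; genes outside the
#'   interactome are ignored.
#' @param interactome An `interactome`.
#' @param dist_matrix Optional precomputed all-pairs distance matrix (dimnames
#'   = gene IDs) to avoid repeated shortest-path calls.
#' @return The mean closest distance, a non-negative scalar.
#' @export
closest_distance <- function(targets, degs, interactome,
                             dist_matrix = NULL) {
  targets <- unique(as.integer(targets))
  if (length(targets) == 0L) {
    stop("closest_distance: empty target set", call. = FALSE)
  }
  if (!all(in_interactome(targets, interactome))) {
    stop("closest_distance: target(s) outside the interactome", call. = FALSE)
  }
  degs <- unique(as.integer(degs))
  degs <- degs[in_interactome(degs, interactome)]
  if (length(degs) == 0L) {
    stop("closest_distance: no DEG lies in the interactome; ",
         "distance undefined", call. = FALSE)
  }
  if (is.null(dist_matrix)) {
    d <- igraph::distances(interactome$graph,
                           v = as.character(targets),
                           to = as.character(degs))
  } else {
    d <- dist_matrix[as.character(targets), as.character(degs),
                     drop = FALSE]
  }
  mean(row_mins(d))
}

# fast row minima via max.col on the negated matrix
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

#' Partition interactome genes into degree bins for randomisation
#'
#' Nodes are sorted by degree; consecutive degree values are accumulated into
#' one bin until it holds at least `min_size` genes, then a new bin starts. A
#' trailing bin smaller than `min_size` is merged into its predecessor, so
#' every bin has at least `min_size` genes whenever the graph itself does.
#' Permutation nulls draw replacements from a gene's own bin, preserving the
#' degree distribution of the randomised sets.
#'
#' @param interactome An `interactome`.
#' @param min_size Minimal number of genes per bin (default 100).
#' @return An object of class `degree_bins`: list with `bins` (list of
#'   integer gene-ID vectors), `bin_of` (named integer vector over genes) and
#'   `min_size`.
#' @export
build_degree_bins <- function(interactome, min_size = 100) {
  stopifnot(min_size >= 1)
  deg <- interactome$degree
  genes <- as.integer(names(deg))
  ord <- order(deg, genes)
  deg <- deg[ord]
  genes <- genes[ord]

  # genes grouped by degree value, ascending
  by_deg <- split(genes, deg)
  bins <- list()
  current <- integer(0)
  for (grp in by_deg) {
    current <- c(current, grp)
    if (length(current) >= min_size) {
      bins[[length(bins) + 1L]] <- current
      current <- integer(0)
    }
  }
  if (length(current) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- current
    } else {
      bins[[length(bins)]] <- c(bins[[length(bins)]], current)
    }
  }
  bin_of <- integer(length(genes))
  names(bin_of) <- as.character(unlist(bins))
  bin_of[] <- rep.int(seq_along(bins), lengths(bins))
  structure(list(bins = bins, bin_of = bin_of, min_size = min_size),
            class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat("<degree_bins> ", length(x$bins), " bin(s), sizes: ",
      paste(lengths(x$bins), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy degree bins into a gene table
#'
#' @param x A `degree_bins` object.
#' @param ... Unused.
#' @return A tibble with columns `gene` and `bin`.
#' @method tidy degree_bins
#' @export
tidy.degree_bins <- function(x, ...) {
  tibble::tibble(gene = as.integer(names(x$bin_of)),
                 bin = unname(x$bin_of))
}

#' Draw a degree-matched random replacement for a gene set
#'
#' Each input gene is replaced by a gene drawn uniformly from its own degree
#' bin, without replacement within the sampled set, so the replacement set
#' has the same size and the same multiset of bin memberships as the input.
#'
#' @param genes Integer gene IDs (a set; duplicates are collapsed).
#' @param bins A `degree_bins` object covering all `genes`.
#' @return An integer vector of the same length as `unique(genes)`.
#' @export
sample_degree_matched <- function(genes, bins) {
  genes <- unique(as.integer(genes))
  bin_idx <- bins$bin_of[as.character(genes)]
  if (anyNA(bin_idx)) {
    stop("sample_degree_matched: gene(s) outside the binned interactome",
         call. = FALSE)
  }
  counts <- table(bin_idx)
  out <- integer(length(genes))
  pos <- 1L
  for (b in names(counts)) {
    members <- bins$bins[[as.integer(b)]]
    k <- counts[[b]]
    if (k > length(members)) {
      stop("sample_degree_matched: bin ", b, " holds ", length(members),
           " gene(s) but ", k, " draw(s) requested without replacement",
           call. = FALSE)
    }
    out[pos:(pos + k - 1L)] <- members[sample.int(length(members), k)]
    pos <- pos + k
  }
  out
}

# deterministic per-(cell type, drug) RNG substream: polynomial string hash
# folded with the global seed, mod 2^31 - 1
pair_seed <- function(seed, cell_type, drug_id) {
  s <- paste(cell_type, drug_id, sep = "\r")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(((seed %% 2147483647) * 48271 + h) %% 2147483647)
}

#' Network-proximity permutation screen of drugs against cell-type DEGs
#'
#' For every (cell type, drug) pair, computes the observed mean closest
#' distance `d_c` between the drug's targets and the cell type's in-network
#' DEGs, then builds a permutation null by redrawing *both* the target set
#' and the DEG set degree-matched (`n_iter` iterations) and recomputing the
#' distance. The z-score is `z_c = (d_c - null_mean) / null_sd` with the
#' population standard deviation; when the null is degenerate
#' (`null_sd = 0`) `z_c` is `NA` and the drug cannot pass z-selection.
#'
#' Each pair uses its own RNG substream derived from `seed`, so the table is
#' reproducible and independent of evaluation order.
#'
#' @param drugs A `drug_table` (see [read_drug_targets()]).
#' @param degs A DEG tibble (see [read_degs()]); cell types without any
#'   in-network DEG are dropped with a warning.
#' @param interactome An `interactome`.
#' @param bins Optional `degree_bins`; built with `min_bin` if `NULL`.
#' @param n_iter Number of permutation iterations (default 1000).
#' @param seed Global integer seed.
#' @param min_bin Minimal degree-bin size used when `bins` is `NULL`.
#' @param cache_distances Precompute the all-pairs distance matrix when the
#'   graph has at most this many nodes (speeds up the permutation loop).
#' @return A tibble with one row per (cell type, drug): `cell_type`,
#'   `drug_id`, `d_c`, `null_mean`, `null_sd`, `z_c`, `n_iter`, `seed`.
#' @export
proximity_screen <- function(drugs, degs, interactome, bins = NULL,
                             n_iter = 1000, seed = 1L, min_bin = 100,
                             cache_distances = 3000) {
  if (n_iter < 2) stop("proximity_screen: n_iter must be >= 2", call. = FALSE)
  if (is.null(bins)) bins <- build_degree_bins(interactome, min_bin)
  sets <- deg_sets(degs)
  dropped <- setdiff(unique(degs$cell_type), names(sets))
  if (length(dropped) > 0L) {
    warning("proximity_screen: cell type(s) without in-network DEGs ",
            "dropped: ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  recs <- drug_records(drugs)
  dm <- NULL
  if (length(interactome$nodes) <= cache_distances) {
    dm <- igraph::distances(interactome$graph)
  }

  grid <- tidyr::expand_grid(cell_type = names(sets),
                             drug_id = names(recs))
  res <- purrr::pmap(grid, function(cell_type, drug_id) {
    proximity_one(recs[[drug_id]]$targets, sets[[cell_type]], interactome,
                  bins, n_iter, pair_seed(seed, cell_type, drug_id), dm)
  })
  dplyr::bind_cols(
    grid,
    dplyr::bind_rows(res),
    tibble::tibble(n_iter = as.integer(n_iter), seed = as.integer(seed))
  ) |>
    dplyr::arrange(.data$cell_type, .data$drug_id)
}

proximity_one <- function(targets, deg_genes, interactome, bins, n_iter,
                          seed, dm) {
  d_obs <- closest_distance(targets, deg_genes, interactome, dm)
  withr::local_seed(seed)
  null_d <- numeric(n_iter)
  t_chr <- NULL
  for (i in seq_len(n_iter)) {
    t_rand <- sample_degree_matched(targets, bins)
    d_rand <- sample_degree_matched(deg_genes, bins)
    if (is.null(dm)) {
      dmat <- igraph::distances(interactome$graph,
                                v = as.character(t_rand),
                                to = as.character(d_rand))
    } else {
      dmat <- dm[as.character(t_rand), as.character(d_rand), drop = FALSE]
    }
    null_d[i] <- mean(row_mins(dmat))
  }
  mu <- mean(null_d)
  # population sd: permutation iterations are the whole null being summarised
  sdv <- sqrt(mean((null_d - mu)^2))
  tibble::tibble(
    d_c = d_obs, null_mean = mu, null_sd = sdv,
    z_c = if (sdv > 0) (d_obs - mu) / sdv else NA_real_
  )
}

#' Select drug candidates per cell type from proximity results
#'
#' A drug is a candidate for a cell type iff its targets are significantly
#' close to the DEGs (`z_c < z_thresh`, default -1.64, one-sided P < 0.05)
#' AND frequently hit DEGs directly (`d_c < d_thresh`, default 1). Both
#' inequalities are strict; pairs with an undefined (`NA`) z-score never
#' pass.
#'
#' @param proximity A tibble from [proximity_screen()].
#' @param z_thresh Strict upper bound on `z_c`.
#' @param d_thresh Strict upper bound on `d_c`.
#' @return A tibble with columns `cell_type`, `drug_id`, one row per selected
#'   pair. Cell types with zero selected drugs simply have no rows.
#' @export
select_candidates <- function(proximity, z_thresh = -1.64, d_thresh = 1.0) {
  proximity |>
    dplyr::filter(!is.na(.data$z_c), .data$z_c < z_thresh,
                  .data$d_c < d_thresh) |>
    dplyr::select("cell_type", "drug_id")
}
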