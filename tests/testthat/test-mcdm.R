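make_expr <- function(vals_by_ct, genes) {
  # vals_by_ct: named list cell type -> matrix genes x cells
  mats <- purrr::imap(vals_by_ct, function(m, ct) {
    colnames(m) <- sprintf("%s_c%d", ct, seq_len(ncol(m)))
    m
  })
  values <- do.call(cbind, unname(mats))
  rownames(values) <- genes
  labels <- rep(names(vals_by_ct), vapply(mats, ncol, integer(1)))
  as_expression_matrix(values, stats::setNames(labels, colnames(values)))
}

test_that("mean aggregate expression matches its closed forms", {
  genes <- 1:2
  expr <- make_expr(list(A = rbind(c(0, 0), c(1, 1)),
                         B = rbind(c(0, 1), c(0.5, 0.5))), genes)
  ea_a <- aggregate_expression(expr, "A")
  # all-zero log10 values: mean(10^0) = 1, log2(1) = 0
  expect_equal(ea_a$ea[ea_a$gene == 1], 0, tolerance = 1e-12)
  # all-one values: log2(10)
  expect_equal(ea_a$ea[ea_a$gene == 2], log2(10), tolerance = 1e-12)
  # two cells at 0 and 1: log2((1 + 10)/2) = log2(5.5)
  ea_b <- aggregate_expression(expr, "B")
  expect_equal(ea_b$ea[ea_b$gene == 1], log2(5.5), tolerance = 1e-12)
  expect_error(aggregate_expression(expr, "nope"), "unknown cell type")
})

test_that("background genes apply the Ea cut-off inclusively", {
  # engineer one gene exactly at Ea = 0.2: D = log10(2^0.2) for all cells
  d_exact <- log10(2^0.2)
  genes <- 1:3
  expr <- make_expr(list(A = rbind(c(d_exact, d_exact), c(0, 0), c(1, 1))),
                    genes)
  bg <- background_genes(expr, "A", cutoff = 0.2)
  expect_true(1L %in% bg)   # Ea exactly at the cut-off is included
  expect_false(2L %in% bg)  # Ea = 0 excluded
  expect_true(3L %in% bg)
  # a -Inf cut-off admits every gene
  expect_setequal(background_genes(expr, "A", cutoff = -Inf), genes)
})

test_that("ligand activity is the Pearson correlation of potentials against
          the gene-set indicator", {
  prior <- as_ligand_prior(matrix(
    c(0.9, 0.1, 0.2, 0.8,
      0.5, 0.5, 0.5, 0.5),
    nrow = 2, byrow = TRUE, dimnames = list(c(101, 102), 1:4)
  ))
  r <- ligand_activity(101, prior, gene_set = c(1, 4), background = 1:4)
  expect_equal(r, stats::cor(c(0.9, 0.1, 0.2, 0.8), c(1, 0, 0, 1)),
               tolerance = 1e-12)
  expect_equal(r, 0.7 / sqrt(0.5), tolerance = 1e-12)

  # an affine transform of the indicator correlates perfectly
  prior2 <- as_ligand_prior(matrix(c(0.9, 0.1, 0.1, 0.9), 1,
                                   dimnames = list(103, 1:4)))
  expect_equal(ligand_activity(103, prior2, c(1, 4), 1:4), 1,
               tolerance = 1e-12)

  # constant potentials carry no signal
  expect_warning(
    r0 <- ligand_activity(102, prior, c(1, 4), 1:4),
    "zero variance"
  )
  expect_equal(r0, 0)

  expect_error(ligand_activity(999, prior, c(1, 4), 1:4), "absent")
  expect_error(ligand_activity(101, prior, 1, 1:2 * 100), "fewer than 3")
})

test_that("ligand activity is invariant under affine rescaling of the
          potentials", {
  withr::local_seed(31)
  pot <- stats::runif(10)
  m <- rbind(pot, 3 * pot + 2)
  dimnames(m) <- list(c(1, 2), 11:20)
  prior <- as_ligand_prior(m)
  gs <- c(12, 15, 19)
  expect_equal(ligand_activity(1, prior, gs, 11:20),
               ligand_activity(2, prior, gs, 11:20), tolerance = 1e-12)
})

test_that("the MCDM keeps only positive ligand activities and sums them
          into directed edge weights", {
  fx <- small_fixture()
  m <- build_mcdm(fx$degs, fx$prior, fx$expr)
  expect_true(all(m$interactions$pearson > 0))
  expect_true(all(m$edges$weight > 0))
  # edge weights are exactly the per-pair sums of kept pearsons
  check <- m$interactions |>
    dplyr::group_by(sender, receiver) |>
    dplyr::summarise(w = sum(pearson), .groups = "drop")
  joined <- dplyr::left_join(m$edges, check,
                             by = c("sender", "receiver"))
  expect_equal(joined$weight, joined$w)
  # deleting one ligand interaction lowers exactly that edge by its pearson
  one <- m$interactions[1, ]
  inter2 <- m$interactions[-1, ]
  w2 <- inter2 |>
    dplyr::group_by(sender, receiver) |>
    dplyr::summarise(w = sum(pearson), .groups = "drop") |>
    dplyr::filter(sender == one$sender, receiver == one$receiver)
  w1 <- m$edges$weight[m$edges$sender == one$sender &
                         m$edges$receiver == one$receiver]
  expect_equal(w1 - (if (nrow(w2)) w2$w else 0), one$pearson)
})

test_that("a planted ligand mirroring the receiver module scores near-perfect
          activity and its interactions enter the model", {
  fx <- small_fixture()
  m <- build_mcdm(fx$degs, fx$prior, fx$expr)
  # fixture construction plants sender-DEG ligands whose prior rows mirror a
  # receiver module; those should dominate the kept activities
  expect_gt(max(m$interactions$pearson), 0.8)
  planted <- m$interactions |> dplyr::filter(pearson > 0.8)
  expect_gt(nrow(planted), 0)
  # every kept ligand is a DEG of its sender and a prior ligand
  deg_pairs <- paste(fx$degs$cell_type, fx$degs$gene)
  expect_true(all(paste(m$interactions$sender, m$interactions$ligand) %in%
                    deg_pairs))
  expect_true(all(m$interactions$ligand %in%
                    as.integer(rownames(fx$prior))))
})

test_that("cell-type centrality handles symmetric, cyclic and degenerate
          directed graphs", {
  # two nodes with equal reciprocal weights: both 1
  m2 <- list(edges = tibble::tibble(sender = c("A", "B"),
                                    receiver = c("B", "A"),
                                    weight = c(0.4, 0.4)))
  c2 <- celldrugnet:::celltype_centrality_impl(m2$edges, c("A", "B"))
  expect_equal(c2$centrality, c(1, 1), tolerance = 1e-8)

  # three-node equal-weight cycle: rotational symmetry, all 1
  m3 <- tibble::tibble(sender = c("A", "B", "C"),
                       receiver = c("B", "C", "A"), weight = 0.5)
  c3 <- celldrugnet:::celltype_centrality_impl(m3, c("A", "B", "C"))
  expect_equal(c3$centrality, rep(1, 3), tolerance = 1e-8)

  # all senders point into one hub: the directed spectrum is nilpotent, the
  # symmetrised fallback makes the hub maximal
  star <- tibble::tibble(sender = c("A", "B", "C"), receiver = "H",
                         weight = c(1, 1, 1))
  expect_message(
    cs <- celldrugnet:::celltype_centrality_impl(star,
                                                 c("A", "B", "C", "H")),
    "symmetrised"
  )
  hub <- cs$centrality[cs$cell_type == "H"]
  expect_equal(hub, 1, tolerance = 1e-8)
  expect_true(all(cs$centrality[cs$cell_type != "H"] < 1))
  # oracle: power iteration on the symmetrised star gives leaves 1/sqrt(3)
  expect_equal(cs$centrality[cs$cell_type != "H"], rep(1 / sqrt(3), 3),
               tolerance = 1e-6)

  # a cell type on no edge scores zero; an empty MCDM warns
  c4 <- celldrugnet:::celltype_centrality_impl(m3, c("A", "B", "C", "Z"))
  expect_equal(c4$centrality[c4$cell_type == "Z"], 0)
  expect_warning(
    c0 <- celldrugnet:::celltype_centrality_impl(
      tibble::tibble(sender = character(), receiver = character(),
                     weight = double()),
      c("A", "B")
    ),
    "no edges"
  )
  expect_equal(c0$centrality, c(0, 0))
})
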