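test_that("closest distance matches worked path-graph cases", {
  g <- path_interactome(5)
  expect_equal(closest_distance(3, 1, g), 2)
  expect_equal(closest_distance(c(2, 4), c(1, 5), g), 1)
  # targets that are themselves DEGs sit at distance zero
  expect_equal(closest_distance(c(2, 3), c(1, 2, 3), g), 0)
})

test_that("closest distance errors on empty or out-of-network inputs", {
  g <- path_interactome(4)
  expect_error(closest_distance(integer(0), 1, g), "empty target")
  expect_error(closest_distance(99, 1, g), "outside the interactome")
  expect_error(closest_distance(1, c(88, 99), g), "no DEG")
})

test_that("closest distance agrees with a BFS brute-force oracle on random
          graphs", {
  withr::local_seed(42)
  for (i in 1:25) {
    g <- random_connected_interactome(sample(8:30, 1))
    targets <- sample(g$nodes, sample(1:4, 1))
    degs <- sample(g$nodes, sample(1:6, 1))
    expect_equal(closest_distance(targets, degs, g),
                 closest_distance_oracle(unique(targets), unique(degs), g),
                 tolerance = 1e-12)
  }
})

test_that("adding a DEG never increases the closest distance", {
  withr::local_seed(43)
  for (i in 1:10) {
    g <- random_connected_interactome(20)
    targets <- sample(g$nodes, 3)
    degs <- sample(g$nodes, 4)
    extra <- sample(setdiff(g$nodes, degs), 1)
    expect_lte(closest_distance(targets, c(degs, extra), g),
               closest_distance(targets, degs, g))
  }
})

test_that("degree bins accumulate ascending degrees and merge a trailing
          undersized bin", {
  # 250 degree-1 nodes and 250 degree-2 nodes: hubs 501/502 serve as anchors
  leaves <- cbind(3:252, rep(1L, 250))       # degree-1 leaves on hub 1
  chains <- cbind(253:502, 503:752)          # chain middles get degree 2
  chains2 <- cbind(503:752, rep(2L, 250))
  g <- make_interactome(rbind(cbind(1L, 2L), leaves, chains, chains2))
  bins <- build_degree_bins(g, min_size = 100)
  sizes <- lengths(bins$bins)
  expect_true(all(sizes >= 100))
  # bins partition the node set
  expect_setequal(unlist(bins$bins), g$nodes)
  # within a bin, degrees form a contiguous ascending range across bins
  degs_by_bin <- lapply(bins$bins, function(b) g$degree[as.character(b)])
  maxima <- vapply(degs_by_bin, max, numeric(1))
  minima <- vapply(degs_by_bin, min, numeric(1))
  expect_true(all(diff(order(minima)) > 0))
  expect_true(all(utils::head(maxima, -1) < utils::tail(minima, -1)))
})

test_that("a graph smaller than the minimal bin size yields a single bin", {
  withr::local_seed(2)
  g <- random_connected_interactome(50)
  bins <- build_degree_bins(g, min_size = 100)
  expect_length(bins$bins, 1L)
  expect_setequal(bins$bins[[1L]], g$nodes)
})

test_that("a trailing undersized degree group merges into the previous bin", {
  # 150 degree-1 leaves plus a small high-degree tail: one final bin of all
  star_leaves <- cbind(2:151, rep(1L, 150))
  g <- make_interactome(star_leaves)
  bins <- build_degree_bins(g, min_size = 100)
  # leaves close a 150-gene bin; hub 1 (degree 150) is undersized and merges
  expect_length(bins$bins, 1L)
  expect_equal(length(bins$bins[[1L]]), 151L)
})

test_that("degree-matched sampling preserves the bin-index multiset, is
          deterministic under a seed, and respects without-replacement", {
  withr::local_seed(3)
  g <- random_connected_interactome(120)
  bins <- build_degree_bins(g, min_size = 20)
  genes <- sample(g$nodes, 10)

  withr::with_seed(99, s1 <- sample_degree_matched(genes, bins))
  withr::with_seed(99, s2 <- sample_degree_matched(genes, bins))
  expect_identical(s1, s2)
  expect_length(s1, length(unique(genes)))
  expect_false(any(duplicated(s1)))
  expect_equal(sort(unname(bins$bin_of[as.character(s1)])),
               sort(unname(bins$bin_of[as.character(genes)])))

  # requesting a whole single-bin graph forces the full node set back
  tiny <- make_interactome(cbind(1:3, c(2L, 3L, 1L)))  # triangle, one bin
  tiny_bins <- build_degree_bins(tiny, min_size = 1)
  expect_setequal(sample_degree_matched(tiny$nodes, tiny_bins), tiny$nodes)
})

test_that("bin-member selection frequencies are uniform", {
  withr::local_seed(4)
  g <- random_connected_interactome(60)
  bins <- build_degree_bins(g, min_size = 60)  # single bin
  gene <- g$nodes[1]
  draws <- replicate(6000, sample_degree_matched(gene, bins))
  tab <- table(factor(draws, levels = g$nodes))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("the permutation z-score handles degenerate nulls and known
          symmetric cases", {
  # targets = DEGs = the whole complete graph: observed and every permuted
  # distance is 0, so the null collapses and z is the undefined sentinel
  n <- 4
  cg <- make_interactome(t(utils::combn(n, 2)))
  drugs <- as_drug_table(
    tibble::tibble(drug_id = "d", name = "d", target = 1:4,
                   action = "inhibit"),
    cg, quiet = TRUE
  )
  degs <- as_deg_table(
    tibble::tibble(cell_type = "T", gene = 1:4, logfc = rep(2, 4),
                   padj = rep(0.01, 4)),
    cg
  )
  res <- proximity_screen(drugs, degs, cg, n_iter = 50, seed = 1,
                          min_bin = 2)
  expect_equal(res$null_sd, 0)
  expect_true(is.na(res$z_c))
  expect_equal(res$d_c, 0)

  expect_error(
    proximity_screen(drugs, degs, cg, n_iter = 1, seed = 1, min_bin = 2),
    "n_iter"
  )
})

test_that("the proximity table is reproducible under a fixed seed and
          independent of pair evaluation order", {
  fx <- small_fixture()
  sub_drugs <- fx$drugs[fx$drugs$drug_id %in%
                          unique(fx$drugs$drug_id)[1:6], ]
  class(sub_drugs) <- class(fx$drugs)
  r1 <- proximity_screen(sub_drugs, fx$degs, fx$interactome, n_iter = 60,
                         seed = 7, min_bin = 15)
  r2 <- proximity_screen(sub_drugs, fx$degs, fx$interactome, n_iter = 60,
                         seed = 7, min_bin = 15)
  expect_identical(r1, r2)

  # a single pair recomputed in isolation matches the full table
  one_drug <- sub_drugs[sub_drugs$drug_id == sub_drugs$drug_id[1], ]
  class(one_drug) <- class(sub_drugs)
  one_ct <- fx$degs[fx$degs$cell_type == r1$cell_type[1], ]
  class(one_ct) <- class(fx$degs)
  r_one <- proximity_screen(one_drug, one_ct, fx$interactome, n_iter = 60,
                            seed = 7, min_bin = 15)
  expect_identical(
    r_one,
    r1[r1$cell_type == r_one$cell_type & r1$drug_id == r_one$drug_id, ]
  )
})

test_that("candidate selection applies both cut-offs strictly and never
          passes undefined z-scores", {
  res <- tibble::tibble(
    cell_type = "T",
    drug_id = c("a", "b", "c", "d"),
    d_c = c(0.5, 1.0, 0.2, 0.3),
    null_mean = 1, null_sd = 1,
    z_c = c(-2.0, -3.0, -1.64, NA),
    n_iter = 10L, seed = 1L
  )
  sel <- select_candidates(res)
  expect_equal(sel$drug_id, "a")
})
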