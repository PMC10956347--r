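# in-memory builders used across test files

make_interactome <- function(edges) {
  # edges: 2-column matrix or data.frame of integer gene IDs
  as_interactome(as.data.frame(edges), quiet = TRUE)
}

path_interactome <- function(n) {
  make_interactome(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

# connected Erdos-Renyi-ish random graph on n nodes (spanning tree + extras)
random_connected_interactome <- function(n, extra = n) {
  parents <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  tree <- cbind(2:n, parents[2:n])
  more <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  make_interactome(rbind(tree, more))
}

# independent breadth-first-search shortest path oracle (no igraph)
bfs_dist <- function(interactome, source) {
  edges <- tidy(interactome)
  nodes <- interactome$nodes
  adj <- lapply(stats::setNames(nodes, nodes), function(x) integer(0))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    adj[[a]] <- c(adj[[a]], edges$to[i])
    adj[[b]] <- c(adj[[b]], edges$from[i])
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[as.character(source)] <- 0
  queue <- source
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[as.character(v)]]) {
      if (is.infinite(dist[as.character(w)])) {
        dist[as.character(w)] <- dist[as.character(v)] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# brute-force mean closest distance via the BFS oracle
closest_distance_oracle <- function(targets, degs, interactome) {
  mean(vapply(targets, function(t) {
    min(bfs_dist(interactome, t)[as.character(degs)])
  }, numeric(1)))
}

# dense eigendecomposition oracle for undirected eigenvector centrality
eigencentrality_oracle <- function(interactome, genes) {
  genes <- sort(genes)
  sub <- igraph::induced_subgraph(interactome$graph, as.character(genes))
  A <- as.matrix(igraph::as_adjacency_matrix(sub))
  A <- A[as.character(genes), as.character(genes)]
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, 1L])
  stats::setNames(v / max(v), as.character(genes))
}
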