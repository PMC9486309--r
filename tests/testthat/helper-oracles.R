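# Independent oracles and random-input generators shared across tests.

# Brute-force seed-pair betweenness: enumerate every geodesic of every
# unordered seed pair (igraph's all_shortest_paths) and count interior
# appearances. Independent of the package's BFS sigma-counting path.
oracle_seed_betweenness <- function(g, seeds) {
  nodes <- igraph::V(g)$name
  out <- setNames(numeric(length(nodes)), nodes)
  seeds <- intersect(seeds, nodes)
  if (length(seeds) < 2) return(out)
  prs <- utils::combn(seeds, 2)
  for (j in seq_len(ncol(prs))) {
    paths <- suppressWarnings(
      igraph::all_shortest_paths(g, from = prs[1, j], to = prs[2, j])$res
    )
    for (p in paths) {
      nm <- names(p)
      if (length(nm) > 2) {
        inner <- nm[-c(1, length(nm))]
        out[inner] <- out[inner] + 1
      }
    }
  }
  out
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of n
# items from N of which the first K are "annotated", tabulate overlap
# counts, and return P(X >= k) exactly.
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)                # each column one draw
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Random simple graph with named vertices; guaranteed >= 1 edge.
random_named_graph <- function(n, p = 0.35) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 1) break
  }
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

# Random annotation collection for round-trip and pair-enumeration tests.
random_collection <- function(n_pathways, universe = sprintf("G%03d", 1:60),
                              min_size = 1, max_size = 12) {
  genes <- lapply(seq_len(n_pathways), function(i) {
    sample(universe, sample(min_size:max_size, 1))
  })
  tibble::tibble(
    pathway_id = sprintf("P%03d", seq_len(n_pathways)),
    name = sprintf("pathway %d", seq_len(n_pathways)),
    source = "random",
    genes = genes
  )
}
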