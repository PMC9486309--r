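#' Read an interactome from a two-column TSV edge list
#'
#' The interactome is an undirected simple graph of molecular interactions:
#' symbols are normalized, self-loops dropped, and duplicate edges
#' (including reversed duplicates) collapsed, each with a reported count.
#' `#` comment lines are allowed.
#'
#' @param path Path to the edge list (two tab-separated symbol columns).
#' @param quiet Suppress the dropped-record message.
#' @return An `igraph` undirected simple graph with gene symbols as vertex
#'   names. Attributes `n_self_loops` and `n_duplicates` record dropped
#'   records.
#' @export
read_interactome <- function(path, quiet = FALSE) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("no edges found in '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("interactome '%s': line(s) %s do not have 2 fields",
                  path, paste(bad, collapse = ", ")))
  }
  a <- normalize_symbol(vapply(fields, `[[`, character(1), 1L))
  b <- normalize_symbol(vapply(fields, `[[`, character(1), 2L))
  as_interactome(tibble::tibble(from = a, to = b), quiet = quiet)
}

#' Build an interactome graph from an edge data frame
#'
#' @param edges Data frame whose first two columns are gene symbols.
#' @param quiet Suppress the dropped-record message.
#' @return An undirected simple `igraph` graph (see [read_interactome()]).
#' @export
as_interactome <- function(edges, quiet = FALSE) {
  a <- normalize_symbol(as.character(edges[[1L]]))
  b <- normalize_symbol(as.character(edges[[2L]]))
  loops <- a == b
  lo <- pmin(a, b)[!loops]
  hi <- pmax(a, b)[!loops]
  key <- paste(lo, hi, sep = "\r")
  dups <- duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dups], to = hi[!dups]),
    directed = FALSE
  )
  if ((sum(loops) > 0 || sum(dups) > 0) && !quiet) {
    inform(sprintf(
      "interactome: dropped %d self-loop(s) and %d duplicate edge(s)",
      sum(loops), sum(dups)
    ))
  }
  g$n_self_loops <- sum(loops)
  g$n_duplicates <- sum(dups)
  g
}

#' Seed-pair shortest-path betweenness
#'
#' For every gene in the interactome, counts the geodesics (hop-count
#' shortest paths) between all unordered pairs of seed genes on which the
#' gene lies as an interior (non-endpoint) node. Multiple geodesics per
#' pair all count; disconnected seed pairs contribute nothing; a seed can
#' score as an interior node of other pairs' geodesics. This is the raw
#' path count, not the fraction-normalized betweenness centrality.
#'
#' Seeds absent from the graph are dropped with a warning and recorded in
#' the `dropped_seeds` attribute.
#'
#' @param graph Interactome graph ([read_interactome()] / [as_interactome()]).
#' @param seeds Character vector of seed gene symbols.
#' @return Tibble with columns `gene` and `betweenness` (one row per graph
#'   node, graph vertex order), attributes `seeds_used` and `dropped_seeds`.
#' @export
seed_pair_betweenness <- function(graph, seeds) {
  seeds <- unique(normalize_symbol(seeds))
  nodes <- igraph::V(graph)$name
  present <- intersect(seeds, nodes)
  absent <- setdiff(seeds, nodes)
  if (length(absent) > 0) {
    warn(sprintf("seed_pair_betweenness: %d seed(s) absent from the graph",
                 length(absent)))
  }
  if (length(present) < 2L) {
    abort("need at least 2 seed genes present in the graph")
  }
  b <- seed_pair_betweenness_counts(
    igraph::as_adj_list(graph, mode = "all"),
    match(present, nodes)
  )
  out <- tibble::tibble(gene = nodes, betweenness = as.numeric(b))
  attr(out, "seeds_used") <- present
  attr(out, "dropped_seeds") <- absent
  out
}

#' Permutation null distribution of seed-pair betweenness
#'
#' Draws `n_seeds` genes uniformly at random without replacement from the
#' graph's nodes, `n_perm` times, and records every gene's seed-pair
#' betweenness per replicate. Replicate r derives its RNG stream from
#' `(rng_seed, r)`, so the null is bit-reproducible and replicate order is
#' independent of evaluation order. An optional degree-stratified mode
#' samples within degree bins to preserve the seeds' degree profile.
#'
#' @param graph Interactome graph.
#' @param n_seeds Number of random seeds per replicate.
#' @param n_perm Number of replicates (default 100).
#' @param rng_seed Master integer seed.
#' @param degree_stratified If `TRUE`, supply `seeds` whose degree profile
#'   the draws should match (sampling within deciles of the degree
#'   distribution).
#' @param seeds Actual seed symbols, only used for degree stratification.
#' @return Numeric matrix, genes (graph vertex order, rownames) x
#'   replicates.
#' @export
permutation_null <- function(graph, n_seeds, n_perm = 100, rng_seed = 1L,
                             degree_stratified = FALSE, seeds = NULL) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n_seeds > n) abort("n_seeds exceeds the number of graph nodes")
  if (n_perm < 1) abort("n_perm must be at least 1")
  adj <- igraph::as_adj_list(graph, mode = "all")

  strata <- NULL
  if (degree_stratified) {
    if (is.null(seeds)) abort("degree stratification needs `seeds`")
    deg <- igraph::degree(graph)
    br <- unique(quantile(deg, probs = seq(0, 1, 0.1)))
    bin <- cut(deg, breaks = br, include.lowest = TRUE)
    seed_bin <- bin[match(intersect(normalize_symbol(seeds), nodes), nodes)]
    strata <- list(bin = bin, counts = table(seed_bin))
  }

  null <- matrix(0, nrow = n, ncol = n_perm,
                 dimnames = list(nodes, NULL))
  for (r in seq_len(n_perm)) {
    set.seed(derive_seed(rng_seed, r))
    idx <- if (is.null(strata)) {
      sample.int(n, n_seeds)
    } else {
      unlist(lapply(names(strata$counts), function(lv) {
        pool <- which(strata$bin == lv)
        sample(pool, min(strata$counts[[lv]], length(pool)))
      }), use.names = FALSE)
    }
    null[, r] <- seed_pair_betweenness_counts(adj, idx)
  }
  null
}

#' Permutation FDR for seed-pair betweenness
#'
#' For each gene i, `fdr = count(betweenness_random > betweenness_actual) /
#' n_perm` — the fraction of random-seed replicates in which the gene's
#' null betweenness strictly exceeds its actual value. Also records
#' `positive_perm_count`, the number of replicates with nonzero null
#' betweenness, used downstream to exclude hub genes whose centrality
#' reflects background topology.
#'
#' @param actual Result of [seed_pair_betweenness()] (or a data frame with
#'   columns `gene`, `betweenness`).
#' @param null Matrix from [permutation_null()], rownames = genes.
#' @return Tibble of class `amdnet_prioritization`: `gene`,
#'   `betweenness_actual`, `fdr`, `positive_perm_count`; the null matrix and
#'   `n_perm` are kept as attributes.
#' @export
permutation_fdr <- function(actual, null) {
  if (!all(c("gene", "betweenness") %in% names(actual))) {
    abort("`actual` needs columns `gene` and `betweenness`")
  }
  if (!setequal(actual$gene, rownames(null))) {
    abort("`actual` and `null` must cover the same genes")
  }
  null <- null[actual$gene, , drop = FALSE]
  n_perm <- ncol(null)
  out <- tibble::tibble(
    gene = actual$gene,
    betweenness_actual = actual$betweenness,
    fdr = unname(rowSums(null > actual$betweenness)) / n_perm,
    positive_perm_count = as.integer(unname(rowSums(null > 0)))
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "null") <- null
  attr(out, "seeds_used") <- attr(actual, "seeds_used")
  class(out) <- c("amdnet_prioritization", class(out))
  out
}

#' Select candidate genes by betweenness, FDR and hub exclusion
#'
#' Retains genes with `betweenness_actual > b_min`, `fdr < fdr_max` and
#' `positive_perm_count < hub_max` (all strict, as the selection rule is
#' stated). The defaults (1000 / 0.05 / 50 of 100 permutations) are the
#' published thresholds for a ~13,000-node interactome; synthetic or
#' smaller graphs need a smaller `b_min` since betweenness scales with
#' seed count squared and graph size.
#'
#' @param records `amdnet_prioritization` tibble from [permutation_fdr()].
#' @param b_min Betweenness threshold (exclusive).
#' @param fdr_max FDR threshold (exclusive).
#' @param hub_max Hub threshold (exclusive) on `positive_perm_count`.
#' @param seeds Optional seed symbols; adds an `is_seed` flag.
#' @return Tibble sorted descending by `betweenness_actual` with columns of
#'   `records` plus `selected` and (when `seeds` given) `is_seed`.
#' @export
select_candidates <- function(records, b_min = 1000, fdr_max = 0.05,
                              hub_max = 50, seeds = NULL) {
  out <- records |>
    dplyr::mutate(selected = .data$betweenness_actual > b_min &
                    .data$fdr < fdr_max &
                    .data$positive_perm_count < hub_max) |>
    dplyr::filter(.data$selected) |>
    dplyr::arrange(dplyr::desc(.data$betweenness_actual), .data$gene)
  if (!is.null(seeds)) {
    out <- annotate_candidates(out, seeds)
  }
  out
}

#' Flag candidate genes that are themselves seeds
#'
#' @param candidates Data frame with a `gene` column.
#' @param seeds Character vector of seed symbols.
#' @return `candidates` with a logical `is_seed` column; the attribute
#'   `overlap_count` holds `|candidates ∩ seeds|`.
#' @export
annotate_candidates <- function(candidates, seeds) {
  seeds <- unique(normalize_symbol(seeds))
  candidates$is_seed <- candidates$gene %in% seeds
  attr(candidates, "overlap_count") <- sum(candidates$is_seed)
  candidates
}

#' Prioritize candidate genes in one call
#'
#' Convenience wrapper: actual seed-pair betweenness, permutation null,
#' permutation FDR, then threshold selection.
#'
#' @inheritParams seed_pair_betweenness
#' @inheritParams permutation_null
#' @inheritParams select_candidates
#' @return `amdnet_prioritization` tibble for all genes, with `selected`
#'   and `is_seed` columns; selected rows first (descending betweenness).
#' @export
prioritize <- function(graph, seeds, n_perm = 100, rng_seed = 1L,
                       b_min = 1000, fdr_max = 0.05, hub_max = 50,
                       degree_stratified = FALSE) {
  actual <- seed_pair_betweenness(graph, seeds)
  if (n_perm == 0L) {
    warn("n_perm = 0: betweenness only, no FDR computed")
    out <- tibble::tibble(
      gene = actual$gene,
      betweenness_actual = actual$betweenness,
      fdr = NA_real_,
      positive_perm_count = NA_integer_
    )
    class(out) <- c("amdnet_prioritization", class(out))
  } else {
    null <- permutation_null(graph, length(attr(actual, "seeds_used")),
                             n_perm, rng_seed,
                             degree_stratified = degree_stratified,
                             seeds = seeds)
    out <- permutation_fdr(actual, null)
  }
  out <- dplyr::mutate(
    out,
    selected = !is.na(.data$fdr) & .data$betweenness_actual > b_min &
      .data$fdr < fdr_max & .data$positive_perm_count < hub_max
  )
  out <- annotate_candidates(out, seeds)
  attr(out, "thresholds") <- list(b_min = b_min, fdr_max = fdr_max,
                                  hub_max = hub_max, n_perm = n_perm)
  dplyr::arrange(out, dplyr::desc(.data$selected),
                 dplyr::desc(.data$betweenness_actual), .data$gene)
}

#' Export the candidate subnetwork as GraphML
#'
#' Writes the subgraph induced by the selected candidates plus the seeds
#' present in the graph, with `betweenness`, `is_seed` and `selected` node
#' attributes.
#'
#' @param graph Interactome graph.
#' @param records `amdnet_prioritization` tibble with `selected` column.
#' @param seeds Seed symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_candidate_subnetwork <- function(graph, records, seeds, path) {
  seeds <- intersect(unique(normalize_symbol(seeds)),
                     igraph::V(graph)$name)
  keep <- union(records$gene[records$selected], seeds)
  sub <- igraph::induced_subgraph(graph, keep)
  idx <- match(igraph::V(sub)$name, records$gene)
  igraph::V(sub)$betweenness <- records$betweenness_actual[idx]
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% seeds
  igraph::V(sub)$selected <- igraph::V(sub)$name %in%
    records$gene[records$selected]
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}

#' @export
tidy.amdnet_prioritization <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.amdnet_prioritization <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_genes = nrow(x),
    n_selected = if ("selected" %in% names(x)) sum(x$selected) else NA_integer_,
    seed_overlap = attr(x, "overlap_count") %||% NA_integer_,
    n_perm = attr(x, "n_perm") %||% th$n_perm %||% NA_integer_
  )
}

#' @export
autoplot.amdnet_prioritization <- function(object, ...) {
  dat <- dplyr::filter(object, .data$betweenness_actual > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$betweenness_actual,
                                    y = .data$fdr)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                        alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "seed-pair betweenness (log scale)",
                  y = "permutation FDR", colour = "selected") +
    ggplot2::theme_minimal()
}

# -- internal ---------------------------------------------------------------

# replicate r of master seed m gets its own stream; kept below 2^31
derive_seed <- function(master, r) {
  (as.double(master) * 48271 + as.double(r) * 69621) %% 2147483647
}
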