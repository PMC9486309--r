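#' Jaccard and overlap coefficients for gene sets
#'
#' `jaccard(A, B)` is `|A ∩ B| / |A ∪ B|`; `overlap_coefficient(A, B)` is
#' `|A ∩ B| / min(|A|, |B|)`; `crosstalk_score(A, B)` is their arithmetic
#' mean, the edge weight of the pathway-crosstalk network. For any nonempty
#' sets, `0 <= JC <= OC <= 1`.
#'
#' @param A,B Character vectors (treated as sets).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D"))
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0) {
    abort("jaccard is undefined for two empty sets")
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' @rdname jaccard
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0) {
    abort("overlap_coefficient needs two nonempty sets")
  }
  length(intersect(A, B)) / min(length(A), length(B))
}

#' @rdname jaccard
#' @export
crosstalk_score <- function(A, B) {
  (jaccard(A, B) + overlap_coefficient(A, B)) / 2
}

#' Build pathway-crosstalk edges from enrichment results
#'
#' One undirected edge per pair of significant pathways sharing at least
#' `min_shared` genes, weighted by the mean of the Jaccard and overlap
#' coefficients. By default the operand sets are the pathways' observed
#' candidate-gene sets (query ∩ pathway), the quantity counted by the
#' shared-candidate-gene rule; set `use = "members"` (and supply
#' `annotations`) to score full pathway memberships instead.
#'
#' @param records `amdnet_enrichment` tibble from [enrich()], or any data
#'   frame with `pathway_id` and a list-column of gene sets named
#'   `observed`. Only rows with `significant == TRUE` are used when the
#'   column is present.
#' @param min_shared Minimum shared-gene count for a pair to become an edge
#'   (default 2).
#' @param use `"observed"` (default) or `"members"`.
#' @param annotations Annotation collection, required for `use = "members"`.
#' @return Tibble of class `amdnet_crosstalk`: columns `pathway_a`,
#'   `pathway_b` (with `pathway_a < pathway_b`), list-column `shared`,
#'   `shared_count`, `jc`, `oc`, `score`; sorted descending by `score`,
#'   ties by (`pathway_a`, `pathway_b`).
#' @export
build_crosstalk_edges <- function(records, min_shared = 2,
                                  use = c("observed", "members"),
                                  annotations = NULL) {
  use <- match.arg(use)
  if ("significant" %in% names(records)) {
    records <- dplyr::filter(records, .data$significant)
  }
  if (use == "observed") {
    if (!"observed" %in% names(records)) {
      abort("`records` must carry an `observed` list-column")
    }
    sets <- setNames(records$observed, records$pathway_id)
  } else {
    if (is.null(annotations)) {
      abort("`annotations` is required when use = \"members\"")
    }
    annotations <- validate_annotation_collection(annotations)
    idx <- match(records$pathway_id, annotations$pathway_id)
    if (anyNA(idx)) abort("pathway_id(s) missing from `annotations`")
    sets <- setNames(annotations$genes[idx], records$pathway_id)
  }
  if (length(sets) < 2L) {
    abort("need at least two significant pathways to build crosstalk edges")
  }
  ids <- sort(names(sets))
  pairs <- utils::combn(ids, 2L)
  edges <- tibble::tibble(
    pathway_a = pairs[1L, ],
    pathway_b = pairs[2L, ],
    shared = purrr::map2(.data$pathway_a, .data$pathway_b,
                         ~ sort(intersect(sets[[.x]], sets[[.y]]))),
    shared_count = lengths(.data$shared)
  ) |>
    dplyr::filter(.data$shared_count >= min_shared) |>
    dplyr::mutate(
      jc = purrr::map2_dbl(.data$pathway_a, .data$pathway_b,
                           ~ jaccard(sets[[.x]], sets[[.y]])),
      oc = purrr::map2_dbl(.data$pathway_a, .data$pathway_b,
                           ~ overlap_coefficient(sets[[.x]], sets[[.y]])),
      score = (.data$jc + .data$oc) / 2
    ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pathway_a, .data$pathway_b)
  class(edges) <- c("amdnet_crosstalk", class(edges))
  edges
}

#' Retain the highest-scoring fraction of crosstalk edges
#'
#' Keeps the `ceiling(fraction * n)` top edges by score; any edge tying the
#' cutoff score is also retained, so the result is deterministic and
#' independent of the order among equal scores. Idempotent, and monotone in
#' `fraction`.
#'
#' @param edges `amdnet_crosstalk` tibble sorted descending by score (as
#'   produced by [build_crosstalk_edges()]).
#' @param fraction Proportion in (0, 1].
#' @return The retained edges, same class and ordering.
#' @export
select_top_fraction <- function(edges, fraction = 0.5) {
  if (nrow(edges) == 0L) abort("no edges to select from")
  if (!(fraction > 0 && fraction <= 1)) abort("`fraction` must be in (0, 1]")
  edges <- dplyr::arrange(edges, dplyr::desc(.data$score),
                          .data$pathway_a, .data$pathway_b)
  n_keep <- ceiling(fraction * nrow(edges))
  cutoff <- edges$score[n_keep]
  out <- dplyr::filter(edges, .data$score >= cutoff)
  class(out) <- unique(c("amdnet_crosstalk", class(out)))
  out
}

#' Assemble a crosstalk network and detect pathway modules
#'
#' Builds the undirected pathway network from retained edges and partitions
#' its nodes with greedy modularity maximization (edge weight = crosstalk
#' score). Nodes adjacent to two or more modules (counting their own) are
#' flagged as bridges — the connector pathways joining modules.
#'
#' Deterministic: nodes enter the graph in sorted `pathway_id` order.
#'
#' @param edges `amdnet_crosstalk` tibble with at least one edge.
#' @return A list of class `crosstalk_network` with elements `nodes`
#'   (tibble: `pathway_id`, `module` integer label, `bridge` logical),
#'   `edges` (the input tibble) and `modularity` (the achieved weighted
#'   modularity).
#' @export
detect_modules <- function(edges) {
  if (nrow(edges) == 0L) abort("cannot detect modules in an edgeless network")
  g <- crosstalk_igraph(edges)
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$score)
  # cut at the coarsest partition achieving maximal modularity, so exact
  # ties (e.g. a single clique, where Q = 0 for one community and for some
  # splits) resolve to the merged partition
  q <- comm$modularity
  k_best <- igraph::vcount(g) - (max(which(q >= max(q) - 1e-12)) - 1L)
  member <- setNames(igraph::cut_at(comm, no = k_best), igraph::V(g)$name)
  nodes <- tibble::tibble(
    pathway_id = igraph::V(g)$name,
    module = as.integer(member)
  )
  # bridge: the node's closed neighbourhood spans >= 2 modules
  adj <- igraph::as_adj_list(g)
  nodes$bridge <- purrr::imap_lgl(adj, function(nb, i) {
    mods <- unique(c(member[[i]], member[as.integer(nb)]))
    length(mods) >= 2L
  })
  structure(
    list(nodes = nodes, edges = edges,
         modularity = igraph::modularity(g, member,
                                         weights = igraph::E(g)$score)),
    class = "crosstalk_network"
  )
}

#' Export a crosstalk network
#'
#' `SIF` writes one line per edge (`a crosstalk b`); `GraphML` carries
#' `jc`, `oc`, `score` and `shared_count` as edge attributes and, when
#' modules have been detected, the module label and bridge flag as node
#' attributes. GraphML files round-trip through [read_crosstalk_graphml()]
#' with scores preserved to at least 5 decimals.
#'
#' @param network A `crosstalk_network` (from [detect_modules()]) or an
#'   `amdnet_crosstalk` edge tibble.
#' @param format `"SIF"` or `"GraphML"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, format = c("SIF", "GraphML"), path) {
  format <- match.arg(format)
  if (inherits(network, "crosstalk_network")) {
    edges <- network$edges
    nodes <- network$nodes
  } else {
    edges <- network
    nodes <- NULL
    warn("export_graph: no module partition on this network; exporting edges only")
  }
  if (format == "SIF") {
    writeLines(paste(edges$pathway_a, "crosstalk", edges$pathway_b),
               path)
    return(invisible(path))
  }
  g <- crosstalk_igraph(edges)
  if (!is.null(nodes)) {
    idx <- match(igraph::V(g)$name, nodes$pathway_id)
    igraph::V(g)$module <- nodes$module[idx]
    igraph::V(g)$bridge <- nodes$bridge[idx]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read back a GraphML crosstalk export
#'
#' @param path Path written by [export_graph()] with `format = "GraphML"`.
#' @return Tibble with columns `pathway_a`, `pathway_b`, `shared_count`,
#'   `jc`, `oc`, `score` (and node table attribute `nodes` when module
#'   labels were present).
#' @export
read_crosstalk_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  out <- tibble::tibble(
    pathway_a = el[, 1], pathway_b = el[, 2],
    shared_count = igraph::E(g)$shared_count,
    jc = igraph::E(g)$jc, oc = igraph::E(g)$oc, score = igraph::E(g)$score
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pathway_a, .data$pathway_b)
  if ("module" %in% igraph::vertex_attr_names(g)) {
    attr(out, "nodes") <- tibble::tibble(
      pathway_id = igraph::V(g)$name,
      module = as.integer(igraph::V(g)$module),
      bridge = as.logical(igraph::V(g)$bridge)
    )
  }
  out
}

#' Write a crosstalk edge table to TSV
#'
#' @param edges `amdnet_crosstalk` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstalk <- function(edges, path) {
  flat <- tidy.amdnet_crosstalk(edges)
  write.table(as.data.frame(flat), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
tidy.amdnet_crosstalk <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(shared_genes = purrr::map_chr(.data$shared,
                                                paste, collapse = ";")) |>
    dplyr::select("pathway_a", "pathway_b", "shared_count", "shared_genes",
                  "jc", "oc", "score")
}

#' @export
glance.amdnet_crosstalk <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x),
    n_pathways = length(unique(c(x$pathway_a, x$pathway_b))),
    mean_score = mean(x$score),
    max_score = if (nrow(x)) max(x$score) else NA_real_
  )
}

#' @export
tidy.crosstalk_network <- function(x, ...) x$nodes

#' @export
glance.crosstalk_network <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_modules = length(unique(x$nodes$module)),
    n_bridges = sum(x$nodes$bridge),
    modularity = x$modularity
  )
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_network> %d pathways, %d edges, %d modules (modularity %.3f), %d bridge node(s)\n",
    nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$module)),
    x$modularity, sum(x$nodes$bridge)
  ))
  invisible(x)
}

#' @export
autoplot.crosstalk_network <- function(object, ...) {
  g <- crosstalk_igraph(object$edges)
  set.seed(1L)  # layout only
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$score)
  nd <- object$nodes[match(igraph::V(g)$name, object$nodes$pathway_id), ]
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  el <- igraph::as_edgelist(g)
  ed <- tibble::tibble(
    x = nd$x[match(el[, 1], nd$pathway_id)],
    y = nd$y[match(el[, 1], nd$pathway_id)],
    xend = nd$x[match(el[, 2], nd$pathway_id)],
    yend = nd$y[match(el[, 2], nd$pathway_id)],
    score = igraph::E(g)$score
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$score),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = factor(.data$module), shape = .data$bridge),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::labs(colour = "module", shape = "bridge",
                  linewidth = "score") +
    ggplot2::theme_void()
}

# -- internal ---------------------------------------------------------------

crosstalk_igraph <- function(edges) {
  node_ids <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  igraph::graph_from_data_frame(
    data.frame(from = edges$pathway_a, to = edges$pathway_b,
               shared_count = edges$shared_count,
               jc = edges$jc, oc = edges$oc, score = edges$score),
    directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
}
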