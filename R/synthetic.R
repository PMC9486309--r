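#' Configuration for a synthetic disease-network study
#'
#' Bundles every knob of the synthetic-study generator. The defaults are
#' the package's desk-scale study conditions: a 2000-node scale-free
#' background (preferential attachment, 3 edges per new node), a planted
#' disease module of 60 seed genes wired through 20 hidden linker genes
#' (2 linker attachments per seed), and 30 annotation gene sets of 10-40
#' members of which 30% are enriched for seed genes, with 3 forced shared
#' genes between designated pathway pairs.
#'
#' @param n_nodes Background graph size.
#' @param attachment_m Edges added per new node in preferential attachment.
#' @param n_seeds Number of planted seed genes (added as new nodes).
#' @param n_linkers Number of background nodes designated as linkers.
#' @param linker_attach Distinct linkers each seed attaches to.
#' @param n_pathways Number of annotation gene sets.
#' @param pathway_size_range Integer pair, inclusive size range (min 3).
#' @param enriched_fraction Fraction of pathways seeded with disease genes.
#' @param overlap_rate Shared genes forced between designated consecutive
#'   pathway pairs (0 disables forcing).
#' @param rng_seed Master integer seed; all generator randomness derives
#'   from it.
#' @param topology `"pa"` (preferential attachment, default) or `"er"`
#'   (Erdős–Rényi with matched edge count, for null experiments).
#' @param mode `"planted"` (seeds attach only to linkers, unambiguous
#'   ground truth) or `"diluted"` (seeds also wired into the background,
#'   harder recovery).
#' @param dilute_attach Extra random background attachments per seed in
#'   diluted mode.
#' @param overlap_mode `"random"` (default) or `"disjoint"` (pathways
#'   partition the universe; no shared genes).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 2000, attachment_m = 3, n_seeds = 60,
                         n_linkers = 20, linker_attach = 2,
                         n_pathways = 30, pathway_size_range = c(10, 40),
                         enriched_fraction = 0.3, overlap_rate = 3,
                         rng_seed = 1L, topology = c("pa", "er"),
                         mode = c("planted", "diluted"), dilute_attach = 2,
                         overlap_mode = c("random", "disjoint")) {
  cfg <- list(
    n_nodes = n_nodes, attachment_m = attachment_m, n_seeds = n_seeds,
    n_linkers = n_linkers, linker_attach = linker_attach,
    n_pathways = n_pathways, pathway_size_range = pathway_size_range,
    enriched_fraction = enriched_fraction, overlap_rate = overlap_rate,
    rng_seed = as.integer(rng_seed), topology = match.arg(topology),
    mode = match.arg(mode), dilute_attach = dilute_attach,
    overlap_mode = match.arg(overlap_mode)
  )
  stopifnot(
    cfg$attachment_m >= 1,
    cfg$n_seeds + cfg$n_linkers <= cfg$n_nodes,
    cfg$n_linkers >= 1,
    cfg$linker_attach >= 1,
    cfg$pathway_size_range[1] >= 3,
    cfg$pathway_size_range[1] <= cfg$pathway_size_range[2],
    cfg$enriched_fraction >= 0, cfg$enriched_fraction <= 1
  )
  if (cfg$linker_attach > cfg$n_linkers) {
    abort("infeasible config: linker_attach exceeds n_linkers")
  }
  if (cfg$mode == "planted" &&
      cfg$n_seeds * cfg$linker_attach < 2 * cfg$n_linkers) {
    abort(paste(
      "infeasible planted config: need n_seeds * linker_attach >=",
      "2 * n_linkers so every linker carries at least two seeds"
    ))
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic interactome with a planted disease module
#'
#' Builds a scale-free (or Erdős–Rényi) background graph, designates a
#' connected scaffold of `n_linkers` background nodes as linkers (one
#' connector node plus low-degree leaves in its neighbourhood, so planted
#' linkers are peripheral rather than topology-driven hubs), and adds
#' `n_seeds` new seed nodes each attached to `linker_attach` distinct
#' linkers. In planted mode seeds attach to linkers only, so every
#' seed-seed geodesic traverses linkers, and the balanced round-robin
#' seed-to-linker assignment guarantees every linker carries at least two
#' seeds — hence lies on at least one seed-pair geodesic (the length-2
#' path through it). The graph is simple, connected, and bit-reproducible
#' from `rng_seed`.
#'
#' @param config A [synth_config()].
#' @return List with elements `graph` (igraph) and `truth` (list of class
#'   `synth_truth`: `seeds`, `linkers`, `config`).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_nodes
  set.seed(derive_seed(config$rng_seed, 101))
  g <- if (config$topology == "pa") {
    igraph::sample_pa(n, m = config$attachment_m, directed = FALSE)
  } else {
    er <- igraph::sample_gnm(n, m = n * config$attachment_m)
    connect_components(er)
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("N%05d", seq_len(n))

  # Connected linker scaffold: one connector node plus low-degree leaves in
  # its neighbourhood. Planted linkers must be distinguishable from
  # topology-driven hubs (which hub exclusion removes by design), so leaves
  # are drawn from the lowest-degree nodes available; the star shape keeps
  # null-model traffic from random seed draws localized to each drawn
  # seed's own linkers instead of flowing through the whole scaffold.
  set.seed(derive_seed(config$rng_seed, 102))
  linkers <- pick_star_scaffold(g, config$n_linkers)

  seeds <- sprintf("SEED%03d", seq_len(config$n_seeds))
  g <- igraph::add_vertices(g, config$n_seeds, name = seeds)

  # balanced round-robin over a randomly permuted linker order:
  # seed i takes linkers ((i-1)*a + 0:(a-1)) mod L, which spreads the
  # n_seeds*a stubs evenly (every linker gets >= 2 under the feasibility
  # rule), while the permutation randomizes which linker is which.
  perm <- sample(linkers)
  a <- config$linker_attach
  L <- config$n_linkers
  new_edges <- character(0)
  for (i in seq_len(config$n_seeds)) {
    lk <- perm[((i - 1) * a + seq_len(a) - 1) %% L + 1]
    new_edges <- c(new_edges, rbind(seeds[i], lk))
  }
  if (config$mode == "diluted") {
    background <- setdiff(igraph::V(g)$name, c(seeds, linkers))
    for (i in seq_len(config$n_seeds)) {
      extra <- sample(background, config$dilute_attach)
      new_edges <- c(new_edges, rbind(seeds[i], extra))
    }
  }
  g <- igraph::add_edges(g, match(new_edges, igraph::V(g)$name))
  g <- igraph::simplify(g)

  truth <- structure(
    list(seeds = seeds, linkers = linkers,
         enriched_pathway_ids = character(0), config = config),
    class = "synth_truth"
  )
  list(graph = g, truth = truth)
}

#' Generate an annotation collection with controlled enrichment and overlap
#'
#' Draws `n_pathways` gene sets from `universe`. Enriched pathways (a
#' random `enriched_fraction` of them) replace one third of their members
#' with seed genes, a known violation of the hypergeometric null; the
#' remaining pathways draw uniformly, so with `enriched_fraction = 0` the
#' per-pathway seed count follows the hypergeometric null exactly.
#' Designated consecutive pathway pairs (P1-P2, P3-P4, ...) are forced to
#' share at least `overlap_rate` genes; in `"disjoint"` overlap mode the
#' pathways partition the universe and share nothing.
#'
#' @param config A [synth_config()].
#' @param universe Character vector of available gene symbols.
#' @param seeds Seed gene symbols (must be within reach of `universe` union
#'   seeds); used only when `enriched_fraction > 0`.
#' @return List with `collection` (annotation tibble as from [read_gmt()])
#'   and `truth` (list: `enriched_pathway_ids`, `forced_pairs`).
#' @export
generate_annotations <- function(config, universe, seeds = character(0)) {
  stopifnot(inherits(config, "synth_config"))
  universe <- unique(normalize_symbol(universe))
  seeds <- unique(normalize_symbol(seeds))
  sizes_ok <- max(config$pathway_size_range) <= length(universe)
  if (!sizes_ok) abort("universe smaller than the largest pathway size")
  set.seed(derive_seed(config$rng_seed, 103))

  np <- config$n_pathways
  ids <- sprintf("PW%03d", seq_len(np))
  size_choices <- seq(config$pathway_size_range[1],
                      config$pathway_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), np, replace = TRUE)]
  n_enriched <- round(config$enriched_fraction * np)
  enriched <- sort(sample(ids, n_enriched))
  nonseed_pool <- setdiff(universe, seeds)

  members <- vector("list", np)
  if (config$overlap_mode == "disjoint") {
    if (sum(sizes) > length(universe)) {
      abort("universe too small for disjoint pathways")
    }
    pool <- sample(universe)
    offset <- cumsum(c(0, sizes[-np]))
    for (j in seq_len(np)) {
      members[[j]] <- pool[offset[j] + seq_len(sizes[j])]
    }
  } else {
    for (j in seq_len(np)) {
      forced <- character(0)
      if (config$overlap_rate > 0 && j %% 2 == 0) {
        prev <- members[[j - 1]]
        forced <- sample(prev, min(config$overlap_rate, length(prev)))
      }
      free <- sizes[j] - length(forced)
      if (ids[j] %in% enriched && length(seeds) > 0) {
        seed_pool <- setdiff(seeds, forced)
        k_seed <- min(max(2L, round(sizes[j] / 3)), length(seed_pool), free)
        picked <- c(sample(seed_pool, k_seed),
                    sample(setdiff(nonseed_pool, forced), free - k_seed))
      } else {
        picked <- sample(setdiff(universe, forced), free)
      }
      members[[j]] <- unique(c(forced, picked))
    }
  }

  collection <- new_annotation_collection(tibble::tibble(
    pathway_id = ids,
    name = paste("synthetic pathway", seq_len(np)),
    source = "synthetic",
    genes = members
  ))
  forced_pairs <- if (config$overlap_rate > 0 &&
                      config$overlap_mode == "random") {
    m <- matrix(ids[seq_len(np - np %% 2)], nrow = 2)
    tibble::tibble(pathway_a = m[1, ], pathway_b = m[2, ])
  } else {
    tibble::tibble(pathway_a = character(0), pathway_b = character(0))
  }
  list(collection = collection,
       truth = list(enriched_pathway_ids = enriched,
                    forced_pairs = forced_pairs))
}

#' Generate a complete synthetic study bundle on disk
#'
#' Writes the four pipeline inputs — interactome edge-list TSV, seed gene
#' list, pathway GMT — plus a machine-readable truth record (JSON) and the
#' generating configuration (YAML). A pipeline run on the bundle needs no
#' other inputs.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return List with the file `paths`, the in-memory `graph`, `collection`
#'   and combined `truth`.
#' @export
generate_study <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- generate_interactome(config)
  ann <- generate_annotations(config, universe = igraph::V(net$graph)$name,
                              seeds = net$truth$seeds)
  truth <- net$truth
  truth$enriched_pathway_ids <- ann$truth$enriched_pathway_ids
  truth$forced_pairs <- ann$truth$forced_pairs

  paths <- list(
    interactome = file.path(dir, "interactome.tsv"),
    seeds = file.path(dir, "seeds.txt"),
    gmt = file.path(dir, "pathways.gmt"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  el <- igraph::as_edgelist(net$graph)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), paths$interactome)
  writeLines(truth$seeds, paths$seeds)
  write_gmt(ann$collection, paths$gmt)
  jsonlite::write_json(
    list(seeds = truth$seeds, linkers = truth$linkers,
         enriched_pathway_ids = truth$enriched_pathway_ids,
         forced_pairs = truth$forced_pairs),
    paths$truth
  )
  yaml::write_yaml(unclass(config), paths$config)
  list(paths = paths, graph = net$graph, collection = ann$collection,
       truth = truth)
}

# -- internal ---------------------------------------------------------------

# connected scaffold of n nodes: a connector ("center") with n - 1 of its
# lowest-degree neighbours as leaves; the smallest degree cap that yields
# enough leaves is used, and the center is drawn from the best-supplied
# candidates so different rng seeds pick different regions
pick_star_scaffold <- function(g, n_linkers) {
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  caps <- sort(unique(c(min(deg), 3, 4, 5, max(deg))))
  for (cap in caps) {
    n_low <- vapply(adj, function(nb) sum(deg[as.integer(nb)] <= cap),
                    numeric(1))
    cand <- which(n_low >= n_linkers - 1)
    if (length(cand) == 0L) next
    top <- cand[n_low[cand] >= quantile(n_low[cand], 0.9)]
    center <- top[sample.int(length(top), 1L)]
    nb <- as.integer(adj[[center]])
    pool <- nb[deg[nb] <= cap]
    leaves <- pool[sample.int(length(pool), n_linkers - 1L)]
    return(igraph::V(g)$name[c(center, leaves)])
  }
  # degenerate graphs: fall back to a BFS prefix of the full graph
  ord <- as.integer(igraph::bfs(g, root = sample.int(igraph::vcount(g), 1L),
                                order = TRUE)$order)
  igraph::V(g)$name[ord[seq_len(n_linkers)]]
}

# join components of a random graph by chaining one vertex of each
connect_components <- function(g) {
  comp <- igraph::components(g)
  if (comp$no == 1L) return(g)
  reps <- vapply(seq_len(comp$no),
                 function(k) which(comp$membership == k)[1L], integer(1))
  igraph::add_edges(g, as.vector(rbind(reps[-length(reps)], reps[-1L])))
}
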