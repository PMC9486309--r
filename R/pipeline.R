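#' Default pipeline thresholds
#'
#' One authoritative record of the pipeline's default thresholds:
#' enrichment significance `alpha = 0.05` on the BH-adjusted p-value,
#' pathway retention at `min_observed = 2` candidate genes, crosstalk edge
#' retention at `min_shared = 2` shared genes and `top_fraction = 0.5` of
#' edges by score, and prioritization at `n_perm = 100` permutations,
#' `b_min = 1000` (exclusive), `fdr_max = 0.05` (exclusive) and
#' `hub_max = 50` positive permutations (exclusive).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    alpha = 0.05,
    min_observed = 2,
    require_raw_p = FALSE,
    min_shared = 2,
    top_fraction = 0.5,
    n_perm = 100,
    b_min = 1000,
    fdr_max = 0.05,
    hub_max = 50,
    rng_seed = 1L,
    crosstalk_input = "significant"
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates enrichment, crosstalk and prioritization from a single
#' config (a named list or a YAML file path), writing every stage's table
#' and graph export plus a JSON run report with record counts at every
#' filter. Inputs: `seeds` (gene list file), `gmt` (annotation GMT) and
#' either `interactome` (edge-list TSV, full prioritization) or
#' `candidate_table` (gene/betweenness TSV, table-audit mode in which the
#' betweenness filter and seed annotation are applied to precomputed
#' values). Thresholds default to [default_run_config()].
#'
#' Set `crosstalk_input: "all"` when the GMT already holds the significant
#' pathways' candidate-gene sets (as the packaged worked-example fixture
#' does), so crosstalk runs on all collection entries rather than on the
#' enrichment-significant subset.
#'
#' With a fixed `rng_seed`, re-running an identical config reproduces
#' every output byte-for-byte.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with `enrichment`, `crosstalk`, `network`,
#'   `prioritization` (whichever ran) and `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort("run_pipeline: an output directory is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(cfg$seeds)) abort("run_pipeline: config$seeds is required")
  report <- list(config = cfg, package_version = as.character(
    utils::packageVersion("amdnet")), counts = list())
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  seeds <- stage("read_seeds", read_gene_list(cfg$seeds, quiet = TRUE))
  report$counts$seed_genes <- length(seeds)

  if (!is.null(cfg$gmt)) {
    annotations <- stage("read_gmt", read_gmt(cfg$gmt))
    report$counts$pathways_in_collection <- nrow(annotations)

    enr <- stage("enrichment", enrich(
      seeds, annotations, alpha = cfg$alpha,
      min_observed = cfg$min_observed,
      require_raw_p = cfg$require_raw_p, quiet = TRUE
    ))
    report$counts$pathways_tested <- nrow(enr)
    report$counts$pathways_significant <- sum(enr$significant)
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    results$enrichment <- enr

    ct_records <- if (identical(cfg$crosstalk_input, "all")) {
      tibble::tibble(pathway_id = annotations$pathway_id,
                     observed = lapply(annotations$genes, intersect, y = seeds))
    } else {
      enr[enr$significant, ]
    }
    ct_records <- ct_records[lengths(ct_records$observed) >=
                               cfg$min_observed, ]
    n_ct_input <- nrow(ct_records)
    report$counts$crosstalk_input_pathways <- n_ct_input
    if (n_ct_input >= 2L) {
      edges <- stage("crosstalk", build_crosstalk_edges(
        ct_records, min_shared = cfg$min_shared
      ))
      report$counts$crosstalk_edges <- nrow(edges)
      if (nrow(edges) > 0) {
        top <- select_top_fraction(edges, cfg$top_fraction)
        report$counts$crosstalk_edges_top <- nrow(top)
        net <- detect_modules(top)
        report$counts$crosstalk_modules <- length(unique(net$nodes$module))
        write_crosstalk(edges, file.path(out_dir, "crosstalk_edges.tsv"))
        export_graph(net, "SIF", file.path(out_dir, "crosstalk.sif"))
        export_graph(net, "GraphML",
                     file.path(out_dir, "crosstalk.graphml"))
        results$crosstalk <- edges
        results$network <- net
      }
    }
  }

  if (!is.null(cfg$interactome)) {
    g <- stage("read_interactome", read_interactome(cfg$interactome,
                                                    quiet = TRUE))
    report$counts$interactome_nodes <- igraph::vcount(g)
    report$counts$interactome_edges <- igraph::ecount(g)
    pri <- stage("prioritize", prioritize(
      g, seeds, n_perm = cfg$n_perm, rng_seed = cfg$rng_seed,
      b_min = cfg$b_min, fdr_max = cfg$fdr_max, hub_max = cfg$hub_max
    ))
    report$counts$genes_scored <- nrow(pri)
    report$counts$candidates_selected <- sum(pri$selected)
    report$counts$candidate_seed_overlap <-
      sum(pri$selected & pri$is_seed)
    write.table(as.data.frame(tidy(pri)),
                file.path(out_dir, "prioritization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    export_candidate_subnetwork(
      g, pri, seeds, file.path(out_dir, "candidate_subnetwork.graphml"))
    results$prioritization <- pri
  } else if (!is.null(cfg$candidate_table)) {
    cand <- stage("audit_candidates",
                  read_candidate_table(cfg$candidate_table))
    report$counts$candidate_rows <- nrow(cand)
    kept <- cand[cand$betweenness > cfg$b_min, ]
    kept <- kept[order(-kept$betweenness, kept$gene), ]
    kept <- annotate_candidates(kept, seeds)
    report$counts$candidates_selected <- nrow(kept)
    report$counts$candidate_seed_overlap <- attr(kept, "overlap_count")
    write.table(as.data.frame(kept),
                file.path(out_dir, "prioritization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$prioritization <- kept
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$report <- report
  invisible(results)
}

#' Audit the packaged worked-example fixtures
#'
#' Recomputes, from the packaged fixtures alone, the worked-example counts
#' of the AMD analysis the fixtures transcribe: the size of the curated
#' seed gene set, the number of candidate rows surviving the betweenness
#' filter, their overlap with the seed set, and the smallest retained
#' betweenness.
#'
#' @param b_min Betweenness threshold (exclusive), default 1000.
#' @return Tibble with one row: `amdgset_size`,
#'   `candidate_count_after_filter`, `seed_overlap_count`,
#'   `min_candidate_betweenness`.
#' @export
audit_fixture_tables <- function(b_min = 1000) {
  seeds <- read_gene_list(amd_fixture("seeds"), quiet = TRUE)
  cand <- read_candidate_table(amd_fixture("candidates"))
  kept <- cand[cand$betweenness > b_min, ]
  kept <- annotate_candidates(kept, seeds)
  tibble::tibble(
    amdgset_size = length(seeds),
    candidate_count_after_filter = nrow(kept),
    seed_overlap_count = attr(kept, "overlap_count"),
    min_candidate_betweenness = min(kept$betweenness)
  )
}
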