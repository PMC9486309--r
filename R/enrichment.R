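#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the one-sided Fisher exact
#' p-value for over-representation on the 2x2 table (k of the n query genes
#' fall in a pathway of K genes inside a background of N genes).
#'
#' @param k Overlap count.
#' @param K Pathway size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return Probability in \[0, 1\]. Vectorized over `k`, `K`, `n`, `N`.
#' @examples
#' hypergeom_upper_tail(3, 5, 6, 20)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) {
    abort(sprintf(
      "inconsistent hypergeometric counts at position(s) %s: need 0 <= k <= min(K, n) and K, n <= N",
      paste(which(bad), collapse = ", ")
    ))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, clipped at 1, reported in the
#' original input order. Output is elementwise >= input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set against pathway annotations
#'
#' For each pathway, tests whether the query set overlaps its membership
#' more than expected under uniform draws from the background universe
#' (hypergeometric upper tail, equivalently one-sided Fisher). Pathways
#' overlapping the query in fewer than `min_observed` genes are dropped
#' before testing; the BH correction runs over exactly the retained tests.
#'
#' Query genes absent from the background are dropped (with a message)
#' so the 2x2 table stays coherent; pathway memberships are likewise
#' intersected with the background.
#'
#' @param query Character vector of query gene symbols (normalized
#'   internally).
#' @param annotations Annotation collection tibble from [read_gmt()] (or any
#'   data frame with `pathway_id`, `name`, and list-column `genes`).
#' @param background Background universe of symbols. Default: the union of
#'   all genes in `annotations`.
#' @param alpha Significance level applied to the BH-adjusted p-value.
#' @param min_observed Minimum number of query genes a pathway must contain
#'   to be tested (default 2).
#' @param require_raw_p If `TRUE`, significance additionally requires the
#'   raw p-value below `alpha` (the stricter joint rule some analyses apply
#'   to GO terms).
#' @param quiet Suppress messages.
#' @return A tibble of class `amdnet_enrichment`, one row per retained
#'   pathway, sorted by ascending `p_raw` (ties by `pathway_id`): columns
#'   `pathway_id`, `name`, `observed_count`, `observed` (list-column of the
#'   query genes in the pathway), `p_raw`, `p_bh`, `significant`.
#'   Attributes record `alpha`, the background size and the effective query
#'   size.
#' @export
enrich <- function(query, annotations, background = NULL, alpha = 0.05,
                   min_observed = 2, require_raw_p = FALSE, quiet = FALSE) {
  annotations <- validate_annotation_collection(annotations)
  if (nrow(annotations) == 0L) abort("annotation collection is empty")
  query <- unique(normalize_symbol(query))
  background <- if (is.null(background)) {
    unique(unlist(annotations$genes, use.names = FALSE))
  } else {
    unique(normalize_symbol(background))
  }
  dropped <- setdiff(query, background)
  if (length(dropped) > 0 && !quiet) {
    inform(sprintf(
      "enrich: %d query gene(s) absent from the background were dropped",
      length(dropped)
    ))
  }
  query <- intersect(query, background)
  if (length(query) == 0L) {
    abort("no query genes remain after intersecting with the background")
  }

  res <- annotations |>
    dplyr::mutate(
      members = purrr::map(.data$genes, intersect, y = background),
      observed = purrr::map(.data$members, intersect, y = query),
      observed_count = lengths(.data$observed),
      K = lengths(.data$members)
    ) |>
    dplyr::filter(.data$observed_count >= min_observed, .data$K > 0)
  if (nrow(res) == 0L) {
    if (!quiet) inform("enrich: no pathway meets the min_observed rule")
  }
  res <- res |>
    dplyr::mutate(
      p_raw = hypergeom_upper_tail(.data$observed_count, .data$K,
                                   length(query), length(background)),
      p_bh = bh_adjust(.data$p_raw),
      significant = if (require_raw_p) {
        .data$p_bh < alpha & .data$p_raw < alpha
      } else {
        .data$p_bh < alpha
      }
    ) |>
    dplyr::arrange(.data$p_raw, .data$pathway_id) |>
    dplyr::select("pathway_id", "name", "observed_count", "observed",
                  "p_raw", "p_bh", "significant")
  res$observed <- lapply(res$observed, function(g) sort(g))
  attr(res, "alpha") <- alpha
  attr(res, "min_observed") <- min_observed
  attr(res, "background_size") <- length(background)
  attr(res, "query_size") <- length(query)
  class(res) <- c("amdnet_enrichment", class(res))
  res
}

#' Write an enrichment table to TSV
#'
#' @param x `amdnet_enrichment` tibble from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  flat <- as.data.frame(tidy(x))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.amdnet_enrichment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      observed_genes = purrr::map_chr(.data$observed,
                                      ~ paste(sort(.x), collapse = ";"))
    ) |>
    dplyr::select("pathway_id", "name", "observed_count", "observed_genes",
                  "p_raw", "p_bh", "significant")
}

#' @export
glance.amdnet_enrichment <- function(x, ...) {
  tibble::tibble(
    n_pathways_tested = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    min_observed = attr(x, "min_observed"),
    background_size = attr(x, "background_size"),
    query_size = attr(x, "query_size")
  )
}

#' @export
autoplot.amdnet_enrichment <- function(object, top = 15, ...) {
  dat <- utils::head(object, top) |>
    dplyr::mutate(
      name = factor(.data$name, levels = rev(unique(.data$name))),
      neglog = -log10(pmax(.data$p_bh, .Machine$double.xmin))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$neglog, y = .data$name,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "BH-adjusted p"), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}
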