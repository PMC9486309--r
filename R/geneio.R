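#' Normalize gene symbols
#'
#' Canonical symbol form used throughout the package: surrounding whitespace
#' stripped, letters uppercased. No alias or identifier mapping is attempted;
#' curated disease-gene tables and pathway membership lists operate at the
#' symbol level, so normalization is deliberately minimal. An optional
#' two-column alias table (columns `from`, `to`) may be applied before
#' normalization for users whose inputs mix synonyms.
#'
#' @param x Character vector of raw symbols.
#' @param alias Optional data frame with columns `from` and `to`; exact
#'   matches of the stripped raw symbol against `from` are replaced by `to`
#'   before uppercasing.
#' @return Character vector of normalized symbols, same length as `x`.
#'   Normalization is idempotent.
#' @examples
#' normalize_symbol(c(" cfh ", "C20orf85"))
#' @export
normalize_symbol <- function(x, alias = NULL) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of gene symbols.")
  }
  out <- trimws(x)
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "empty or whitespace-only gene symbol at position(s) %s",
      paste(which(bad), collapse = ", ")
    ))
  }
  if (!is.null(alias)) {
    stopifnot(is.data.frame(alias), all(c("from", "to") %in% names(alias)))
    hit <- match(out, trimws(alias$from))
    out[!is.na(hit)] <- trimws(alias$to)[hit[!is.na(hit)]]
  }
  toupper(out)
}

#' Read a gene set from a one-symbol-per-line file
#'
#' Lines beginning with `#` are comments; symbols are normalized with
#' [normalize_symbol()] and deduplicated (set semantics). Duplicate lines
#' are reported with a count.
#'
#' @param path Path to a plain-text file, one symbol per line.
#' @param alias Optional alias table, see [normalize_symbol()].
#' @param quiet Suppress the duplicate-count message.
#' @return Character vector of unique normalized symbols, in first-seen order.
#' @export
read_gene_list <- function(path, alias = NULL, quiet = FALSE) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("no gene symbols found in '%s'", path))
  }
  syms <- normalize_symbol(lines, alias = alias)
  n_dup <- sum(duplicated(syms))
  if (n_dup > 0 && !quiet) {
    inform(sprintf("read_gene_list: dropped %d duplicate symbol(s) in '%s'",
                   n_dup, basename(path)))
  }
  unique(syms)
}

#' Read an annotation collection from a GMT file
#'
#' Standard GMT dialect: tab-separated, field 1 the pathway identifier,
#' field 2 a free-text description, fields 3+ the member symbols. Lines
#' beginning with `#` are ignored. Member symbols are normalized and
#' deduplicated per pathway.
#'
#' @param path Path to a GMT file.
#' @param source Free-text tag recorded in the `source` column (defaults to
#'   the file name).
#' @return A tibble with columns `pathway_id`, `name`, `source` and the
#'   list-column `genes` (character vectors of unique normalized symbols).
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_annotation_collection(tibble::tibble(
      pathway_id = character(), name = character(),
      source = character(), genes = list()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    abort(sprintf("malformed GMT line(s) %s in '%s': fewer than 3 fields",
                  paste(which(n_fields < 3L), collapse = ", "), path))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate pathway_id in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tbl <- tibble::tibble(
    pathway_id = ids,
    name = vapply(fields, `[[`, character(1), 2L),
    source = source,
    genes = lapply(fields, function(f) unique(normalize_symbol(f[-(1:2)])))
  )
  new_annotation_collection(tbl)
}

#' Write an annotation collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` recovers the same
#' membership sets (member order is not significant).
#'
#' @param collection Annotation collection tibble (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- validate_annotation_collection(collection, allow_empty_members = TRUE)
  lines <- purrr::pmap_chr(
    list(collection$pathway_id, collection$name, collection$genes),
    function(id, name, genes) paste(c(id, name, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate table (gene, betweenness) from TSV
#'
#' Carrier for worked-example candidate-gene tables: tab-separated columns
#' `gene` and `betweenness` (non-negative integers), `#` comments allowed,
#' an optional header row is detected and skipped.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene` (unique normalized symbols) and
#'   `betweenness` (non-negative numbers).
#' @export
read_candidate_table <- function(path) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("no rows in '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    abort(sprintf("candidate table '%s': line(s) %s do not have 2 fields",
                  path, paste(which(lengths(fields) != 2L), collapse = ", ")))
  }
  first <- fields[[1L]]
  if (is.na(suppressWarnings(as.numeric(first[2L])))) fields <- fields[-1L]
  gene <- normalize_symbol(vapply(fields, `[[`, character(1), 1L))
  btw <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  if (anyDuplicated(gene)) {
    abort(sprintf("duplicate gene symbol(s) in '%s': %s", path,
                  paste(unique(gene[duplicated(gene)]), collapse = ", ")))
  }
  if (any(is.na(btw)) || any(btw < 0)) {
    abort(sprintf("non-numeric or negative betweenness in '%s'", path))
  }
  tibble::tibble(gene = gene, betweenness = btw)
}

#' Paths to the packaged worked-example fixtures
#'
#' The package ships plain-text transcriptions of the worked-example tables
#' of a published AMD (age-related macular degeneration) network analysis:
#' the curated 176-gene AMD seed set, the 24 enriched pathways with their
#' candidate-gene lists (GMT), and the 42-row candidate table of
#' shortest-path genes with betweenness above 1000. A fourth file, the
#' published crosstalk score table, is shipped for reference only; its
#' published rendering is corrupted and it is never used in computation.
#'
#' @param which One of `"seeds"`, `"pathways"`, `"candidates"`,
#'   `"crosstalk_scores"`.
#' @return Path to the installed fixture file.
#' @export
amd_fixture <- function(which = c("seeds", "pathways", "candidates",
                                  "crosstalk_scores")) {
  which <- match.arg(which)
  file <- switch(which,
    seeds = "amdgset_table1.txt",
    pathways = "pathways_table3.gmt",
    candidates = "candidates_table5.tsv",
    crosstalk_scores = "crosstalk_table4_scores.tsv"
  )
  path <- system.file("extdata", file, package = "amdnet")
  if (!nzchar(path)) abort(sprintf("packaged fixture '%s' not found", file))
  path
}

# -- internal ---------------------------------------------------------------

read_clean_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(trimws(lines), "#")]
}

new_annotation_collection <- function(tbl) {
  class(tbl) <- c("annotation_collection", class(tbl))
  tbl
}

validate_annotation_collection <- function(x, allow_empty_members = FALSE) {
  if (!is.data.frame(x) ||
      !all(c("pathway_id", "genes") %in% names(x))) {
    abort("an annotation collection needs columns `pathway_id` and `genes`")
  }
  if (!"name" %in% names(x)) x$name <- x$pathway_id
  if (anyDuplicated(x$pathway_id)) {
    abort("duplicate pathway_id values in annotation collection")
  }
  if (!allow_empty_members && any(lengths(x$genes) == 0L)) {
    abort("annotation collection has pathway(s) with no members")
  }
  x
}
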