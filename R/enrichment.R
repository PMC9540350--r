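# Local overrepresentation analysis: one-sided Fisher's exact test per
# annotation term with Benjamini-Hochberg FDR across terms.

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated term identifier, term
#' description, then member gene symbols. Lines with fewer than three
#' fields are skipped with a warning count; duplicate members within a set
#' are deduplicated.
#'
#' @param path GMT file path.
#' @return list of annotation sets, each a list with `term_id`, `term_name`,
#'   `member_genes`; attribute `n_skipped` counts malformed lines.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_hipnet(sprintf("GMT file not found: %s", path), "unreadable_file")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 3
  if (any(!ok)) {
    warning(sprintf("skipped %d GMT line(s) with fewer than 3 fields",
                    sum(!ok)))
  }
  sets <- lapply(parts[ok], function(p) {
    list(term_id = p[1], term_name = p[2],
         member_genes = unique(p[-(1:2)]))
  })
  attr(sets, "n_skipped") <- sum(!ok)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets annotation-set list as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$term_id, s$term_name, s$member_genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Overrepresentation analysis against a background gene list
#'
#' For each annotation term, tests whether the query gene set contains more
#' term members than expected from the background using a one-sided
#' (greater) Fisher's exact test on the 2x2 table of query/term membership
#' (the upper hypergeometric tail), then applies Benjamini-Hochberg FDR
#' correction across all tested terms. Query genes outside the background
#' are dropped before testing and reported.
#'
#' @param query_genes character vector of query gene symbols.
#' @param background_genes character vector defining the test universe
#'   (e.g. every gene in the catalog); at least two genes.
#' @param annotation_sets annotation-set list (see [read_gmt()]).
#' @return tibble sorted by ascending p-value with columns `term_id`,
#'   `term_name`, `k` (overlap), `n` (background-restricted query size),
#'   `K` (term size in background), `N` (background size),
#'   `fold_enrichment`, `p_value`, `fdr_q`; attribute `n_dropped` counts
#'   query genes outside the background.
#' @export
overrepresentation <- function(query_genes, background_genes,
                               annotation_sets) {
  background <- unique(as.character(background_genes))
  N <- length(background)
  if (N < 2) {
    stop_hipnet("background must contain at least 2 genes",
                "invalid_background")
  }
  query_in <- unique(as.character(query_genes))
  query <- intersect(query_in, background)
  n_dropped <- length(query_in) - length(query)
  if (length(query) == 0) {
    stop_hipnet("no query genes remain after background intersection",
                "empty_query", list(n_dropped = n_dropped))
  }
  n <- length(query)
  rows <- lapply(annotation_sets, function(s) {
    members <- intersect(s$member_genes, background)
    K <- length(members)
    k <- length(intersect(members, query))
    # upper tail P(X >= k) of Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K > 0) (k / n) / (K / N) else NA_real_
    tibble::tibble(term_id = s$term_id, term_name = s$term_name,
                   k = as.integer(k), n = as.integer(n), K = as.integer(K),
                   N = as.integer(N), fold_enrichment = fold, p_value = p)
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) > 0) {
    res$fdr_q <- stats::p.adjust(res$p_value, method = "BH")
    res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  } else {
    res$fdr_q <- numeric(0)
  }
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Export a query in the request shape of a remote enrichment service
#'
#' Thin adapter producing the JSON body a hosted overrepresentation service
#' expects (gene list, organism, annotation dataset, test type). Provided
#' for interoperability; never required by the local pipeline.
#'
#' @param query_genes character vector of gene symbols.
#' @param organism taxon identifier string (default human, `"9606"`).
#' @param annotation dataset label to request.
#' @return JSON string.
#' @export
export_enrichment_request <- function(query_genes, organism = "9606",
                                      annotation = "GO:0008150") {
  jsonlite::toJSON(list(geneInputList = paste(query_genes, collapse = ","),
                        organism = organism,
                        annotDataSet = annotation,
                        enrichmentTestType = "FISHER",
                        correction = "FDR"),
                   auto_unbox = TRUE)
}
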