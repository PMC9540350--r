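# Functional network construction from STRING-dialect alias/links files.

#' Load STRING-dialect edges for a set of genes
#'
#' Resolves each gene's Entrez ID to a STRING protein identifier through the
#' aliases file (any alias row whose alias equals the Entrez ID string is
#' accepted), then extracts links between resolved genes. Both directions of
#' a symmetric pair collapse to one undirected edge keeping the maximum
#' combined score; self-loops are dropped. Gzip-compressed files are read
#' transparently.
#'
#' @param aliases_file path to a `protein.aliases`-dialect file
#'   (tab-separated: string_protein_id, alias, source; optional `#` header).
#' @param links_file path to a `protein.links`-dialect file
#'   (space-separated: protein1, protein2, combined_score; header row).
#' @param genes data frame with columns `gene_symbol_human` and `entrez_id`
#'   for the query set.
#' @return tibble of edges (`gene_a`, `gene_b`, `combined_score` on the
#'   integer 0-1000 scale, `gene_a < gene_b`), with attributes
#'   `unresolved` (genes whose Entrez ID had no alias row) and
#'   `n_malformed` (skipped malformed links rows).
#' @export
load_string_edges <- function(aliases_file, links_file, genes) {
  for (f in c(aliases_file, links_file)) {
    if (!file.exists(f)) {
      stop_hipnet(sprintf("input file not found: %s", f), "unreadable_file")
    }
  }
  al_lines <- readLines(aliases_file, warn = FALSE)
  al_lines <- al_lines[nzchar(al_lines)]
  if (length(al_lines) > 0 && startsWith(al_lines[1], "#")) {
    al_lines <- al_lines[-1]
  }
  al_parts <- strsplit(al_lines, "\t", fixed = TRUE)
  al_ok <- lengths(al_parts) >= 2
  string_id <- vapply(al_parts[al_ok], `[[`, character(1), 1)
  alias <- vapply(al_parts[al_ok], `[[`, character(1), 2)

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  entrez_chr <- as.character(genes$entrez_id)
  idx <- match(entrez_chr, alias)
  resolved <- !is.na(idx) & !is.na(genes$entrez_id)
  unresolved <- genes$gene_symbol_human[!resolved]
  # STRING id -> human gene symbol for the query set only
  sid2gene <- stats::setNames(genes$gene_symbol_human[resolved],
                              string_id[idx[resolved]])

  lk_lines <- readLines(links_file, warn = FALSE)
  lk_lines <- lk_lines[nzchar(lk_lines)]
  n_malformed <- 0L
  edges <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                          combined_score = integer(0))
  if (length(lk_lines) > 1) {
    body <- lk_lines[-1]  # header row
    parts <- strsplit(body, "[ \t]+")
    ok <- lengths(parts) == 3
    score_chr <- vapply(parts, function(p) if (length(p) == 3) p[3] else NA_character_,
                        character(1))
    score <- suppressWarnings(as.integer(score_chr))
    ok <- ok & !is.na(score) & score >= 0 & score <= 1000
    n_malformed <- sum(!ok)
    if (n_malformed > 0) {
      warning(sprintf("skipped %d malformed links row(s)", n_malformed))
    }
    p1 <- vapply(parts[ok], `[[`, character(1), 1)
    p2 <- vapply(parts[ok], `[[`, character(1), 2)
    g1 <- sid2gene[p1]
    g2 <- sid2gene[p2]
    keep <- !is.na(g1) & !is.na(g2) & g1 != g2
    if (any(keep)) {
      ga <- pmin(g1[keep], g2[keep])
      gb <- pmax(g1[keep], g2[keep])
      edges <- tibble::tibble(gene_a = unname(ga), gene_b = unname(gb),
                              combined_score = score[ok][keep]) %>%
        dplyr::group_by(.data$gene_a, .data$gene_b) %>%
        dplyr::summarise(combined_score = max(.data$combined_score),
                         .groups = "drop")
    }
  }
  attr(edges, "unresolved") <- unresolved
  attr(edges, "n_malformed") <- n_malformed
  edges
}

#' Build an undirected network over a gene set
#'
#' Keeps edges between input genes whose combined score meets the threshold
#' (given on the normalized 0-1 scale and compared as
#' `combined_score >= round(1000 * threshold)`, matching the common
#' "scores >= 0.4" usage). Isolated nodes are retained: unconnected genes
#' are part of the network and are reported as such.
#'
#' @param genes character vector of gene symbols (the node set).
#' @param edges edge tibble from [load_string_edges()].
#' @param score_threshold confidence threshold in `[0, 1]`.
#' @param catalog optional catalog tibble; when given, node annotations
#'   (`entrez_id`, `is_hip`, `study_count`, `annotations`) are attached.
#' @return a `hip_network` object: list with `nodes` (tibble incl. `degree`)
#'   and `edges`, plus `unconnected` (zero-degree gene symbols).
#' @export
build_network <- function(genes, edges, score_threshold = 0.4,
                          catalog = NULL) {
  if (!is.numeric(score_threshold) || length(score_threshold) != 1 ||
      is.na(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    stop_hipnet("score_threshold must lie in [0, 1]", "invalid_threshold",
                list(score_threshold = score_threshold))
  }
  genes <- unique(as.character(genes))
  cutoff <- round(1000 * score_threshold)
  edges <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes &
                   edges$combined_score >= cutoff, , drop = FALSE]
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = sort(genes)))
  nodes <- tibble::tibble(gene_symbol_human = as.character(names(deg)),
                          degree = as.integer(deg))
  if (!is.null(catalog)) {
    idx <- match(nodes$gene_symbol_human, catalog$gene_symbol_human)
    nodes$entrez_id <- catalog$entrez_id[idx]
    nodes$is_hip <- catalog$is_hip[idx]
    nodes$study_count <- catalog$study_count[idx]
    ann <- catalog$annotations[idx]
    ann[is.na(idx)] <- list(list())
    nodes$annotations <- ann
  }
  structure(list(nodes = nodes,
                 edges = tibble::as_tibble(edges),
                 unconnected = nodes$gene_symbol_human[nodes$degree == 0],
                 score_threshold = score_threshold),
            class = "hip_network")
}

#' @export
print.hip_network <- function(x, ...) {
  cat(sprintf("<hip_network> %d nodes, %d edges (score >= %.2f), %d unconnected\n",
              nrow(x$nodes), nrow(x$edges), x$score_threshold,
              length(x$unconnected)))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param network a `hip_network`.
#' @return an undirected [igraph::graph] with `combined_score` edge weights.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes[, "gene_symbol_human"]))
}

#' Restrict a network to its most frequently reported nodes
#'
#' Keeps the `n` nodes with the highest study counts (ties broken by
#' ascending gene symbol) and the induced edges. The bait gene HTT, when
#' present, is always retained in addition.
#'
#' @param network a `hip_network` whose nodes carry `study_count`.
#' @param n positive integer number of nodes to keep.
#' @param bait bait gene symbol always retained (default `"HTT"`).
#' @return the induced `hip_network`.
#' @export
top_nodes <- function(network, n, bait = "HTT") {
  stopifnot(n >= 1)
  nodes <- network$nodes
  if (n >= nrow(nodes)) return(network)
  if (!"study_count" %in% names(nodes)) {
    stop_hipnet("network nodes carry no study_count; build with a catalog",
                "missing_annotation")
  }
  ord <- order(-nodes$study_count, nodes$gene_symbol_human)
  keep <- nodes$gene_symbol_human[ord][seq_len(n)]
  if (bait %in% nodes$gene_symbol_human && !bait %in% keep) {
    keep <- c(keep, bait)
  }
  edges <- network$edges[network$edges$gene_a %in% keep &
                           network$edges$gene_b %in% keep, , drop = FALSE]
  build_like <- build_network(keep, edges, score_threshold = 0)
  # preserve node annotations from the parent network
  idx <- match(build_like$nodes$gene_symbol_human, nodes$gene_symbol_human)
  for (col in setdiff(names(nodes), names(build_like$nodes))) {
    build_like$nodes[[col]] <- nodes[[col]][idx]
  }
  build_like$score_threshold <- network$score_threshold
  build_like
}

#' Export a network as Cytoscape-ready tab-separated files
#'
#' The nodes file has one row per node (gene symbol, Entrez ID, HIP flag,
#' study count, degree, flattened annotations); the edges file has
#' `gene_a`, `gene_b`, `combined_score`. The pair round-trips losslessly
#' through [read_network()].
#'
#' @param network a `hip_network`.
#' @param nodes_path,edges_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
export_network <- function(network, nodes_path, edges_path) {
  nodes <- network$nodes
  if ("annotations" %in% names(nodes)) {
    nodes$annotations <- vapply(nodes$annotations, flatten_annotations,
                                character(1))
  }
  write_tsv_strict(as.data.frame(nodes), nodes_path)
  write_tsv_strict(as.data.frame(network$edges), edges_path)
  invisible(list(nodes = nodes_path, edges = edges_path))
}

#' Read a network exported by [export_network()]
#'
#' @param nodes_path,edges_path paths written by [export_network()].
#' @return a `hip_network`.
#' @export
read_network <- function(nodes_path, edges_path) {
  nd <- read_tsv_strict(nodes_path)
  ed <- read_tsv_strict(edges_path)
  edges <- tibble::tibble(
    gene_a = if (nrow(ed)) ed$gene_a else character(0),
    gene_b = if (nrow(ed)) ed$gene_b else character(0),
    combined_score = if (nrow(ed)) as.integer(ed$combined_score) else integer(0))
  net <- build_network(nd$gene_symbol_human, edges, score_threshold = 0)
  if ("entrez_id" %in% names(nd)) {
    idx <- match(net$nodes$gene_symbol_human, nd$gene_symbol_human)
    net$nodes$entrez_id <- suppressWarnings(as.integer(nd$entrez_id[idx]))
    net$nodes$is_hip <- nd$is_hip[idx] == "TRUE"
    net$nodes$study_count <- as.integer(nd$study_count[idx])
    if ("annotations" %in% names(nd)) {
      net$nodes$annotations <- lapply(nd$annotations[idx],
                                      unflatten_annotations)
    }
  }
  net
}
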