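# User dataset ingestion: QUANT_-tagged annotation parsing, study
# registration, and overlap classification against the catalog.

#' Parse a user interaction dataset from TSV
#'
#' The table must carry a gene-symbol column (default name `gene_symbol`;
#' alternatives configurable). Any column whose header starts with `QUANT_`
#' becomes a per-gene annotation: the label is the header with the tag
#' stripped, and the column is
#' \itemize{
#'   \item quantitative when every non-missing value parses as a finite
#'     number (stored as numeric), or
#'   \item categorical otherwise, with values split on `","` into sets so a
#'     protein can carry several categories at once (e.g. localization to
#'     multiple compartments).
#' }
#' Missing values are the empty string and `"NA"` (case-insensitive). Rows
#' with an empty gene symbol are dropped and counted.
#'
#' @param path TSV file path.
#' @param study_id study identifier to register the dataset under.
#' @param gene_column candidate gene-symbol column names, first match wins
#'   (matched case-insensitively).
#' @return a `user_dataset`: list with `study_id`, `records` (tibble of
#'   `gene_symbol_human` + one column per annotation label), `quant_columns`
#'   (named character vector, `"quantitative"` or `"categorical"`), and
#'   `n_dropped`.
#' @export
parse_user_table <- function(path, study_id,
                             gene_column = c("gene_symbol", "gene", "symbol",
                                             "gene_symbol_human")) {
  raw <- read_tsv_strict(path)
  hit <- which(tolower(names(raw)) %in% tolower(gene_column))
  if (length(hit) == 0) {
    stop_hipnet(sprintf("no gene-symbol column found (looked for: %s)",
                        paste(gene_column, collapse = ", ")),
                "missing_column", list(columns = gene_column))
  }
  genes <- trimws(raw[[hit[1]]])
  keep <- !is_missing_token(genes)
  n_dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  genes <- genes[keep]

  quant_cols <- grep("^QUANT_", names(raw), value = TRUE)
  records <- tibble::tibble(gene_symbol_human = genes)
  kinds <- character(0)
  for (col in quant_cols) {
    label <- sub("^QUANT_", "", col)
    vals <- trimws(raw[[col]])
    present <- !is_missing_token(vals)
    num <- suppressWarnings(as.numeric(vals[present]))
    if (all(is.finite(num)) && any(present)) {
      out <- rep(NA_real_, length(vals))
      out[present] <- num
      records[[label]] <- out
      kinds[label] <- "quantitative"
    } else {
      out <- rep(list(character(0)), length(vals))
      out[present] <- lapply(strsplit(vals[present], ",", fixed = TRUE),
                             trimws)
      records[[label]] <- out
      kinds[label] <- "categorical"
    }
  }
  structure(list(study_id = study_id, records = records,
                 quant_columns = kinds, n_dropped = n_dropped),
            class = "user_dataset")
}

#' Register a user dataset as a new study
#'
#' Every record becomes a confirmed interaction observation under the
#' dataset's study identifier (metadata fields empty unless provided), the
#' catalog's study counts and HIP flags are updated, the dataset's
#' annotations are attached to the catalog, and the dataset's genes are
#' partitioned into `known` (at least one prior confirmed observation) and
#' `novel`.
#'
#' @param catalog catalog tibble (may be empty; new genes are added).
#' @param observations existing observation tibble.
#' @param dataset a `user_dataset` from [parse_user_table()].
#' @return list with updated `observations`, updated `catalog`, and
#'   `overlap` (list of `known` and `novel` gene vectors).
#' @export
integrate_study <- function(catalog, observations, dataset) {
  stopifnot(inherits(dataset, "user_dataset"))
  prior_ids <- unique(observations$study_id)
  if (dataset$study_id %in% prior_ids) {
    stop_hipnet(sprintf("study_id '%s' is already registered",
                        dataset$study_id),
                "duplicate_study", list(study_id = dataset$study_id))
  }
  genes <- unique(dataset$records$gene_symbol_human)
  prior_conf <- filter_confirmed(observations)
  known_genes <- unique(prior_conf$gene_symbol_human)
  known <- intersect(genes, known_genes)
  novel <- setdiff(genes, known_genes)

  new_obs <- tibble::tibble(
    obs_id = sprintf("%s_obs%05d", gsub("[^A-Za-z0-9]+", "_", dataset$study_id),
                     seq_along(genes)),
    gene_symbol_source = genes,
    gene_symbol_human = genes,
    entrez_id = NA_integer_,
    study_id = dataset$study_id,
    model_species = "unspecified",
    tissue = "", htt_length = "", detection_method = "",
    common_name = "", cell_culture_comment = "",
    interaction_result = "Y",
    interaction_confirmed = TRUE)
  observations <- dplyr::bind_rows(observations, new_obs)

  catalog <- rebuild_counts(catalog, filter_confirmed(observations))
  catalog <- attach_dataset_annotations(catalog, dataset)
  list(observations = observations, catalog = catalog,
       overlap = list(known = sort(known), novel = sort(novel)))
}

# Recompute study_count / is_hip from the confirmed observations while
# preserving catalog-only genes and their annotations.
rebuild_counts <- function(catalog, confirmed_observations) {
  fresh <- build_catalog(NULL, confirmed_observations)
  extra <- catalog[!catalog$gene_symbol_human %in% fresh$gene_symbol_human, ,
                   drop = FALSE]
  if (nrow(extra) > 0) {
    extra$study_count <- 0L
    extra$is_hip <- FALSE
    fresh <- dplyr::bind_rows(fresh, extra)
  }
  idx <- match(fresh$gene_symbol_human, catalog$gene_symbol_human)
  old_hit <- !is.na(idx)
  fresh$annotations[old_hit] <- catalog$annotations[idx[old_hit]]
  fresh$entrez_id[old_hit & is.na(fresh$entrez_id)] <-
    catalog$entrez_id[idx[old_hit & is.na(fresh$entrez_id)]]
  dplyr::arrange(fresh, .data$gene_symbol_human)
}

attach_dataset_annotations <- function(catalog, dataset) {
  if (length(dataset$quant_columns) == 0) return(catalog)
  rec <- dataset$records
  for (i in seq_len(nrow(rec))) {
    g <- rec$gene_symbol_human[i]
    j <- match(g, catalog$gene_symbol_human)
    if (is.na(j)) next
    ann <- catalog$annotations[[j]]
    for (label in names(dataset$quant_columns)) {
      val <- rec[[label]][[i]]
      if (length(val) == 0 || (length(val) == 1 && is.na(val))) next
      ann[[label]] <- val
    }
    catalog$annotations[[j]] <- ann
  }
  catalog
}
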