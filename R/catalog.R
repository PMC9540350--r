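# Catalog assembly: merging interaction report tables, ortholog mapping,
# confirmed-interaction filtering, and the unified gene-centric catalog.

# The prioritized per-observation metadata columns retained for filtering.
PRIORITIZED_COLUMNS <- c("model", "model_organism", "tissue", "htt_length",
                         "common_name", "cell_culture_comment",
                         "detection_method", "study_identifier")

MANDATORY_COLUMNS <- c("gene_symbol", "study_identifier", "interaction_result")

# Tuple on which literal duplicate observations are collapsed.
DEDUP_KEY <- c("gene_symbol_source", "study_id", "model_species", "tissue",
               "htt_length", "detection_method")

#' Combine the `model` and `model_organism` columns into one species label
#'
#' Interaction catalogs carry two partially redundant columns describing the
#' experimental model. They are collapsed into a single `model_species`
#' annotation: when both are present and disagree, the organism column wins
#' (it names the species; the model column often names the assay); when one
#' is empty the other passes through; when both are empty the result is
#' `"unspecified"`, never an error.
#'
#' @param model character vector, the `model` column (may be empty strings).
#' @param model_organism character vector, the `model_organism` column.
#' @return character vector of canonical species/model labels.
#' @examples
#' combine_model_columns("Mice", "Mice")            # "Mice"
#' combine_model_columns("", "Human")               # "Human"
#' combine_model_columns("Yeast two-hybrid", "Yeast") # "Yeast"
#' @export
combine_model_columns <- function(model, model_organism) {
  model <- trimws(as.character(model))
  organism <- trimws(as.character(model_organism))
  model[is.na(model)] <- ""
  organism[is.na(organism)] <- ""
  out <- ifelse(nzchar(organism), organism, model)
  out[!nzchar(out)] <- "unspecified"
  out
}

#' Merge a base interaction table with supplemental studies
#'
#' Concatenates the base catalog with any number of supplemental observation
#' tables, fills absent prioritized metadata columns with empty strings,
#' collapses the `model`/`model_organism` pair via [combine_model_columns()],
#' and deduplicates on the full metadata tuple (source gene symbol, study,
#' model species, tissue, HTT length, detection method). Observation ids are
#' assigned deterministically in input order.
#'
#' @param base_table data frame of raw observation rows. Must contain
#'   `gene_symbol`, `study_identifier` and `interaction_result`; the other
#'   prioritized metadata columns are optional and filled as `""`.
#' @param supplements list of data frames with the same contract.
#' @return a tibble of observations with columns `obs_id`,
#'   `gene_symbol_source`, `gene_symbol_human`, `entrez_id`, `study_id`,
#'   `model_species`, `tissue`, `htt_length`, `detection_method`,
#'   `common_name`, `cell_culture_comment`, `interaction_result`,
#'   `interaction_confirmed`. `gene_symbol_human` is seeded with the source
#'   symbol and finalized by [map_orthologs()].
#' @seealso [filter_confirmed()], [map_orthologs()]
#' @export
merge_ppi_catalog <- function(base_table, supplements = list()) {
  tables <- c(list(base_table), supplements)
  tables <- lapply(tables, function(tab) {
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    missing <- setdiff(MANDATORY_COLUMNS, names(tab))
    if (length(missing) > 0) {
      stop_hipnet(sprintf("mandatory column(s) missing from input table: %s",
                          paste(missing, collapse = ", ")),
                  "missing_column", list(columns = missing))
    }
    for (col in c(PRIORITIZED_COLUMNS, "entrez_id")) {
      if (!col %in% names(tab)) tab[[col]] <- ""
    }
    tab
  })
  raw <- dplyr::bind_rows(lapply(tables, function(tab) {
    tibble::tibble(
      gene_symbol_source = trimws(as.character(tab$gene_symbol)),
      entrez_id = suppressWarnings(as.integer(tab$entrez_id)),
      study_id = trimws(as.character(tab$study_identifier)),
      model_species = combine_model_columns(tab$model, tab$model_organism),
      tissue = trimws(as.character(tab$tissue)),
      htt_length = trimws(as.character(tab$htt_length)),
      detection_method = trimws(as.character(tab$detection_method)),
      common_name = trimws(as.character(tab$common_name)),
      cell_culture_comment = trimws(as.character(tab$cell_culture_comment)),
      interaction_result = as.character(tab$interaction_result)
    )
  }))
  if (any(!nzchar(raw$gene_symbol_source))) {
    stop_hipnet("empty gene symbol in input table", "missing_column",
                list(columns = "gene_symbol"))
  }
  if (any(!nzchar(raw$study_id))) {
    stop_hipnet("empty study identifier in input table", "missing_column",
                list(columns = "study_identifier"))
  }
  obs <- dplyr::distinct(raw, dplyr::across(dplyr::all_of(DEDUP_KEY)),
                         .keep_all = TRUE)
  obs$obs_id <- sprintf("obs%06d", seq_len(nrow(obs)))
  obs$gene_symbol_human <- obs$gene_symbol_source
  obs$interaction_confirmed <- trimws(obs$interaction_result) == "Y"
  obs[, c("obs_id", "gene_symbol_source", "gene_symbol_human", "entrez_id",
          "study_id", "model_species", "tissue", "htt_length",
          "detection_method", "common_name", "cell_culture_comment",
          "interaction_result", "interaction_confirmed")]
}

#' Keep only confirmed interaction observations
#'
#' An observation is confirmed when its raw interaction-result field equals
#' `"Y"` after whitespace trimming (case-sensitive). Only confirmed
#' observations participate in filtering and network construction.
#'
#' @param observations observation tibble from [merge_ppi_catalog()].
#' @return the confirmed subset of `observations`.
#' @export
filter_confirmed <- function(observations) {
  observations[trimws(observations$interaction_result) == "Y", , drop = FALSE]
}

#' Map source gene symbols to human orthologs
#'
#' Observations from human models pass through unchanged. Non-human symbols
#' are replaced by the mapped human symbol (and Entrez ID) from a static
#' ortholog table keyed on (source organism, source symbol). Non-human
#' observations with no mapping are excluded, not defaulted: the mapping
#' table is the single source of truth for orthology.
#'
#' @param observations observation tibble.
#' @param ortholog_map data frame with columns `source_organism`,
#'   `source_symbol`, `human_symbol`, `entrez_id`.
#' @return list with `observations` (mapped, unmapped rows dropped) and
#'   `excluded` (number of dropped observations).
#' @export
map_orthologs <- function(observations, ortholog_map) {
  if (nrow(observations) == 0) {
    return(list(observations = observations, excluded = 0L))
  }
  map_key <- character(0)
  if (!is.null(ortholog_map) && nrow(as.data.frame(ortholog_map)) > 0) {
    ortholog_map <- as.data.frame(ortholog_map, stringsAsFactors = FALSE)
    map_key <- paste(canon_value(ortholog_map$source_organism),
                     canon_value(ortholog_map$source_symbol), sep = "\r")
  }
  is_human <- canon_value(observations$model_species) == "human"
  obs_key <- paste(canon_value(observations$model_species),
                   canon_value(observations$gene_symbol_source), sep = "\r")
  idx <- match(obs_key, map_key)
  keep <- is_human | !is.na(idx)
  excluded <- sum(!keep)
  out <- observations[keep, , drop = FALSE]
  idx <- idx[keep]
  hit <- !is.na(idx)
  if (any(hit)) {
    out$gene_symbol_human[hit] <- as.character(ortholog_map$human_symbol[idx[hit]])
    out$entrez_id[hit] <- as.integer(ortholog_map$entrez_id[idx[hit]])
  }
  list(observations = out, excluded = excluded)
}

#' Build the unified gene-centric catalog
#'
#' Produces one record per distinct human gene appearing in either the omics
#' tables or the confirmed interaction observations. A gene is flagged as a
#' huntingtin-interacting protein (HIP) when it carries at least one
#' confirmed observation; `study_count` is the number of distinct studies
#' reporting it. Genes present only in the omics tables are retained with
#' `is_hip = FALSE` so that expression context is never lost.
#'
#' @param omics_measurements omics tibble (see [average_sexes()]); may be
#'   `NULL` or empty. Only its `gene_symbol_human` column is consulted.
#' @param confirmed_observations confirmed, ortholog-mapped observations.
#' @return a tibble with columns `gene_symbol_human`, `entrez_id`, `is_hip`,
#'   `study_count` and a list-column `annotations`.
#' @export
build_catalog <- function(omics_measurements, confirmed_observations) {
  omics_genes <- character(0)
  if (!is.null(omics_measurements) && nrow(as.data.frame(omics_measurements)) > 0) {
    omics_genes <- unique(as.character(omics_measurements$gene_symbol_human))
  }
  obs <- confirmed_observations
  per_gene <- if (!is.null(obs) && nrow(obs) > 0) {
    obs %>%
      dplyr::group_by(.data$gene_symbol_human) %>%
      dplyr::summarise(
        study_count = dplyr::n_distinct(.data$study_id),
        entrez_id = dplyr::first(.data$entrez_id[!is.na(.data$entrez_id)],
                                 default = NA_integer_),
        .groups = "drop")
  } else {
    tibble::tibble(gene_symbol_human = character(0),
                   study_count = integer(0), entrez_id = integer(0))
  }
  genes <- sort(union(omics_genes, per_gene$gene_symbol_human))
  idx <- match(genes, per_gene$gene_symbol_human)
  catalog <- tibble::tibble(
    gene_symbol_human = genes,
    entrez_id = ifelse(is.na(idx), NA_integer_, per_gene$entrez_id[idx]),
    study_count = ifelse(is.na(idx), 0L, per_gene$study_count[idx])
  )
  catalog$study_count <- as.integer(catalog$study_count)
  catalog$is_hip <- catalog$study_count >= 1L
  catalog$annotations <- rep(list(list()), nrow(catalog))
  catalog[, c("gene_symbol_human", "entrez_id", "is_hip", "study_count",
              "annotations")]
}

#' Average male and female bulk measurements
#'
#' Bulk allelic-series tables report each (gene, tissue, age, Q-length)
#' value per sex; the catalog stores the sex-averaged value. Single-sex rows
#' pass through unchanged.
#'
#' @param bulk_table data frame with columns `gene_symbol_human`, `tissue`,
#'   `age_months`, `q_length`, `sex`, `value`.
#' @return tibble keyed on (gene, tissue, age, Q) with the mean `value`.
#' @export
average_sexes <- function(bulk_table) {
  bulk_table %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$gene_symbol_human, .data$tissue, .data$age_months,
                    .data$q_length) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

#' Serialize a catalog to tab-separated text
#'
#' One row per gene; the `annotations` list-column is flattened as
#' `label=value1,value2` pairs joined with `;`.
#'
#' @param catalog catalog tibble from [build_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  flat <- catalog
  flat$annotations <- vapply(catalog$annotations, flatten_annotations,
                             character(1))
  write_tsv_strict(flat, path)
}

#' Read a catalog written by [write_catalog()]
#' @param path input file path.
#' @return catalog tibble.
#' @export
read_catalog <- function(path) {
  raw <- read_tsv_strict(path)
  tibble::tibble(
    gene_symbol_human = raw$gene_symbol_human,
    entrez_id = suppressWarnings(as.integer(raw$entrez_id)),
    is_hip = raw$is_hip == "TRUE",
    study_count = as.integer(raw$study_count),
    annotations = lapply(raw$annotations, unflatten_annotations)
  )
}
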