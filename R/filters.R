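# Interaction-level metadata filtering with per-filter AND/OR/NOT operators.

FILTERABLE_FIELDS <- c("model_species", "tissue", "htt_length",
                       "detection_method", "common_name",
                       "cell_culture_comment", "study_id")

#' Construct a metadata filter
#'
#' A filter selects interaction observations by one of the prioritized
#' metadata fields using one of three logical operators:
#' \describe{
#'   \item{OR}{keep observations whose field value is any of `values`.}
#'   \item{NOT}{drop observations whose field value is any of `values`.}
#'   \item{AND}{keep genes that have, for every selected value, at least one
#'     observation carrying that value (e.g. genes identified at least once
#'     in mice AND at least once in humans).}
#' }
#' Value matching is exact string equality after whitespace trimming and
#' case-folding; no substring matching is performed.
#'
#' @param field one of `model_species`, `tissue`, `htt_length`,
#'   `detection_method`, `common_name`, `cell_culture_comment`, `study_id`.
#' @param values non-empty character vector of values to match.
#' @param operator `"AND"`, `"OR"`, or `"NOT"`.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(field, values, operator = c("OR", "AND", "NOT")) {
  operator <- match.arg(operator)
  if (!field %in% FILTERABLE_FIELDS) {
    stop_hipnet(sprintf("'%s' is not a filterable metadata field", field),
                "invalid_field", list(field = field))
  }
  values <- as.character(values)
  if (length(values) == 0) {
    stop_hipnet("filter values must be non-empty", "empty_values")
  }
  structure(list(field = field, values = values, operator = operator),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s %s {%s}\n", x$field, x$operator,
              paste(x$values, collapse = ", ")))
  invisible(x)
}

#' Apply metadata filters to confirmed observations
#'
#' Filters are applied at the interaction level and combined across fields
#' with a logical AND. The semantics are:
#' \enumerate{
#'   \item The constrained observation set keeps every observation passing
#'     all OR-filters (value in the selected set) and all NOT-filters
#'     (value not in the selected set).
#'   \item The base gene set is every gene with at least one constrained
#'     observation.
#'   \item Each AND-filter then requires, for every one of its values, that
#'     the gene has at least one constrained observation carrying that
#'     value; the result is the base set intersected with all AND
#'     conditions.
#' }
#' An empty filter list returns every gene with a confirmed observation.
#'
#' @param observations confirmed observation tibble.
#' @param filters list of [filter_spec()] objects, at most one per field.
#' @return character vector of human gene symbols (sorted).
#' @examples
#' obs <- tibble::tibble(
#'   gene_symbol_human = c("A", "A", "B"),
#'   model_species = c("Mice", "Human", "Mice"),
#'   tissue = "brain", htt_length = "", detection_method = "",
#'   common_name = "", cell_culture_comment = "",
#'   study_id = c("S1", "S2", "S1"),
#'   interaction_result = "Y", interaction_confirmed = TRUE)
#' apply_filters(obs, list(filter_spec("model_species",
#'                                     c("Mice", "Human"), "AND")))
#' @export
apply_filters <- function(observations, filters = list()) {
  if (inherits(filters, "filter_spec")) filters <- list(filters)
  fields <- vapply(filters, function(f) f$field, character(1))
  if (anyDuplicated(fields)) {
    dup <- unique(fields[duplicated(fields)])
    stop_hipnet(sprintf("multiple filters on the same field: %s",
                        paste(dup, collapse = ", ")),
                "duplicate_field", list(fields = dup))
  }
  if (nrow(observations) == 0) return(character(0))

  keep <- rep(TRUE, nrow(observations))
  for (f in filters) {
    if (f$operator == "OR") {
      keep <- keep & canon_value(observations[[f$field]]) %in% canon_value(f$values)
    } else if (f$operator == "NOT") {
      keep <- keep & !(canon_value(observations[[f$field]]) %in% canon_value(f$values))
    }
  }
  constrained <- observations[keep, , drop = FALSE]
  genes <- unique(constrained$gene_symbol_human)

  for (f in filters) {
    if (f$operator != "AND") next
    col <- canon_value(constrained[[f$field]])
    for (v in canon_value(f$values)) {
      with_v <- unique(constrained$gene_symbol_human[col == v])
      genes <- intersect(genes, with_v)
    }
  }
  sort(genes)
}

#' Keep genes reported in at least k studies
#'
#' Uses the global (unfiltered) distinct-study count stored in the catalog,
#' so the threshold is comparable across filter settings.
#'
#' @param genes character vector of gene symbols.
#' @param catalog catalog tibble; every gene must be present.
#' @param k positive integer minimum number of distinct studies.
#' @return the subset of `genes` with `study_count >= k`.
#' @export
min_study_filter <- function(genes, catalog, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop_hipnet("k must be a positive integer", "invalid_threshold",
                list(k = k))
  }
  idx <- match(genes, catalog$gene_symbol_human)
  if (anyNA(idx)) {
    missing <- genes[is.na(idx)]
    stop_hipnet(sprintf("gene(s) absent from catalog: %s",
                        paste(utils::head(missing, 5), collapse = ", ")),
                "unknown_gene", list(genes = missing))
  }
  genes[catalog$study_count[idx] >= k]
}

#' Intersect the current gene set with a query gene list
#'
#' Matching is case-insensitive. Query symbols absent from the current set
#' are reported, not raised as errors, so exploratory lists with mixed
#' nomenclature degrade gracefully.
#'
#' @param genes character vector, the current gene set.
#' @param query_list character vector of query symbols.
#' @return list with `genes` (matched members of `genes`, original casing)
#'   and `unmatched` (query symbols with no match) plus `n_unmatched`.
#' @export
gene_list_search <- function(genes, query_list) {
  gkey <- canon_value(genes)
  qkey <- unique(canon_value(query_list))
  hit <- gkey %in% qkey
  unmatched <- unique(query_list[!canon_value(query_list) %in% gkey])
  list(genes = sort(genes[hit]),
       unmatched = unmatched,
       n_unmatched = length(unmatched))
}
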