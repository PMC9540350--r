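# Per-gene and aggregated omics views, bounding envelopes, single-cell
# highlight rules.

OMICS_MODALITIES <- c("bulk_rna", "bulk_protein", "snrna_fc", "scrna_fraction")

check_modality <- function(modality) {
  if (!is.character(modality) || length(modality) != 1 ||
      !modality %in% OMICS_MODALITIES) {
    stop_hipnet(sprintf("unknown omics modality '%s'", as.character(modality)),
                "invalid_modality", list(modality = modality))
  }
  modality
}

#' Extract the omics series for one gene
#'
#' @param omics omics tibble with columns `gene_symbol_human`, `modality`,
#'   and the index columns `tissue`, `age_months`, `q_length` (bulk) or
#'   `cell_type` (single cell), plus `value`.
#' @param gene gene symbol.
#' @param modality one of `bulk_rna`, `bulk_protein`, `snrna_fc`,
#'   `scrna_fraction`.
#' @return tibble of the gene's measurements in that modality; zero rows
#'   (not an error) when the gene has none.
#' @export
node_omics <- function(omics, gene, modality) {
  check_modality(modality)
  omics[omics$gene_symbol_human == gene & omics$modality == modality, ,
        drop = FALSE]
}

#' Aggregate an omics modality across a gene set
#'
#' For every index tuple, aggregates the per-gene values across the
#' requested genes: the median for log2-ratio modalities (`bulk_rna`,
#' `bulk_protein`, `snrna_fc`; the median is a central tendency that log
#' ratios support, a sum is not) and the sum for `scrna_fraction`
#' (cumulative expression mass across the node set). Genes with no value at
#' a tuple are skipped for that tuple.
#'
#' @param omics omics tibble.
#' @param genes non-empty character vector of gene symbols.
#' @param modality modality name.
#' @param stat `"auto"` (default assignment above), `"median"`, or `"sum"`.
#' @return tibble of aggregated values indexed like the input, with an
#'   `n_genes` column counting contributing genes per tuple.
#' @export
aggregate_omics <- function(omics, genes, modality, stat = "auto") {
  check_modality(modality)
  if (length(genes) == 0) {
    stop_hipnet("gene set must be non-empty", "empty_genes")
  }
  if (stat == "auto") {
    stat <- if (modality == "scrna_fraction") "sum" else "median"
  }
  if (!stat %in% c("median", "sum")) {
    stop_hipnet(sprintf("unknown aggregation statistic '%s'", stat),
                "invalid_statistic")
  }
  agg_fun <- if (stat == "median") stats::median else sum
  sub <- omics[omics$gene_symbol_human %in% genes &
                 omics$modality == modality, , drop = FALSE]
  index_cols <- intersect(c("tissue", "age_months", "q_length", "cell_type"),
                          names(sub))
  sub %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(index_cols))) %>%
    dplyr::summarise(value = agg_fun(.data$value),
                     n_genes = dplyr::n_distinct(.data$gene_symbol_human),
                     .groups = "drop")
}

#' Central 90% bounding envelope of a value set
#'
#' Returns the 5th and 95th percentiles by linear interpolation between
#' closest order statistics ([stats::quantile()] type 7), so a point
#' outside the returned bounds lies in the upper or lower 5% of the data.
#'
#' @param values numeric vector with at least one finite value.
#' @return named numeric vector `c(lower = q05, upper = q95)`.
#' @export
bounding_envelope <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop_hipnet("bounding_envelope requires at least one value", "empty_values")
  }
  q <- stats::quantile(values, probs = c(0.05, 0.95), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Highlight single-nucleus fold changes per cell type
#'
#' Classifies each cell type's log2(disease/control) fold change as `up`
#' when `value >= threshold`, `down` when `value <= -threshold`, otherwise
#' `none`. The default threshold 0.15 on the log2 scale corresponds to a
#' change greater than 10% in either direction (2^0.15 - 1 ~ 11%).
#'
#' @param series `snrna_fc` omics tibble with `cell_type` and `value`.
#' @param threshold non-negative log2 fold-change threshold (default 0.15).
#' @return tibble with `cell_type`, `value`, and `highlight` in
#'   `{"up", "down", "none"}`.
#' @export
highlight_snrna <- function(series, threshold = 0.15) {
  if (nrow(series) > 0 && !all(series$modality == "snrna_fc")) {
    stop_hipnet("highlight_snrna expects an snrna_fc series",
                "invalid_modality")
  }
  tibble::tibble(
    cell_type = series$cell_type,
    value = series$value,
    highlight = ifelse(series$value >= threshold, "up",
                       ifelse(series$value <= -threshold, "down", "none")))
}

#' Highlight broadly expressed genes in single-cell fractions
#'
#' Flags cell types in which the expressed-cell fraction meets the
#' threshold (default 0.8: at least 80% of analyzed single cells express
#' the gene).
#'
#' @param series `scrna_fraction` omics tibble with `cell_type` and `value`
#'   in `[0, 1]`.
#' @param threshold fraction threshold in `[0, 1]` (default 0.8, inclusive).
#' @return tibble with `cell_type`, `value`, and logical `highlight`.
#' @export
highlight_scrna <- function(series, threshold = 0.8) {
  if (nrow(series) > 0 && !all(series$modality == "scrna_fraction")) {
    stop_hipnet("highlight_scrna expects an scrna_fraction series",
                "invalid_modality")
  }
  if (any(series$value < 0 | series$value > 1, na.rm = TRUE)) {
    stop_hipnet("scrna_fraction values must lie in [0, 1]", "invalid_value")
  }
  tibble::tibble(cell_type = series$cell_type,
                 value = series$value,
                 highlight = series$value >= threshold)
}
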