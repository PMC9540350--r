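# Seeded synthetic generators for every input the pipeline consumes:
# interaction catalogs, STRING-dialect edge files, allelic-series omics,
# and spiked IP-MS designs with known ground truth.

#' Specification for the synthetic fixture generators
#'
#' Bundles every tunable of the generators with a single seed so identical
#' specifications produce byte-identical outputs. Defaults emulate the
#' study conditions of a cortex IP-MS comparison in a polyQ allelic-series
#' design: four sample groups (Q20/Q140 crossed with 2/10 months), three
#' biological replicates, 4-fold interaction spikes, and log2-scale noise
#' of 0.2.
#'
#' @param seed integer random seed.
#' @param n_genes genes in the interaction catalog.
#' @param n_studies distinct study identifiers.
#' @param n_observations interaction observations to draw.
#' @param species,tissues,htt_lengths,methods metadata vocabularies.
#' @param confirm_prob probability an observation is confirmed (`"Y"`).
#' @param edge_prob STRING edge probability between gene pairs.
#' @param alias_missing_frac fraction of genes with no alias row.
#' @param omics_slope_sd spread of per-gene polyQ slopes (log2 units across
#'   the full Q range).
#' @param omics_noise_sd Gaussian noise on bulk log2 values.
#' @param cell_types striatal cell-type labels for single-cell modalities.
#' @param n_proteins,n_spiked IP-MS matrix size and number of proteins
#'   spiked in the Q140 groups.
#' @param spike_log2fc log2 fold change of spiked proteins (default 2,
#'   i.e. 4-fold).
#' @param noise_sd_log2 replicate noise on log2 abundances (default 0.2).
#' @param n_replicates biological replicates per sample group (default 3).
#' @param saint_true_range,saint_decoy_range SAINT score ranges for true
#'   interactors and decoys.
#' @param stable_frac fraction of proteins in the stable isotope class.
#' @param stability_noise_sd noise on generated stability ratios.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 20220301L,
                         n_genes = 60L,
                         n_studies = 8L,
                         n_observations = 400L,
                         species = c("Human", "Mice", "Rat", "Yeast"),
                         tissues = c("brain", "striatum", "cerebral cortex",
                                     "cerebellum", "liver"),
                         htt_lengths = c("full-length", "fragment", "exon1"),
                         methods = c("affinity purification", "yeast two-hybrid",
                                     "co-immunoprecipitation"),
                         confirm_prob = 0.85,
                         edge_prob = 0.1,
                         alias_missing_frac = 0.1,
                         omics_slope_sd = 0.5,
                         omics_noise_sd = 0.1,
                         cell_types = c("MSN D1", "MSN D2", "astrocyte",
                                        "oligodendrocyte", "interneuron",
                                        "microglia"),
                         n_proteins = 200L,
                         n_spiked = 20L,
                         spike_log2fc = 2,
                         noise_sd_log2 = 0.2,
                         n_replicates = 3L,
                         saint_true_range = c(0.85, 1),
                         saint_decoy_range = c(0, 0.5),
                         stable_frac = 0.3,
                         stability_noise_sd = 0.02) {
  spec <- as.list(environment())
  spec$seed <- as.integer(seed)
  structure(spec, class = "fixture_spec")
}

fixture_genes <- function(spec) {
  tibble::tibble(
    gene_symbol_human = sprintf("GENE%04d", seq_len(spec$n_genes)),
    entrez_id = 100000L + seq_len(spec$n_genes))
}

#' Generate a synthetic interaction catalog file
#'
#' Writes a tab-separated table in the curated-catalog dialect (columns
#' `gene_symbol`, `model`, `model_organism`, `tissue`, `htt_length`,
#' `common_name`, `cell_culture_comment`, `detection_method`,
#' `study_identifier`, `interaction_result`, `entrez_id`) and returns the
#' ground-truth answer sets needed to check the filter engine, computed
#' from the drawn rows before writing.
#'
#' @param spec a [fixture_spec()].
#' @param path output TSV path.
#' @return list with `path`, `table` (the raw rows), and `manifest`:
#'   `genes_confirmed` (all genes with a confirmed row), `by_value`
#'   (field -> value -> confirmed gene set), and `species_tissue`
#'   (named `"species|tissue"` -> genes with a confirmed row carrying both).
#' @export
sim_ppi_catalog <- function(spec, path) {
  set.seed(spec$seed + 1L)
  genes <- fixture_genes(spec)
  studies <- sprintf("STUDY_%02d", seq_len(spec$n_studies))
  n <- spec$n_observations
  gi <- sample.int(spec$n_genes, n, replace = TRUE)
  tab <- data.frame(
    gene_symbol = genes$gene_symbol_human[gi],
    entrez_id = genes$entrez_id[gi],
    model = sample(c("", "knock-in", "transgenic"), n, replace = TRUE),
    model_organism = sample(spec$species, n, replace = TRUE),
    tissue = sample(spec$tissues, n, replace = TRUE),
    htt_length = sample(spec$htt_lengths, n, replace = TRUE),
    common_name = "",
    cell_culture_comment = "",
    detection_method = sample(spec$methods, n, replace = TRUE),
    study_identifier = sample(studies, n, replace = TRUE),
    interaction_result = ifelse(stats::runif(n) < spec$confirm_prob, "Y", "N"),
    stringsAsFactors = FALSE)
  conf <- tab[tab$interaction_result == "Y", , drop = FALSE]
  by_value <- list()
  for (field in c("model_organism", "tissue", "htt_length",
                  "detection_method", "study_identifier")) {
    by_value[[field]] <- lapply(
      stats::setNames(nm = sort(unique(conf[[field]]))),
      function(v) sort(unique(conf$gene_symbol[conf[[field]] == v])))
  }
  st <- split(conf$gene_symbol, paste(conf$model_organism, conf$tissue,
                                      sep = "|"))
  manifest <- list(
    genes_confirmed = sort(unique(conf$gene_symbol)),
    by_value = by_value,
    species_tissue = lapply(st, function(g) sort(unique(g))))
  write_tsv_strict(tab, path)
  list(path = path, table = tab, manifest = manifest)
}

#' Generate STRING-dialect alias and links files
#'
#' Draws an Erdos-Renyi graph over the fixture genes with integer combined
#' scores in `[150, 999]`, writes both directions of every edge to a
#' space-separated links file, and writes a tab-separated aliases file
#' mapping synthetic STRING protein identifiers to Entrez IDs. A held-out
#' fraction of genes receives no alias row so unresolved-identifier
#' handling is exercised.
#'
#' @param spec a [fixture_spec()].
#' @param genes gene table (`gene_symbol_human`, `entrez_id`), e.g. from
#'   the catalog generator.
#' @param aliases_path,links_path output paths.
#' @return list with the two paths, `aliased` (gene symbols that received
#'   an alias), and `manifest` edge tibble (`gene_a`, `gene_b`,
#'   `combined_score`, `gene_a < gene_b`, aliased genes only).
#' @export
sim_string_files <- function(spec, genes, aliases_path, links_path) {
  set.seed(spec$seed + 2L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  ng <- nrow(genes)
  string_ids <- sprintf("9606.SYNP%05d", seq_len(ng))
  n_missing <- floor(spec$alias_missing_frac * ng)
  missing_idx <- if (n_missing > 0) sample.int(ng, n_missing) else integer(0)
  has_alias <- setdiff(seq_len(ng), missing_idx)
  aliases <- data.frame(
    string_protein_id = string_ids[has_alias],
    alias = as.character(genes$entrez_id[has_alias]),
    source = "Ensembl_UniProt_entrez",
    stringsAsFactors = FALSE)
  writeLines(c("#string_protein_id\talias\tsource",
               sprintf("%s\t%s\t%s", aliases$string_protein_id,
                       aliases$alias, aliases$source)),
             aliases_path)

  pairs <- which(upper.tri(matrix(TRUE, ng, ng)), arr.ind = TRUE)
  present <- stats::runif(nrow(pairs)) < spec$edge_prob
  pairs <- pairs[present, , drop = FALSE]
  scores <- if (nrow(pairs) > 0) {
    sample(150:999, nrow(pairs), replace = TRUE)
  } else integer(0)
  lines <- c("protein1 protein2 combined_score")
  if (nrow(pairs) > 0) {
    lines <- c(lines,
               sprintf("%s %s %d", string_ids[pairs[, 1]],
                       string_ids[pairs[, 2]], scores),
               sprintf("%s %s %d", string_ids[pairs[, 2]],
                       string_ids[pairs[, 1]], scores))
  }
  writeLines(lines, links_path)

  both_aliased <- pairs[, 1] %in% has_alias & pairs[, 2] %in% has_alias
  ga <- genes$gene_symbol_human[pairs[both_aliased, 1]]
  gb <- genes$gene_symbol_human[pairs[both_aliased, 2]]
  manifest <- tibble::tibble(
    gene_a = pmin(ga, gb), gene_b = pmax(ga, gb),
    combined_score = as.integer(scores[both_aliased])) %>%
    dplyr::arrange(.data$gene_a, .data$gene_b)
  list(aliases_path = aliases_path, links_path = links_path,
       aliased = genes$gene_symbol_human[has_alias], manifest = manifest)
}

#' Generate allelic-series omics tables
#'
#' Bulk RNA and protein log2 ratios follow a per-gene linear trend in
#' polyQ length, `value = slope_g * (Q - 20) / 155 + noise`, over the
#' tissue panel, ages 2/6/10 months (no 2-month point for Q50, as in the
#' allelic-series design) and Q lengths 50-175. Single-nucleus fold
#' changes are drawn around per-cell-type means and single-cell expression
#' fractions from a Beta distribution.
#'
#' @param spec a [fixture_spec()].
#' @param genes gene table (`gene_symbol_human`).
#' @return list with `omics` (long tibble across all four modalities) and
#'   `manifest` (`slopes` per gene, `snrna_means` per cell type).
#' @export
sim_omics <- function(spec, genes) {
  set.seed(spec$seed + 3L)
  gsym <- genes$gene_symbol_human
  slopes <- stats::setNames(stats::rnorm(length(gsym), 0, spec$omics_slope_sd),
                            gsym)
  qs <- c(50, 80, 92, 111, 140, 175)
  grid <- expand.grid(gene_symbol_human = gsym, tissue = spec$tissues,
                      age_months = c(2, 6, 10), q_length = qs,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$q_length == 50 & grid$age_months == 2), , drop = FALSE]
  bulk <- function(modality) {
    tibble::tibble(
      gene_symbol_human = grid$gene_symbol_human,
      modality = modality,
      tissue = grid$tissue,
      age_months = grid$age_months,
      q_length = grid$q_length,
      cell_type = NA_character_,
      value = unname(slopes[grid$gene_symbol_human]) *
        (grid$q_length - 20) / 155 +
        stats::rnorm(nrow(grid), 0, spec$omics_noise_sd))
  }
  snrna_means <- stats::setNames(
    stats::rnorm(length(spec$cell_types), 0, 0.2), spec$cell_types)
  sc_grid <- expand.grid(gene_symbol_human = gsym,
                         cell_type = spec$cell_types,
                         stringsAsFactors = FALSE)
  snrna <- tibble::tibble(
    gene_symbol_human = sc_grid$gene_symbol_human,
    modality = "snrna_fc", tissue = "striatum",
    age_months = NA_real_, q_length = NA_real_,
    cell_type = sc_grid$cell_type,
    value = unname(snrna_means[sc_grid$cell_type]) +
      stats::rnorm(nrow(sc_grid), 0, spec$omics_noise_sd))
  scrna <- tibble::tibble(
    gene_symbol_human = sc_grid$gene_symbol_human,
    modality = "scrna_fraction", tissue = "striatum",
    age_months = NA_real_, q_length = NA_real_,
    cell_type = sc_grid$cell_type,
    value = stats::rbeta(nrow(sc_grid), 2, 2))
  omics <- dplyr::bind_rows(bulk("bulk_rna"), bulk("bulk_protein"),
                            snrna, scrna)
  list(omics = omics,
       manifest = list(slopes = slopes, snrna_means = snrna_means))
}

#' Generate a spiked IP-MS experiment with known ground truth
#'
#' Emulates the four-group design Q20/Q140 crossed with 2/10 months, each
#' with `n_replicates` biological replicates. Protein abundances are
#' log-normal around per-protein baselines; spiked proteins carry
#' `spike_log2fc` extra log2 units in both Q140 groups; every sample also
#' carries a bait-capture factor that the bait row (`Htt`) tracks exactly,
#' so bait normalization removes it. SAINT scores are drawn high for true
#' interactors and low for decoys; light/heavy isotope intensities realize
#' the assigned stability class (stable near 1, fast-exchanging near 0.5).
#'
#' @param spec a [fixture_spec()].
#' @return list with `abundance` (matrix incl. the `Htt` bait row),
#'   `groups` (per-column group labels), `saint` (long tibble: protein,
#'   group, replicate, score), `isotopes` (protein, light, heavy), and
#'   `truth` (per-protein tibble: spiked, specific, stability_class,
#'   true_ratio).
#' @export
sim_ipms <- function(spec) {
  set.seed(spec$seed + 4L)
  groups4 <- c("Q20-2M", "Q140-2M", "Q20-10M", "Q140-10M")
  cols <- as.vector(vapply(groups4, function(g)
    sprintf("%s_R%d", g, seq_len(spec$n_replicates)),
    character(spec$n_replicates)))
  col_groups <- rep(groups4, each = spec$n_replicates)
  proteins <- sprintf("PROT%04d", seq_len(spec$n_proteins))
  spiked <- proteins[seq_len(spec$n_spiked)]
  # true interactors: all spiked proteins plus the first half of the rest
  n_true_extra <- floor((spec$n_proteins - spec$n_spiked) / 2)
  specific <- c(spiked,
                proteins[spec$n_spiked + seq_len(n_true_extra)])
  base_log2 <- stats::runif(spec$n_proteins, 18, 26)
  is_q140 <- grepl("^Q140", col_groups)
  bait_factor <- 2^stats::rnorm(length(cols), 0, 0.3)
  log2mat <- matrix(base_log2, nrow = spec$n_proteins, ncol = length(cols))
  log2mat[proteins %in% spiked, is_q140] <-
    log2mat[proteins %in% spiked, is_q140] + spec$spike_log2fc
  log2mat <- log2mat + matrix(stats::rnorm(length(log2mat), 0,
                                           spec$noise_sd_log2),
                              nrow = spec$n_proteins)
  abundance <- 2^log2mat * rep(bait_factor, each = spec$n_proteins)
  rownames(abundance) <- proteins
  colnames(abundance) <- cols
  bait_base <- 2^24
  abundance <- rbind(abundance,
                     Htt = bait_base * bait_factor)

  saint <- expand.grid(protein = proteins, group = groups4,
                       replicate = seq_len(spec$n_replicates),
                       stringsAsFactors = FALSE)
  is_true <- saint$protein %in% specific
  saint$score <- ifelse(
    is_true,
    stats::runif(nrow(saint), spec$saint_true_range[1], spec$saint_true_range[2]),
    stats::runif(nrow(saint), spec$saint_decoy_range[1], spec$saint_decoy_range[2]))
  saint <- tibble::as_tibble(saint)

  n_stable <- floor(spec$stable_frac * spec$n_proteins)
  stability_class <- rep("exchanging", spec$n_proteins)
  stability_class[sample.int(spec$n_proteins, n_stable)] <- "stable"
  true_ratio <- ifelse(stability_class == "stable", 1.0, 0.5)
  obs_ratio <- pmin(1, pmax(
    0.01, true_ratio + ifelse(stability_class == "stable",
                              -abs(stats::rnorm(spec$n_proteins, 0,
                                                spec$stability_noise_sd)),
                              stats::rnorm(spec$n_proteins, 0,
                                           spec$stability_noise_sd))))
  total <- 2^stats::runif(spec$n_proteins, 16, 22)
  isotopes <- tibble::tibble(
    protein = proteins,
    light = total * obs_ratio,
    heavy = total * (1 - obs_ratio))

  truth <- tibble::tibble(
    protein = proteins,
    spiked = proteins %in% spiked,
    spike_log2fc = ifelse(proteins %in% spiked, spec$spike_log2fc, 0),
    specific = proteins %in% specific,
    stability_class = stability_class,
    true_ratio = true_ratio)
  list(abundance = abundance, groups = col_groups, saint = saint,
       isotopes = isotopes, truth = truth)
}

#' Write the IP-MS fixture tables as TSV files
#'
#' @param ipms result of [sim_ipms()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_ipms_fixture <- function(ipms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- data.frame(protein = rownames(ipms$abundance),
                   ipms$abundance, check.names = FALSE)
  paths <- list(
    abundance = file.path(dir, "abundance.tsv"),
    saint = file.path(dir, "saint.tsv"),
    isotopes = file.path(dir, "isotopes.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_tsv_strict(ab, paths$abundance)
  write_tsv_strict(as.data.frame(ipms$saint), paths$saint)
  write_tsv_strict(as.data.frame(ipms$isotopes), paths$isotopes)
  write_tsv_strict(as.data.frame(ipms$truth), paths$truth)
  paths
}
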