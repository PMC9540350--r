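# Shared fixture builders and independent oracles used across test files.

# Build an observation tibble (already merged/mapped shape) with defaults.
make_obs <- function(gene, study = "S1", species = "Human", tissue = "",
                     htt = "", method = "", result = "Y") {
  n <- max(lengths(list(gene, study, species, tissue, htt, method, result)))
  tibble::tibble(
    obs_id = sprintf("o%04d", seq_len(n)),
    gene_symbol_source = rep_len(gene, n),
    gene_symbol_human = rep_len(gene, n),
    entrez_id = NA_integer_,
    study_id = rep_len(study, n),
    model_species = rep_len(species, n),
    tissue = rep_len(tissue, n),
    htt_length = rep_len(htt, n),
    detection_method = rep_len(method, n),
    common_name = "",
    cell_culture_comment = "",
    interaction_result = rep_len(result, n),
    interaction_confirmed = rep_len(result, n) == "Y")
}

# Raw interaction table in the input dialect of merge_ppi_catalog().
make_raw_table <- function(gene, study = "S1", model = "", organism = "Human",
                           tissue = "", htt = "", method = "", result = "Y") {
  n <- max(lengths(list(gene, study, model, organism, tissue, htt, method,
                        result)))
  data.frame(gene_symbol = rep_len(gene, n),
             model = rep_len(model, n),
             model_organism = rep_len(organism, n),
             tissue = rep_len(tissue, n),
             htt_length = rep_len(htt, n),
             detection_method = rep_len(method, n),
             study_identifier = rep_len(study, n),
             interaction_result = rep_len(result, n),
             stringsAsFactors = FALSE)
}

# Independent filter oracle: plain nested-loop set algebra over the
# observation rows, written without reference to apply_filters().
oracle_filter <- function(obs, filters) {
  canon <- function(x) tolower(trimws(x))
  constrained <- rep(TRUE, nrow(obs))
  for (f in filters) {
    vals <- canon(f$values)
    for (i in seq_len(nrow(obs))) {
      v <- canon(obs[[f$field]][i])
      if (f$operator == "OR" && !(v %in% vals)) constrained[i] <- FALSE
      if (f$operator == "NOT" && (v %in% vals)) constrained[i] <- FALSE
    }
  }
  sub <- obs[constrained, , drop = FALSE]
  genes <- unique(sub$gene_symbol_human)
  for (f in filters) {
    if (f$operator != "AND") next
    for (v in canon(f$values)) {
      keep <- character(0)
      for (g in genes) {
        rows <- sub[sub$gene_symbol_human == g, , drop = FALSE]
        if (any(canon(rows[[f$field]]) == v)) keep <- c(keep, g)
      }
      genes <- intersect(genes, keep)
    }
  }
  sort(genes)
}

# Independent hypergeometric upper-tail oracle via log-binomial
# coefficients: P(X >= k) for X ~ Hypergeom(N, K, n).
oracle_hyper_tail <- function(N, K, n, k) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Random confirmed-observation fixture of a given size.
random_obs_fixture <- function(n, seed) {
  set.seed(seed)
  make_obs(
    gene = sprintf("G%03d", sample.int(80, n, replace = TRUE)),
    study = sprintf("S%02d", sample.int(10, n, replace = TRUE)),
    species = sample(c("Human", "Mice", "Rat", "Yeast"), n, replace = TRUE),
    tissue = sample(c("brain", "striatum", "cortex", "liver"), n,
                    replace = TRUE),
    htt = sample(c("full-length", "fragment"), n, replace = TRUE),
    method = sample(c("AP", "Y2H", "coIP"), n, replace = TRUE))
}
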