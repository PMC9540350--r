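# Downstream IP-MS computations: SAINT specificity aggregation, bait
# normalization, quantified-protein filtering, min-CV replicate selection,
# differential interaction calling, isotope stability ratios, and the
# specific & stable quadrant assignment.

#' Aggregate SAINT scores into a specificity call
#'
#' For one protein in one IP sample group, averages the two highest SAINT
#' scores across replicates; the interaction is specific when the average
#' meets the threshold (inclusive, default 0.8).
#'
#' @param scores numeric vector of SAINT scores in `[0, 1]`, length >= 2.
#' @param threshold specificity threshold (default 0.8).
#' @return list with `avg_top2` and logical `specific`.
#' @export
saint_specificity <- function(scores, threshold = 0.8) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) {
    stop_hipnet("saint_specificity requires at least 2 scores",
                "too_few_scores", list(n = length(scores)))
  }
  if (any(scores < 0 | scores > 1)) {
    stop_hipnet("SAINT scores must lie in [0, 1]", "invalid_value")
  }
  top2 <- sort(scores, decreasing = TRUE)[1:2]
  avg <- mean(top2)
  list(avg_top2 = avg, specific = avg >= threshold)
}

#' Normalize an abundance matrix to the bait protein
#'
#' Divides every protein's abundance in each sample by the bait's abundance
#' in that sample, then rescales by the across-sample mean bait abundance
#' so the bait row becomes constant and the original abundance units are
#' preserved. This makes interaction levels comparable across IPs that
#' captured different amounts of bait.
#'
#' @param abundance_matrix numeric matrix, rows = proteins (rownames),
#'   columns = samples; `NA` marks unquantified values.
#' @param bait_gene rowname of the bait protein (e.g. `"Htt"`); must be
#'   quantified and positive in every sample.
#' @return the normalized matrix (same dimnames).
#' @export
normalize_to_bait <- function(abundance_matrix, bait_gene) {
  if (!bait_gene %in% rownames(abundance_matrix)) {
    stop_hipnet(sprintf("bait '%s' not found in abundance matrix", bait_gene),
                "missing_bait")
  }
  bait <- abundance_matrix[bait_gene, ]
  bad <- which(is.na(bait) | bait <= 0)
  if (length(bad) > 0) {
    samples <- colnames(abundance_matrix)[bad]
    if (is.null(samples)) samples <- as.character(bad)
    stop_hipnet(sprintf("bait missing or non-positive in sample(s): %s",
                        paste(samples, collapse = ", ")),
                "invalid_bait", list(samples = samples))
  }
  sweep(abundance_matrix, 2, bait, "/") * mean(bait)
}

#' Keep proteins quantified in at least one sample group
#'
#' Retains proteins with at least `min_values` non-missing replicate
#' abundances within at least one sample group.
#'
#' @param abundance_matrix numeric matrix (proteins x samples).
#' @param groups character/factor of length `ncol(abundance_matrix)`
#'   assigning each sample column to a group.
#' @param min_values minimum non-missing values per group (default 2).
#' @return the retained submatrix.
#' @export
filter_quantified <- function(abundance_matrix, groups, min_values = 2) {
  stopifnot(length(groups) == ncol(abundance_matrix))
  groups <- as.character(groups)
  keep <- vapply(seq_len(nrow(abundance_matrix)), function(i) {
    counts <- tapply(!is.na(abundance_matrix[i, ]), groups, sum)
    any(counts >= min_values)
  }, logical(1))
  abundance_matrix[keep, , drop = FALSE]
}

#' Select the replicates minimizing the coefficient of variation
#'
#' Within each sample group, evaluates every size-`keep` subset of
#' replicates: per subset, the per-protein CV (sd/mean over replicate
#' abundances, proteins fully quantified in the subset only) is aggregated
#' by its median, and the subset with minimal aggregate CV is selected.
#' Ties break by the lexicographically first replicate combination.
#'
#' @param abundance_matrix numeric matrix (proteins x samples).
#' @param groups group assignment per column (see [filter_quantified()]).
#' @param keep replicates to retain per group (default 2).
#' @return named list: per group, the character vector of selected sample
#'   column names.
#' @export
select_replicates_min_cv <- function(abundance_matrix, groups, keep = 2) {
  stopifnot(length(groups) == ncol(abundance_matrix))
  groups <- as.character(groups)
  cols <- colnames(abundance_matrix)
  if (is.null(cols)) cols <- as.character(seq_len(ncol(abundance_matrix)))
  out <- list()
  for (g in unique(groups)) {
    members <- sort(cols[groups == g])
    if (length(members) < keep) {
      stop_hipnet(sprintf("group '%s' has fewer than %d replicates", g, keep),
                  "too_few_replicates", list(group = g))
    }
    subsets <- utils::combn(members, keep, simplify = FALSE)
    agg <- vapply(subsets, function(ss) {
      sub <- abundance_matrix[, ss, drop = FALSE]
      complete <- stats::complete.cases(sub)
      if (!any(complete)) return(NA_real_)
      cv <- apply(sub[complete, , drop = FALSE], 1,
                  function(x) stats::sd(x) / mean(x))
      stats::median(cv)
    }, numeric(1))
    if (all(is.na(agg))) {
      stop_hipnet(sprintf("no protein fully quantified in any replicate subset of group '%s'", g),
                  "no_complete_protein", list(group = g))
    }
    out[[g]] <- subsets[[which.min(agg)]]  # which.min skips NA, first-min tie-break
  }
  out
}

#' Call differential interactions between two sample groups
#'
#' Per protein: `log2fc = log2(mean_b / mean_a)` on (bait-normalized)
#' abundances, a two-sided two-sample Student's t-test (equal variance) on
#' log2 abundances, and a differential call when `|log2fc| >= fc_threshold`
#' and `p < alpha`. Proteins without at least two non-missing values in
#' each group are reported as untested.
#'
#' @param abundance_matrix numeric matrix (proteins x samples), normalized.
#' @param groups group assignment per column.
#' @param group_a,group_b the two group labels to compare (fold change is
#'   b over a, e.g. a = Q20 control, b = Q140).
#' @param fc_threshold absolute log2 fold-change threshold (default 1,
#'   inclusive).
#' @param alpha p-value threshold (default 0.05, strict).
#' @return tibble with `protein`, `mean_a`, `mean_b`, `log2fc`, `p_value`,
#'   `tested`, `call`.
#' @export
differential_interactions <- function(abundance_matrix, groups, group_a,
                                      group_b, fc_threshold = 1.0,
                                      alpha = 0.05) {
  groups <- as.character(groups)
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) {
      stop_hipnet(sprintf("group '%s' not present in column groups", g),
                  "unknown_group", list(group = g))
    }
  }
  a_cols <- which(groups == group_a)
  b_cols <- which(groups == group_b)
  proteins <- rownames(abundance_matrix)
  if (is.null(proteins)) proteins <- as.character(seq_len(nrow(abundance_matrix)))
  rows <- lapply(seq_len(nrow(abundance_matrix)), function(i) {
    xa <- abundance_matrix[i, a_cols]
    xb <- abundance_matrix[i, b_cols]
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      return(tibble::tibble(protein = proteins[i], mean_a = NA_real_,
                            mean_b = NA_real_, log2fc = NA_real_,
                            p_value = NA_real_, tested = FALSE, call = FALSE))
    }
    ma <- mean(xa); mb <- mean(xb)
    l2fc <- log2(mb / ma)
    la <- log2(xa); lb <- log2(xb)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else {
      p <- stats::t.test(lb, la, var.equal = TRUE)$p.value
    }
    tibble::tibble(protein = proteins[i], mean_a = ma, mean_b = mb,
                   log2fc = l2fc, p_value = p, tested = TRUE,
                   call = abs(l2fc) >= fc_threshold & p < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Stable-isotope interaction stability ratio
#'
#' For an interactor quantified in its light (endogenous) and heavy
#' (isotope-labeled reference) forms after a mixed-lysate IP, returns
#' `light / (light + heavy)`. Ratios near 1 indicate little in-solution
#' exchange (a stable interaction); ratios near 0.5 indicate fast exchange
#' with the reference pool (a transient association).
#'
#' @param light,heavy non-negative intensities (vectorized; equal length).
#' @return numeric vector of stability ratios in `(0, 1]`.
#' @export
stability_ratio <- function(light, heavy) {
  if (any(light < 0 | heavy < 0, na.rm = TRUE)) {
    stop_hipnet("intensities must be non-negative", "invalid_value")
  }
  tot <- light + heavy
  if (any(tot == 0, na.rm = TRUE)) {
    stop_hipnet("light + heavy must be positive", "invalid_value")
  }
  light / tot
}

#' Assign specific & stable quadrant classes
#'
#' Classifies interactors on the (SAINT specificity, stability ratio)
#' plane: `specific_stable` in the upper-right quadrant
#' (`saint_avg >= saint_threshold` and `stability >= stability_threshold`),
#' `specific_only`, `stable_only`, or `neither` otherwise. A missing
#' stability ratio yields a specificity-only class with
#' `stability_missing = TRUE`.
#'
#' @param saint_avg numeric vector of averaged-top-two SAINT scores.
#' @param stability numeric vector of stability ratios (`NA` allowed).
#' @param saint_threshold specificity threshold in `[0, 1]` (default 0.8).
#' @param stability_threshold stability threshold, required, in `(0.5, 1)`:
#'   between the fast-exchange anchor 0.5 and the fully stable anchor 1.
#' @return tibble with `saint_avg`, `stability`, `class`,
#'   `stability_missing`.
#' @export
assign_specific_stable <- function(saint_avg, stability,
                                   saint_threshold = 0.8,
                                   stability_threshold) {
  if (!is.numeric(stability_threshold) || length(stability_threshold) != 1 ||
      is.na(stability_threshold) ||
      stability_threshold <= 0.5 || stability_threshold >= 1.0) {
    stop_hipnet("stability_threshold must lie in (0.5, 1.0)",
                "invalid_threshold", list(stability_threshold = stability_threshold))
  }
  if (!is.numeric(saint_threshold) || saint_threshold < 0 || saint_threshold > 1) {
    stop_hipnet("saint_threshold must lie in [0, 1]", "invalid_threshold")
  }
  spec <- saint_avg >= saint_threshold
  stab <- !is.na(stability) & stability >= stability_threshold
  cls <- ifelse(spec & stab, "specific_stable",
                ifelse(spec, "specific_only",
                       ifelse(stab, "stable_only", "neither")))
  tibble::tibble(saint_avg = saint_avg, stability = stability, class = cls,
                 stability_missing = is.na(stability))
}

#' Partition named gene sets into Venn regions
#'
#' Counts, for 2-4 named sets, the members of every non-empty membership
#' region (element in exactly that subset of sets). Counts sum to the
#' cardinality of the union.
#'
#' @param named_sets named list of 2-4 character vectors.
#' @return named integer vector; region names join set labels with `"&"`.
#' @export
venn_partition <- function(named_sets) {
  m <- length(named_sets)
  if (m < 2 || m > 4) {
    stop_hipnet("venn_partition supports 2 to 4 sets", "invalid_set_count",
                list(m = m))
  }
  labels <- names(named_sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop_hipnet("sets must have unique non-empty names", "invalid_set_names")
  }
  sets <- lapply(named_sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  regions <- list()
  for (size in seq_len(m)) {
    for (combo in utils::combn(m, size, simplify = FALSE)) {
      name <- paste(labels[combo], collapse = "&")
      inside <- rowSums(membership[, combo, drop = FALSE]) == size
      outside <- if (size < m) {
        rowSums(membership[, -combo, drop = FALSE]) == 0
      } else TRUE
      regions[[name]] <- sum(inside & outside)
    }
  }
  out <- unlist(regions)
  storage.mode(out) <- "integer"
  out
}
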