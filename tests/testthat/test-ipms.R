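test_that("SAINT specificity averages the two highest scores, inclusive", {
  expect_equal(saint_specificity(c(1.0, 1.0, 0.0)),
               list(avg_top2 = 1.0, specific = TRUE))
  # (0.9 + 0.7) / 2 = 0.8 is exactly at the inclusive boundary
  r <- saint_specificity(c(0.9, 0.7, 0.1))
  expect_equal(r$avg_top2, 0.8)
  expect_true(r$specific)
  expect_error(saint_specificity(0.9),
               class = "hipnet_error_too_few_scores")
  expect_error(saint_specificity(c(0.5, 1.2)),
               class = "hipnet_error_invalid_value")
  # random score lists match a sort-and-mean oracle
  set.seed(23)
  for (i in 1:20) {
    s <- runif(sample(2:6, 1))
    expect_equal(saint_specificity(s)$avg_top2,
                 mean(rev(sort(s))[1:2]))
  }
})

test_that("bait normalization equalizes capture and preserves units", {
  m <- rbind(P1 = c(10, 20), Htt = c(2, 4))
  colnames(m) <- c("s1", "s2")
  norm <- normalize_to_bait(m, "Htt")
  expect_equal(unname(norm["P1", ]), c(15, 15))
  expect_equal(unname(norm["Htt", ]), c(3, 3))        # bait row constant
  # bait equal in all samples: identity
  m2 <- rbind(P1 = c(7, 9), Htt = c(5, 5))
  expect_equal(normalize_to_bait(m2, "Htt"), m2)
  # missing or non-positive bait errors, naming the sample
  m3 <- rbind(P1 = c(1, 1), Htt = c(2, NA))
  colnames(m3) <- c("s1", "s2")
  err <- expect_error(normalize_to_bait(m3, "Htt"),
                      class = "hipnet_error_invalid_bait")
  expect_match(conditionMessage(err), "s2")
  expect_error(normalize_to_bait(m, "NotThere"),
               class = "hipnet_error_missing_bait")
})

test_that("quantified-protein filter requires a complete-enough group", {
  groups <- c("A", "A", "A", "B", "B", "B")
  m <- rbind(
    full_one_group = c(1, 2, 3, NA, NA, NA),
    one_per_group = c(1, NA, NA, 2, NA, NA),
    two_in_b = c(NA, NA, NA, 1, 2, NA))
  kept <- filter_quantified(m, groups, min_values = 2)
  expect_setequal(rownames(kept), c("full_one_group", "two_in_b"))
  # random missingness equals the comprehension oracle
  set.seed(4)
  rm <- matrix(runif(60), nrow = 10)
  rm[sample(60, 25)] <- NA
  rownames(rm) <- sprintf("p%02d", 1:10)
  kept <- filter_quantified(rm, groups, 2)
  oracle <- vapply(seq_len(10), function(i) {
    any(tapply(!is.na(rm[i, ]), groups, sum) >= 2)
  }, logical(1))
  expect_setequal(rownames(kept), rownames(rm)[oracle])
})

test_that("replicate selection minimizes the aggregate CV", {
  # replicates 1 and 2 identical, 3 an outlier on every protein
  m <- cbind(R1 = c(10, 20, 30), R2 = c(10, 20, 30), R3 = c(50, 5, 90))
  rownames(m) <- c("p1", "p2", "p3")
  sel <- select_replicates_min_cv(m, groups = rep("G", 3), keep = 2)
  expect_equal(sel$G, c("R1", "R2"))
  # keep = group size is the identity
  sel_all <- select_replicates_min_cv(m, rep("G", 3), keep = 3)
  expect_equal(sel_all$G, c("R1", "R2", "R3"))
  # random values equal the exhaustive C(3,2) oracle
  set.seed(14)
  rm <- matrix(rlnorm(30), nrow = 10,
               dimnames = list(sprintf("p%02d", 1:10), c("A", "B", "C")))
  sel <- select_replicates_min_cv(rm, rep("G", 3), keep = 2)
  combos <- combn(c("A", "B", "C"), 2, simplify = FALSE)
  aggs <- vapply(combos, function(cc) {
    median(apply(rm[, cc], 1, function(x) sd(x) / mean(x)))
  }, numeric(1))
  expect_equal(sel$G, combos[[which.min(aggs)]])
})

test_that("differential calls combine fold change and Student's t", {
  groups <- c(rep("Q20", 3), rep("Q140", 3))
  m <- rbind(flat = c(100, 100, 100, 100, 100, 100),
             fourfold = c(100, 100, 100, 400, 400, 400))
  res <- differential_interactions(m, groups, "Q20", "Q140")
  flat <- res[res$protein == "flat", ]
  expect_equal(flat$log2fc, 0)
  expect_false(flat$call)
  expect_equal(flat$p_value, 1)     # degenerate equal groups, no exception
  four <- res[res$protein == "fourfold", ]
  expect_equal(four$log2fc, 2)
  expect_true(four$call)

  # untested proteins are reported, not dropped
  m2 <- rbind(sparse = c(5, NA, NA, 7, 8, 9))
  res2 <- differential_interactions(m2, groups, "Q20", "Q140")
  expect_false(res2$tested)
  expect_true(is.na(res2$p_value))
})

test_that("t-test p-values match the textbook equal-variance formula", {
  set.seed(33)
  groups <- c(rep("A", 3), rep("B", 3))
  m <- matrix(2^(rnorm(60, 20, 1)), nrow = 10,
              dimnames = list(sprintf("p%02d", 1:10), NULL))
  res <- differential_interactions(m, groups, "A", "B")
  for (i in 1:10) {
    la <- log2(m[i, 1:3]); lb <- log2(m[i, 4:6])
    sp <- sqrt(((3 - 1) * var(la) + (3 - 1) * var(lb)) / (3 + 3 - 2))
    tstat <- (mean(lb) - mean(la)) / (sp * sqrt(1 / 3 + 1 / 3))
    p_oracle <- 2 * pt(-abs(tstat), df = 4)
    expect_equal(res$p_value[i], p_oracle, tolerance = 1e-12)
  }
  # antisymmetry: swapping groups negates log2fc, preserves p
  rev_res <- differential_interactions(m, groups, "B", "A")
  expect_equal(rev_res$log2fc, -res$log2fc)
  expect_equal(rev_res$p_value, res$p_value)
})

test_that("stability ratios hit the anchors and are scale-invariant", {
  expect_equal(stability_ratio(1000, 1000), 0.5)  # fast-exchange anchor
  expect_equal(stability_ratio(500, 0), 1.0)      # fully stable limit
  expect_equal(stability_ratio(1, 3), 0.25)
  # scale invariance
  set.seed(6)
  l <- runif(20, 1, 100); h <- runif(20, 1, 100)
  expect_equal(stability_ratio(7.3 * l, 7.3 * h), stability_ratio(l, h))
  expect_error(stability_ratio(0, 0), class = "hipnet_error_invalid_value")
  expect_error(stability_ratio(-1, 2), class = "hipnet_error_invalid_value")
})

test_that("specific & stable quadrants classify on both thresholds", {
  r <- assign_specific_stable(c(1.0, 0.0, 0.9, 0.1),
                              c(1.0, 0.5, 0.6, 0.9),
                              stability_threshold = 0.75)
  expect_equal(r$class, c("specific_stable", "neither",
                          "specific_only", "stable_only"))
  # missing stability falls back to specificity only and is flagged
  miss <- assign_specific_stable(c(0.9, 0.1), c(NA, NA),
                                 stability_threshold = 0.75)
  expect_equal(miss$class, c("specific_only", "neither"))
  expect_true(all(miss$stability_missing))
  expect_error(assign_specific_stable(0.9, 0.9, stability_threshold = 0.4),
               class = "hipnet_error_invalid_threshold")
  expect_error(assign_specific_stable(0.9, 0.9, stability_threshold = 1.0),
               class = "hipnet_error_invalid_threshold")
  # randomized grid equals the two-threshold comprehension oracle
  set.seed(19)
  sa <- runif(100); st <- runif(100)
  rr <- assign_specific_stable(sa, st, 0.8, 0.75)
  oracle <- ifelse(sa >= 0.8 & st >= 0.75, "specific_stable",
                   ifelse(sa >= 0.8, "specific_only",
                          ifelse(st >= 0.75, "stable_only", "neither")))
  expect_equal(rr$class, oracle)
})

test_that("Venn partitions count every membership region exactly", {
  two <- venn_partition(list(A = c("x", "y"), B = c("p", "q", "r")))
  expect_equal(two[["A"]], 2L)
  expect_equal(two[["B"]], 3L)
  expect_equal(two[["A&B"]], 0L)
  same <- venn_partition(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(same[["A&B"]], 4L)
  expect_equal(same[["A"]] + same[["B"]], 0L)
  expect_error(venn_partition(list(A = "x")),
               class = "hipnet_error_invalid_set_count")
  expect_error(venn_partition(setNames(rep(list("x"), 5), letters[1:5])),
               class = "hipnet_error_invalid_set_count")

  # random sets: region counts equal brute-force membership enumeration
  set.seed(27)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- c("W", "X", "Y", "Z")
  part <- venn_partition(sets)
  expect_equal(sum(part), length(unique(unlist(sets))))   # conservation
  for (el in unique(unlist(sets))) {
    region <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                       logical(1))], collapse = "&")
    expect_true(part[[region]] >= 1)
  }
  oracle_ab <- sum(vapply(unique(unlist(sets)), function(el) {
    el %in% sets$W && el %in% sets$X && !el %in% sets$Y && !el %in% sets$Z
  }, logical(1)))
  expect_equal(part[["W&X"]], oracle_ab)
})
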