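string_fixture <- function(dir, aliases, links) {
  ap <- file.path(dir, "aliases.txt")
  lp <- file.path(dir, "links.txt")
  writeLines(c("#string_protein_id\talias\tsource", aliases), ap)
  writeLines(c("protein1 protein2 combined_score", links), lp)
  list(aliases = ap, links = lp)
}

test_that("symmetric link pairs collapse to one undirected edge", {
  dir <- withr::local_tempdir()
  fx <- string_fixture(dir,
    aliases = c("9606.P1\t101\tentrez", "9606.P2\t102\tentrez",
                "9606.P3\t103\tentrez"),
    links = c("9606.P1 9606.P2 700", "9606.P2 9606.P1 700"))
  genes <- data.frame(gene_symbol_human = c("A", "B", "C"),
                      entrez_id = 101:103)
  edges <- load_string_edges(fx$aliases, fx$links, genes)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$gene_a, "A")
  expect_equal(edges$gene_b, "B")
  expect_equal(edges$combined_score, 700L)
})

test_that("genes without alias rows are counted unresolved", {
  dir <- withr::local_tempdir()
  fx <- string_fixture(dir,
    aliases = "9606.P1\t101\tentrez",
    links = "9606.P1 9606.P9 500")
  genes <- data.frame(gene_symbol_human = c("A", "B"), entrez_id = 101:102)
  edges <- load_string_edges(fx$aliases, fx$links, genes)
  expect_equal(nrow(edges), 0)
  expect_equal(attr(edges, "unresolved"), "B")
})

test_that("malformed links rows are skipped with a warning count", {
  dir <- withr::local_tempdir()
  fx <- string_fixture(dir,
    aliases = c("9606.P1\t101\tentrez", "9606.P2\t102\tentrez"),
    links = c("9606.P1 9606.P2 700", "9606.P1 9606.P2 notanumber",
              "9606.P1 9606.P2"))
  genes <- data.frame(gene_symbol_human = c("A", "B"), entrez_id = 101:102)
  expect_warning(edges <- load_string_edges(fx$aliases, fx$links, genes),
                 "malformed")
  expect_equal(attr(edges, "n_malformed"), 2L)
  expect_equal(nrow(edges), 1)
  expect_error(load_string_edges("/nonexistent", fx$links, genes),
               class = "hipnet_error_unreadable_file")
})

test_that("loaded edges equal the generator manifest and input symmetry", {
  spec <- fixture_spec(seed = 5, n_genes = 40, edge_prob = 0.15)
  dir <- withr::local_tempdir()
  genes <- data.frame(gene_symbol_human = sprintf("GENE%04d", 1:40),
                      entrez_id = 100001:100040)
  st <- sim_string_files(spec, genes, file.path(dir, "a.txt"),
                         file.path(dir, "l.txt"))
  edges <- load_string_edges(st$aliases_path, st$links_path, genes)
  edges <- dplyr::arrange(edges, gene_a, gene_b)
  expect_equal(edges$gene_a, st$manifest$gene_a)
  expect_equal(edges$gene_b, st$manifest$gene_b)
  expect_equal(edges$combined_score, st$manifest$combined_score)
  expect_true(all(edges$gene_a < edges$gene_b))
})

test_that("score threshold is applied on the 0-1 scale and is monotone", {
  edges <- tibble::tibble(gene_a = c("A", "A", "B"),
                          gene_b = c("B", "C", "C"),
                          combined_score = c(400L, 399L, 999L))
  genes <- c("A", "B", "C", "D")
  net0 <- build_network(genes, edges, 0)
  expect_equal(nrow(net0$edges), 3)
  net04 <- build_network(genes, edges, 0.4)
  expect_equal(nrow(net04$edges), 2)   # 399 falls below round(1000 * 0.4)
  net1 <- build_network(genes, edges, 1.0)
  expect_equal(nrow(net1$edges), 0)
  expect_setequal(net1$unconnected, genes)
  expect_error(build_network(genes, edges, 1.5),
               class = "hipnet_error_invalid_threshold")
  # monotone: raising the threshold never adds edges
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(t) nrow(build_network(genes, edges, t)$edges),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degrees and unconnected nodes match a brute-force count", {
  set.seed(31)
  genes <- sprintf("N%02d", 1:10)
  pairs <- t(combn(genes, 2))
  present <- runif(nrow(pairs)) < 0.3
  edges <- tibble::tibble(gene_a = pairs[present, 1],
                          gene_b = pairs[present, 2],
                          combined_score = sample(150:999, sum(present),
                                                  replace = TRUE))
  thr <- 0.5
  net <- build_network(genes, edges, thr)
  cutoff <- round(1000 * thr)
  for (g in genes) {
    oracle_deg <- sum((edges$gene_a == g | edges$gene_b == g) &
                        edges$combined_score >= cutoff)
    expect_equal(net$nodes$degree[net$nodes$gene_symbol_human == g],
                 oracle_deg)
  }
  expect_setequal(net$unconnected,
                  net$nodes$gene_symbol_human[net$nodes$degree == 0])
})

test_that("top_nodes keeps highest study counts with symbol tie-break and bait", {
  obs <- dplyr::bind_rows(
    make_obs(rep("A", 5), study = sprintf("S%d", 1:5)),
    make_obs(rep("B", 2), study = sprintf("S%d", 1:2)),
    make_obs(rep("C", 2), study = sprintf("S%d", 1:2)),
    make_obs("D"), make_obs("HTT", study = "S9"))
  catalog <- build_catalog(NULL, obs)
  edges <- tibble::tibble(gene_a = "A", gene_b = "B", combined_score = 900L)
  net <- build_network(c("A", "B", "C", "D"), edges, 0.4, catalog)
  top2 <- top_nodes(net, 2)
  expect_setequal(top2$nodes$gene_symbol_human, c("A", "B"))  # tie B < C
  expect_identical(top_nodes(net, 10), net)                    # n >= |nodes|

  net_bait <- build_network(c("A", "B", "HTT"), edges, 0.4, catalog)
  top1 <- top_nodes(net_bait, 1)
  expect_true("HTT" %in% top1$nodes$gene_symbol_human)
  expect_true("A" %in% top1$nodes$gene_symbol_human)
})

test_that("network export round-trips through the reader", {
  obs <- make_obs(c("A", "B"), study = c("S1", "S2"))
  catalog <- build_catalog(NULL, obs)
  edges <- tibble::tibble(gene_a = "A", gene_b = "B", combined_score = 812L)
  net <- build_network(c("A", "B", "C"), edges, 0.4, catalog)
  dir <- withr::local_tempdir()
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  export_network(net, np, ep)
  expect_equal(length(readLines(np)), 4)  # header + 3 nodes
  expect_equal(length(readLines(ep)), 2)  # header + 1 edge
  back <- read_network(np, ep)
  expect_equal(back$nodes$gene_symbol_human, net$nodes$gene_symbol_human)
  expect_equal(back$nodes$degree, net$nodes$degree)
  expect_equal(back$nodes$study_count, net$nodes$study_count)
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))

  # empty network exports header-only files
  empty <- build_network(character(0),
                         edges[0, , drop = FALSE], 0.4)
  export_network(empty, np, ep)
  expect_equal(length(readLines(np)), 1)
  expect_equal(length(readLines(ep)), 1)
})
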