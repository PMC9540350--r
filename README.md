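# hipnet

Huntington's disease is caused by a CAG-repeat (polyglutamine, "polyQ")
expansion in the huntingtin gene (*HTT*). Hundreds of studies have reported
huntingtin-interacting proteins (HIPs) across wildly different experimental
contexts — organisms, tissues, HTT fragment lengths, detection methods —
and alongside them sit rich multi-omics resources from polyQ allelic-series
mouse models. `hipnet` is a headless R toolkit for integrating, filtering,
and scoring this evidence. It is written for computational biologists
studying protein-interaction rewiring in neurodegeneration who need the
analysis steps scriptable and reproducible rather than behind a dashboard.

## What it does

* **Catalog assembly** — merges tab-separated interaction report tables,
  collapses the redundant `model`/`model_organism` columns into one
  `model_species` label, maps non-human symbols to human orthologs through
  a static mapping table, keeps only confirmed reports (`"Y"` in the
  interaction-result column), and builds a gene-centric catalog with a HIP
  flag and a distinct-study count per gene.
* **Metadata filtering** — interaction-level filters over the prioritized
  metadata fields with three operators. For a field *F* with selected
  values *V*: OR keeps observations with *F* ∈ *V*; NOT drops them; AND
  keeps genes that have, for every *v* ∈ *V*, at least one observation
  with *F* = *v*. Filters on different fields always combine by AND.
  Minimum-study filtering and case-insensitive gene-list search compose
  with these.
* **Network construction** — resolves Entrez IDs through STRING-dialect
  `protein.aliases` files, loads `protein.links` edges, collapses symmetric
  pairs (keeping the maximum combined score), thresholds at
  `combined_score ≥ round(1000·t)` for a user threshold *t* ∈ [0,1], keeps
  isolated nodes, and exports Cytoscape-ready node/edge TSVs.
* **Omics overlay** — per-gene and set-aggregated views of bulk RNA/protein
  log2 ratios (median aggregation), snRNA-seq fold changes and scRNA
  expression fractions (sum aggregation); central 90% bounding envelopes
  (5th/95th percentiles); highlight rules |log2FC| ≥ 0.15 (snRNA) and
  fraction ≥ 0.8 (scRNA).
* **Enrichment** — one-sided Fisher's exact overrepresentation of a query
  set against a background over GMT gene sets,
  p = P(X ≥ k), X ~ Hypergeom(N, K, n), with Benjamini–Hochberg FDR.
* **User datasets** — TSV upload with `QUANT_`-tagged annotation columns
  (all-numeric ⇒ quantitative, otherwise categorical with comma-separated
  multi-values), registration as a new study, and known/novel overlap
  classification against the catalog.
* **IP-MS scoring** — the downstream computations for immunoaffinity
  purification mass spectrometry of HTT complexes: average of the two
  highest SAINT scores per group with an inclusive 0.8 specificity
  threshold; bait (Htt) normalization; ≥2-quantified-values group filter;
  replicate selection minimizing the median per-protein CV; differential
  calls with |log2(Q140/Q20)| ≥ 1 and Student's-t p < 0.05; stable-isotope
  stability ratios light/(light+heavy) (≈1 stable, ≈0.5 fast-exchanging);
  specific & stable quadrant assignment; and Venn partitioning of
  assignment sets across tissues and polyQ lengths.
* **Synthetic fixtures** — seeded generators for every input above
  (interaction tables, STRING files, allelic-series omics, spiked IP-MS
  designs with truth manifests), so the full pipeline runs and tests
  offline.

## Worked example

```r
library(hipnet)

spec <- fixture_spec(seed = 1, n_genes = 30, n_observations = 200)
ppi  <- sim_ppi_catalog(spec, tempfile(fileext = ".tsv"))
obs  <- filter_confirmed(merge_ppi_catalog(ppi$table))
catalog <- build_catalog(NULL, obs)
catalog
#> # A tibble: 30 x 5
#>   gene_symbol_human entrez_id is_hip study_count annotations
#> 1 GENE0001             100001 TRUE             5 <list [0]>
#> 2 GENE0002             100002 TRUE             3 <list [0]>
#> 3 GENE0003             100003 TRUE             5 <list [0]>

# genes seen at least once in mice AND at least once in humans,
# with at least one brain or striatum observation
genes <- apply_filters(obs, list(
  filter_spec("model_species", c("Mice", "Human"), "AND"),
  filter_spec("tissue", c("brain", "striatum"), "OR")))
length(genes)
#> [1] 8

genes2 <- min_study_filter(genes, catalog, k = 2)
st    <- sim_string_files(spec, catalog, tempfile(), tempfile())
edges <- load_string_edges(st$aliases_path, st$links_path, catalog)
build_network(genes2, edges, score_threshold = 0.4, catalog = catalog)
#> <hip_network> 8 nodes, 2 edges (score >= 0.40), 4 unconnected

stability_ratio(1000, 1000)   # equal light/heavy: fast-exchange anchor
#> [1] 0.5
stability_ratio(900, 100)     # mostly light: stable interaction
#> [1] 0.9
```

The catalog lists every gene with its HIP status and how many distinct
studies reported it; the filtered network keeps unconnected genes as
isolated nodes (they are still HIPs — they just lack functional edges at
this confidence). The stability ratio reads light-isotope fraction: 0.5
means the endogenous interactor exchanged freely with the heavy-labeled
reference pool during the IP, 0.9 means it mostly stayed bait-bound.

A shell entry point wrapping the same functions ships in
`inst/cli/hipnet.R` (after install: `Rscript <library>/hipnet/cli/hipnet.R
<subcommand> --config run.yaml`); subcommands are `simulate`, `build-db`,
`filter`, `network`, `omics`, `enrich`, `upload`, `ipms`, each writing a
run manifest alongside its outputs.

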