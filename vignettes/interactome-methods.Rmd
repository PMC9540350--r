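---
title: "Models and methods behind hipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hipnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipnet)
```

`hipnet` integrates three kinds of evidence about huntingtin (HTT)
protein interactions — curated literature reports with experimental
metadata, multi-omics measurements from polyQ allelic-series mouse models,
and quantitative IP-MS experiments — into one filterable, scriptable
analysis surface. This vignette explains the procedures, the parameters
that matter, and the choices made where more than one defensible design
existed.

## The catalog model

The unit of literature evidence is the *observation*: one report of one
interaction in one experimental context, carrying the prioritized metadata
columns `model_species`, `tissue`, `htt_length`, `detection_method`,
`common_name`, `cell_culture_comment`, and `study_id`. Curated interaction
tables carry two partially redundant columns for the experimental model;
we collapse them with an *organism-wins* rule: when `model` and
`model_organism` disagree, the organism column is kept, because it names
the species while the model column frequently names the assay
("Yeast two-hybrid"). Both empty yields `"unspecified"`, never an error —
missing metadata should restrict filters, not crash pipelines.

Duplicate observations are collapsed on the full tuple (source symbol,
study, model species, tissue, HTT length, detection method). This
preserves genuinely repeated detections — the same gene found by two
methods, or in two tissues, within one study — while removing literal
re-entries. A coarser key (say, gene × study) would silently discard the
metadata diversity the filter engine exists to query.

Non-human gene symbols are mapped to human orthologs through a static
table keyed on (source organism, source symbol). Orthology services return
version-dependent answers; freezing the mapping as an input table is the
only way two runs of the pipeline can agree. A non-human symbol without an
entry is excluded and counted, not passed through: an unmapped symbol in a
human-centric catalog would be a silent identity error.

The catalog keys genes on the human symbol, carrying the Entrez ID as an
attribute. A gene is a HIP (huntingtin-interacting protein) when at least
one *confirmed* observation reports it — confirmation meaning the raw
interaction-result field equals `"Y"` after whitespace trimming,
case-sensitively, since curated tables use `"N"` and free-text comments in
the same column. `study_count` counts distinct studies, not observations:
"reported in k studies" is the reproducibility notion a minimum-study
filter should threshold, and it is invariant to how many rows a prolific
study contributed.

## Filter semantics

Filters act at the interaction level, with at most one filter per field,
and different fields always combine by AND. The normative semantics:

1. OR- and NOT-filters constrain the observation set: an observation
   survives if its value is in the OR set for every OR-filter and outside
   the value set of every NOT-filter.
2. The base gene set is every gene with a surviving observation.
3. Each AND-filter imposes a *per-value existence* condition on genes:
   for every selected value, the gene must have at least one surviving
   observation carrying that value.

Two consequences are worth spelling out. "Mice OR-filter plus brain
OR-filter" requires a *single* observation that is simultaneously mouse
and brain — evidence of the interaction in mouse brain — not one mouse
observation and one brain observation. "Mice+Human AND-filter" requires
independent mouse and human detections, which may be different
observations. The AND conditions are evaluated inside the constrained set,
the strictest reading consistent with both behaviors; a looser reading
(AND conditions on the unconstrained observations) would let a NOT-filter
be bypassed by the very observations it excluded.

Value matching is exact equality after trimming and case-folding. Fuzzy or
substring matching would make filter results depend on vocabulary
accidents ("brain" matching "hindbrain") and was rejected.

One use case in the field filters for interactions "identified only with
full-length HTT". We implement this as inclusion (`htt_length =
full-length`), not as exclusion of genes also seen with fragments; the
stricter exclusion semantics is expressible by adding a NOT-filter, so
nothing is lost, and inclusion is what the operator named.

## Network construction

Edges come from STRING-dialect files: an aliases file resolving Entrez IDs
to STRING protein identifiers (any alias row whose alias equals the Entrez
string is accepted — alias `source` tags vary across releases and carry no
information we rely on) and a links file of directed scored pairs. Scores
stay on STRING's integer 0–1000 scale; the user threshold *t* ∈ [0,1] is
applied as `combined_score ≥ round(1000·t)`, so the conventional
"medium confidence 0.4" cut is exactly 400. Symmetric duplicates collapse
keeping the maximum score, and isolated nodes are retained — an
unconnected HIP is a finding (no functional neighbors at this confidence),
not an artifact to drop.

## Omics overlay

Bulk allelic-series values are sex-averaged log2 ratios versus the Q20
control, indexed by tissue, age (2/6/10 months) and Q length
(50–175). Aggregating across a gene set uses the **median** for log2-ratio
modalities — a sum of log ratios is not a central tendency — and the
**sum** for scRNA expressed-cell fractions, where cumulative expression
mass across a node set is the quantity of interest. The assignment is
overridable per call because the choice is a convention, not a theorem.

The 90% bounding envelope is the (5th, 95th) percentile pair computed by
linear interpolation between order statistics (`stats::quantile` type 7).
The envelope population is all genes sharing (modality, tissue, age,
Q length) — the per-panel reading: an envelope pooled across ages would
mix maturation effects into the polyQ comparison. The percentile method is
fixed and documented because envelope membership at the boundary depends
on it.

Highlight rules are inclusive at their thresholds: snRNA |log2(Q175/WT)| ≥
0.15 (a fold change of 2^0.15 − 1 ≈ 11%, i.e. anything highlighted moved
by more than 10%) and scRNA fraction ≥ 0.8.

## Overrepresentation

Enrichment of a query set against a background uses the one-sided
hypergeometric tail — for a term with K background members, query size n,
background N and overlap k, p = P(X ≥ k) — computed via
`stats::phyper`, with Benjamini–Hochberg FDR across all tested terms.
BH is the standard FDR procedure and the one meant when tools say "FDR
correction" without qualification. Query genes outside the background are
dropped and counted before testing; testing a gene the background cannot
produce would inflate every term. The test suite checks the tail against
an independent log-binomial-coefficient enumeration over every table with
N ≤ 60. Annotation sets travel as GMT files so no network access is ever
needed; a thin adapter exports queries in the request shape of hosted
enrichment services but is never exercised by the pipeline.

## User datasets and study registration

An uploaded TSV becomes a new *study*: each row a confirmed observation
under the dataset's study identifier, with metadata fields empty unless
provided. Columns tagged `QUANT_` become annotations; a column is
quantitative iff every non-missing value parses as a finite number,
otherwise categorical with comma-separated multi-values (a protein
localized to nucleus and cytoplasm keeps both). The all-numeric rule is
the only inference that never misclassifies a numeric column, at the cost
of demoting columns with stray text — the safer failure. Overlap
classification (known vs novel) is computed against the catalog *before*
registration, and registering the same study identifier twice is an error:
study identifiers are the keys study-filters and partitions rely on.

## IP-MS scoring

The quantitative pipeline mirrors a label-free + metabolic-labeling IP-MS
design with four sample groups (Q20/Q140 × 2/10 months), three biological
replicates each:

* **Specificity.** Per protein and group, the two highest SAINT scores are
  averaged; the interaction is specific when the average is at least 0.8
  (inclusive — the threshold is described as "at least").
* **Bait normalization.** Abundances are divided by the bait (Htt) level
  per sample, then rescaled by the mean bait level so units are preserved
  and the bait row becomes exactly constant. A missing or zero bait value
  is an error naming the sample — imputing the normalizer would corrupt
  every protein in that sample.
* **Quantified filter.** A protein is retained with ≥2 non-missing
  replicate values in at least one sample group.
* **Replicate selection.** Within each group, every size-2 replicate
  subset is scored by the median per-protein CV (sd/mean over proteins
  complete in the subset) and the minimizer is kept, ties to the
  lexicographically first pair. The median was chosen as the aggregate
  because a handful of high-CV proteins should not veto an otherwise
  tight pair; this aggregation choice is ours.
* **Differential calls.** log2 fold change of group means on normalized
  abundances; two-sided two-sample Student's t (equal variance, the
  classical test, not Welch) on log2 abundances; call =
  |log2FC| ≥ 1 and p < 0.05. The fold-change threshold is inclusive and
  configurable. A protein with zero variance in both groups and equal
  means gets p = 1 and no call rather than an exception. The fold change
  here is the group-mean ratio of bait-normalized abundances; vendor
  pipelines compute a per-peptide "protein ratio" internally, which is
  not reproducible outside the vendor tool, so the documented group-mean
  ratio is used throughout.
* **Stability.** With light (endogenous) and heavy (labeled reference)
  intensities from a 1:1 mixed-lysate IP, the stability ratio is
  light/(light+heavy): 1.0 means no in-solution exchange, 0.5 means full
  equilibration with the reference pool. The ratio is scale-invariant, so
  absolute intensity calibration cancels.
* **Specific & stable.** Upper-right-quadrant assignment on the
  (SAINT average, stability) plane. The specificity threshold is 0.8; the
  stability threshold has no canonical published value, so it is a
  required configuration parameter constrained to (0.5, 1.0) — between
  the fast-exchange and fully-stable anchors — with 0.75, the midpoint,
  suggested. It is echoed into every output so downstream readers can see
  which quadrant definition produced a table.
* **Venn partitions.** Assignment sets across tissues and polyQ lengths
  are compared by exhaustive membership regions for 2–4 sets (the
  displayable range); counts always sum to the union size.

## The synthetic generators

The generators exist so the full pipeline is exercisable without any
versioned external resource, and their defaults *are* the emulated study
conditions:

* interaction catalogs over configurable metadata vocabularies with an
  85% confirmation rate, plus a truth manifest of answer sets recomputed
  from the drawn rows (tests verify manifests by re-scanning the emitted
  files, which catches format bugs the in-memory path would hide);
* STRING files with Erdős–Rényi edges, integer scores uniform on
  [150, 999], both directions written, and 10% of genes held out of the
  aliases file to exercise unresolved-identifier handling;
* bulk omics values linear in Q length — slope·(Q − 20)/155 + Gaussian
  noise (σ = 0.1) — over the tissue panel with no 2-month point at Q50,
  matching the allelic-series design; snRNA fold changes around
  per-cell-type means; scRNA fractions Beta(2, 2);
* IP-MS matrices with 200 proteins, 20 spiked at +2 log2 units (4-fold)
  in both Q140 groups, replicate noise σ(log2) = 0.2, n = 3 per group, a
  per-sample bait-capture factor that the bait row tracks exactly, SAINT
  scores uniform on [0.85, 1] for true interactors versus [0, 0.5] for
  decoys, and stability classes realized as ratios near 1.0 (stable) or
  0.5 (exchanging) with σ = 0.02.

At these settings the differential pipeline recovers every spike with no
false calls: the spike is ≈12 pooled standard errors tall, while a null
protein would need a ≈6σ excursion to cross the fold-change gate alone.
That is the *designed* regime — the point of the end-to-end check is
pipeline correctness (normalization, filtering, testing, thresholding
composed in the right order), not statistical power at the margin.

What the generators do **not** emulate: correlated missingness,
intensity-dependent variance, batch structure, compositional effects in
fractions, shared-peptide ambiguity, or any biology beyond the statistical
structure the pipeline assumes. A green test suite therefore certifies the
computations, not performance on real spectra.

Problem sizes in the tests (catalogs of a few hundred to 1500
observations, 200-protein matrices, 10^4-point envelope samples, the
exhaustive N ≤ 60 enrichment sweep) were chosen as the smallest sizes at
which every property is sharply testable.

## Determinism and degenerate inputs

Every stochastic component is a pure function of a single integer seed;
identical configurations produce byte-identical outputs, and the pipeline
driver writes a run manifest (inputs, thresholds, package version, seed)
next to every output. Degenerate inputs are handled by policy, stated at
each function: empty filter lists mean "no constraint", empty series are
empty results, unmapped orthologs and unresolved Entrez IDs are counted
exclusions, and genuinely contradictory requests (two filters on one
field, duplicate study registration, out-of-range thresholds) raise typed
conditions naming the offending field.

## Known limitations

* Orthology, annotation sets, and STRING edges are frozen inputs; the
  package deliberately performs no live lookups, so results are only as
  current as the supplied tables.
* The filter engine's AND semantics for multi-value filters interacting
  with NOT-filters follows the strictest consistent reading (per-value
  existence within the constrained set); other readings exist.
* Isoform-level identity is out of scope — genes are keyed by human
  symbol.
* The stability threshold for the specific & stable quadrant is a
  reported configuration choice, not an estimated quantity.
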