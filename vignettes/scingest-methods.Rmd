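---
title: "scingest: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scingest: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scingest)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. Nothing here states a number the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The metadata model

A submission is three flat documents — sample, experiment, analysis —
each an ordered list of records keyed by a unique `alias`. A ruleset
assigns each field a tier. We use the triad
**mandatory / recommended / optional**: mandatory fields missing are
errors, recommended missing are warnings (warnings never fail a
report), optional fields are simply kept when present. The tier
vocabulary is closed; any other tier string is rejected at ruleset load.
This triad is the one the conversion step operates on — the target
entity schema has only mandatory/optional, so "recommended" is exactly
the tier that must be dropped on conversion — which is why we treat
"required" as a synonym of "mandatory" rather than a fourth tier.

The packaged default ruleset is a deliberately minimal single-cell
inventory (it is configuration, not a fixed standard): sample records
carry a `material` discriminator (`organism` or `specimen`) and the
sample-section rules are conditioned on it via a `when` clause, so "the
mandatory fields of a record" is well defined per record kind — an
organism needs an `organism` ontology term and `sex`; a specimen needs a
`specimen_tissue` term and a `derived_from` reference. Ontology terms
are validated *syntactically only* (CURIE pattern `PREFIX:digits`);
the package operates offline and performs no ontology-server lookups, so
a syntactically valid but non-existent term passes. Reference fields
(`entity_ref`) must resolve to an alias in the referenced document.

Field names are normalised to lower-case snake case on read because
spreadsheet headers vary in case and spacing; values are kept verbatim.
Empty cells are treated as absent fields, which makes TSV, XLSX and JSON
encodings of the same content read identically.

## 2. The entity graph and the conversion

The target data model types every piece of an assay: one **project**,
**biomaterials** (donor organisms, specimens, optionally cell
suspensions), **protocols**, **processes** and **files**, with links in
which a process consumes inputs and produces outputs under protocols.
The subcategory registry is fixed at the minimal set covering an
scRNA-seq assay path (donor_organism, specimen_from_organism,
cell_suspension; collection/dissociation/library_preparation/sequencing
protocols; a generic process; sequence_file, analysis_file; project).
Dissociation and cell-suspension steps are registered but not produced
by the default mapping — the emulated porcine PBMC design does not state
them, so they are left available for custom graphs rather than invented.

Conversion runs in a fixed stage order — validate, clean, split, link,
graph-validate — and refuses to proceed when metadata validation fails.
Design choices worth recording:

* **Recommended fields are dropped, not demoted.** The removed
  (document, record, field) triples are returned as a manifest so the
  operation is auditable.
* **One process link per experiment record**, from its specimen to all
  of that experiment's files: files of one library share provenance. An
  experiment without files yields no sequencing link, and a graph with
  no files at all passes validation with a warning rather than failing —
  metadata-first submissions are legitimate intermediate states.
* **Reference fields stay inside entity content after link
  construction.** The production schema strips them; we keep them so
  `flatten_graph()` is lossless and `flatten(convert(S)) =
  clean(S)` holds field for field. This divergence is intentional and
  confined to entity `content`.
* **UUIDs are name-based by default**: the MD5 of
  `(namespace, category, entity_id)` in canonical 8-4-4-4-12 layout with
  name-based version/variant bits. Deterministic UUIDs make conversions
  reproducible and diffable, and make the idempotence property
  (`convert(flatten(convert(S)))` has identical entity ids and UUIDs)
  testable. `random_uuids = TRUE` gives production-like behaviour.
* **`described_by` URIs** are `<base>/<schema_version>/<subcategory>`
  with the base a configuration knob, mirroring a published schema
  directory layout.
* The experiment record's full content lives on the
  library-preparation protocol entity (the sequencing protocol carries
  the subset describing the run); this gives flattening a single,
  unambiguous home for each source record.
* Spreadsheet export writes one TSV per subcategory with system columns
  (`uuid`, `described_by`, `schema_version`, `entity_id`) leading.

Graph validation reports all problems instead of throwing: project
cardinality, dangling link ids, non-empty and disjoint inputs/outputs,
non-empty protocol lists, acyclicity of the input→output relation
(checked with igraph), orphan files (every file must be the output of
exactly one link), donor-rooted specimens, and UUID form/uniqueness.

## 3. Pseudobulk collapse and barChart tracks

`collapse_by_celltype()` computes entry (gene, type) as the mean
(default) or median over member cells. Mean is the default because it
is the conventional behaviour of the upstream matrix-collapsing
utilities this step mirrors and satisfies the mass-conservation
identity (mean × member count sums to the gene total), which the tests
verify at 1e-9 relative; median is offered for robustness to outlier
cells. Cell-type columns are ordered lexicographically in the C locale,
and that one ordering is used everywhere downstream (the `expScores`
vector in every BED record), so tracks built on different machines are
byte-comparable. Expression values are taken as-is: whether the matrix
holds raw counts or normalised values is the caller's choice, and no
log-transform is applied.

The BED score column must be an integer in [0, 1000]; how to derive it
from expression is not standardised, so the package defines it as
global-max normalisation: `round(1000 · max_t x_gt / max_{g,t} x_gt)`,
with 0 when the global max is 0. This keeps the most-expressed gene at
exactly 1000 and preserves cross-gene comparability within one track.

Dialects: the core content is BED6 + gene symbol + cell-type count +
comma-joined scores (9 columns, `plus3`). The default `plus4` appends
one literal `"0"` placeholder column (matching the 10-column "BED6+4"
convention of browser barChart tracks); `plus5` appends two. The
placeholders are non-functional offset/length slots and are documented
as such. Sorting is lexicographic chromosome then start then end —
`chr10` before `chr2` — matching the browser tool chain's sorter, and
the writer refuses unsorted records rather than silently reordering.
Coordinates are 0-based half-open throughout; GFF3 input is shifted by
−1 on read. Number formatting uses up to 17 significant digits so a
written track re-parses to exactly the records written.

## 4. Tree-ensemble network inference

For each gene *g* the package fits an ensemble of `n_trees` regression
trees predicting *g*'s expression from the TF expressions (excluding
*g* itself when it is a TF, so self-edges cannot occur). The importance
of TF *f* in one tree is the summed decrease in residual sum of squares
over the nodes split on *f*:

> ΔSSE = S_L²/N_L + S_R²/N_R − S²/N,

where S are within-node sums of the target — the regression analogue of
impurity-decrease importance (the classification literature's "Gini
importance"). Edge importance is the per-tree total averaged over the
ensemble, reported in the target's variance units and **unnormalised**
by default (per-target sums may differ; `normalize = TRUE` rescales
each target's importances to sum to one).

Defaults: 100 trees; `max_features = "sqrt"` (features tried per
split), the conventional random-forest subset rule; bootstrap
resampling on; minimum node size 5 (the customary regression-forest
leaf size — full-depth trees on 200 noisy cells mostly fit noise below
that); unlimited depth. An extra-trees variant (random thresholds) is
available behind `method = "extratrees"`. Splits search midpoints
between distinct sorted feature values; ties in reduction keep the
first candidate in (sampled-feature, ascending-threshold) order, making
tree construction fully deterministic given the RNG stream.

Determinism and invariances: each target's ensemble is seeded as
`cfg$seed + target index`, so the whole edge table is a pure function
of (matrix, TF list, config). Cells are canonically reordered by cell
id before fitting, so permuting matrix columns cannot change the
result. A zero-variance target receives exactly zero importances (there
is no impurity to reduce) rather than an error, and a constant
predictor matrix yields zero importances the same way. The compiled
core also reports each tree's root split, which is how the test suite
checks a single depth-1 tree against an exhaustive-split oracle
written independently in R; an external random-forest implementation is
used in the tests only as a cross-check of importance ordering, never
as the implementation.

Hub scores sum a TF's outgoing importances; with variance-reduction
importances this weights a regulator by total variance explained
across its targets, which is what "strongest hub" means here. For
planted-network evaluation the candidate set is all TF→non-TF edges
(TF→TF edges have no planted truth and are excluded).

The HTML export embeds the node-link JSON in the page and renders it
with a small inline canvas force layout; it deliberately has no
external dependencies so the file can be archived alongside results
and opened anywhere.

## 5. What the fixtures emulate — and what they do not

`make_submission()` emulates the *structure* of a seven-donor porcine
PBMC submission (seven organisms, one blood specimen each, one
scRNA-seq experiment per specimen, paired FASTQ records), with sex,
breed and optional health status randomised per seed. It does not
emulate the scale (tens of thousands of cells) or the field richness of
a real consortium submission.

`make_expression()` plants a linear network: 5 TFs i.i.d. Normal(0, 1)
across 200 cells; 15 targets, each the sum of 2 randomly chosen TF
parents weighted Uniform(1, 3) plus Normal(0, 0.1) noise; 20 further
non-TF genes of pure Normal(0, 1) noise; the matrix is shifted by its
global minimum so values are non-negative (count-score compatible for
the track builder). Cells are labelled round-robin over CD4_T, B, NK
and Mono. These sizes keep the full suite fast while exercising every
code path; they were chosen once as the fixture's study conditions and
are not tuned. The generator is deliberately *not* a realistic
scRNA-seq simulator: no dropout, no overdispersion, no library-size
variation, and no cell-type-specific expression structure (labels are
independent of expression). Passing the planted-network recovery check
therefore demonstrates that the estimator recovers strong linear signal
under light noise — not that it would achieve the same ranking quality
on real droplet data, where the unstated preprocessing and much lower
signal-to-noise make published importance scores non-reproducible
targets.

`make_annotation()` tiles the 40 genes over two chromosomes in
non-overlapping 1 kb intervals on a 2 kb grid with alternating strands
— enough to exercise coordinate conventions, strand carriage and
cross-chromosome sorting, nothing more.

## 6. Numerical and degenerate-input conventions

* All identifier sorts use radix (C-locale) ordering, so results do not
  depend on the session locale.
* Split-search and ranking tie-breaks are deterministic (first
  candidate / lexicographic), so equal importances rank reproducibly.
* A target with fewer than `2 × min_node_size` usable cells, or a node
  with a constant feature, simply does not split.
* Validation reports accumulate issues rather than stopping at the
  first, so one run shows every problem; conversion, by contrast, fails
  fast on the first unresolvable reference because a partial graph is
  not a useful artifact.
* Problem sizes in the test suite (25 round-trip seeds; 20 random
  collapse matrices up to 50×200; 100-tree recovery on the 40×200
  fixture) are the package's chosen verification scale.

## 7. Known limitations

* No live submission to archives, no ontology-server validation, no
  cloud transfer: the package is the desk-scale, offline part of the
  brokering path.
* XLSX reading requires the optional readxl package; TSV/JSON cover the
  same content.
* The spreadsheet export writes scalar content fields only; structured
  project content (contributor lists) lives in the JSON entity
  serialisation.
* Text BED only — binary track compilation (bigBed) and the browser
  plugin that renders the tracks are out of scope; the package emits the
  data they consume.
* The inference module assumes expression values are comparable across
  cells as given; normalisation is upstream of this package.
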