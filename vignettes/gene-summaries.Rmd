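---
title: "Generating gene summaries from structured annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating gene summaries from structured annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesum)
```

## The problem

Model-organism databases carry rich structured annotation — Gene Ontology
(GO) terms with evidence codes, Disease Ontology terms on human genes,
anatomy-ontology expression annotations, orthology calls supported by
varying numbers of prediction methods, collated high-throughput
(microarray / tiling array / RNA-seq) results, and InterPro protein
domains — but most genes in most nematode genomes have little or no
*directly curated* functional annotation. `genesum` turns whatever
structured data a gene does have into a short English paragraph, using
rule-based sentence templates rather than free generation, so that every
sentence is traceable to specific records.

## The procedure and its assumptions

Summary generation is a strict pipeline: parse → bundle → ortholog
selection → statement building → gating → realization → writing. Three
design commitments shape it:

* **Statements before sentences.** Builders produce category-tagged
  statements (ordered item lists, a total count, qualifiers) without any
  text; templates render them later. This separates content decisions
  (which terms, which orthologs) from surface decisions (truncation,
  conjunctions) and lets gating operate on categories alone.
* **Build, then gate.** Every applicable statement is built for every gene,
  and a gating profile then removes categories that are redundant for genes
  that already have curated data. Gating never edits statement content.
* **Determinism everywhere.** Identical inputs must produce byte-identical
  outputs. All orderings are specified (input order for items, lexicographic
  tie-breaks for orthologs, a fixed category and template order for
  sentences), and the writers fix encoding (UTF-8), newlines (`\n`) and row
  order (by gene id).

### Ortholog selection

Two criteria are implemented. For *C. elegans* genes, **all** human
orthologs tied at the maximal prediction-method count are selected, and
their transferred annotations are merged (the disease list is the
deduplicated union); this follows the plural phrasing of production
summaries ("Human ortholog(s) of this gene ..."), which admits ties even
when the example shows a single gene. For the other nine species, exactly
**one** ortholog is selected, ranked lexicographically by (method count,
GO-annotation count of the candidate gene), because the transferred-process
sentence names a single source gene. Remaining ties prefer *C. elegans*,
then alphabetical species, then symbol — the ranking data do not order such
candidates, so the tie-break is an explicit package choice made for
determinism.

### Gating profiles

The stated inclusion rules are: ortholog-transferred statements only when GO
data are absent; large-scale and domain statements only when GO *and*
curated expression data are absent. The production *act-3* summary, however,
contains both a curated-expression sentence and a domain sentence, which the
literal rule would forbid. The package therefore ships two profiles:
`strict` encodes the literal rules; `ws292` (default) blocks large-scale and
domain statements on GO data only, matching the evidenced behaviour. Two
further interpretation choices are fixed here: "GO data present" counts any
aspect and any evidence code, and "expression data" means curated
anatomy-ontology annotations only — large-scale expression-enrichment
records do not block the very statements they feed. Disease statements gate
together with function-transfer statements, since both ride on the same
ortholog-transfer strategy. Process transfer to non-elegans genes is
ungated: the *fem-2* example carries its own GO sentence alongside the
transferred-process sentence.

### Evidence classes

GO sentences distinguish experimental from predicted support by evidence
code: `IEA`, `ISS`, `ISO`, `IBA` and `RCA` (the electronic / sequence /
ortholog / phylogenetic / computational-analysis codes) render as
"Predicted to enable ..." / "Predicted to be involved in ...", everything
else as "Enables ..." / "Is involved in ...". The set is a configurable
argument (`predicted_codes`) with that default. The `contributes_to`
qualifier always renders "Contributes to ..." — including the
mid-sentence capital in "Human ACTB Contributes to ...", which is
reproduced verbatim from production output rather than corrected. A
transferred molecular-function term whose name begins with "structural
constituent" is rendered as its own fragment sentence ("A structural
constituent of ...") rather than folded into the enables list, again
matching the production surface.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `exemplar_count` | 3 | items shown when a truncating category overflows |
| `several_threshold` | 10 | totals ≥ this render "several"; totals in `exemplar_count+1 .. 9` render the spelled count ("seven chemicals") |
| `category_order` | 12 categories | sentence order within a paragraph |
| `truncating_categories` | disease, function transfer, gene/chemical regulation | categories subject to truncation |
| `predicted_codes` | IEA, ISS, ISO, IBA, RCA | evidence codes rendered as "Predicted to" |

The `several_threshold` default is a package choice: production text shows
an exact word at seven and "several" for larger, unstated counts, so any cut
between 8 and the first observed "several" count is consistent; 10 keeps
spelled counts in the single-digit range where they read naturally.
Counts are spelled for 1–999; larger totals are outside the engine's
domain (no single gene record table at this granularity approaches it).

## What the fixtures emulate — and what they do not

`make_example_fixture()` writes complete, constant input sets
(OBO + GAF + TSVs + config) whose pipeline output reproduces four
production-style summaries verbatim; quantities invisible in those
paragraphs (the diseases beyond the three named, the extra enables terms,
the regulator genes beyond three, the four unnamed chemicals) are synthetic
records named as such (`synthetic disease 4`, `synthetic-chemical-4`), sized
to ten diseases, ten enables terms, ten regulators and seven chemicals so
the printed "several ..."/"seven ..." forms arise from the ordinary
truncation rule rather than special-casing. `make_random_bundle()` generates
seeded random bundles — ontology DAGs built by drawing parents only from
earlier terms (acyclic by construction), genes across all ten species, and
records in every category — for property tests.

Passing tests on these inputs demonstrate the engine's rules, not release
behaviour: real annotation sets are orders of magnitude larger, have deeper
ontologies, annotation redundancy along the graph, and evidence-code
distributions the fixtures do not model. In particular the package performs
no ontology-closure reasoning and no graph-based trimming of term lists to
informative ancestors (exemplar choice here is purely order-based), so on
dense real annotation sets its sentences would be longer and less abstracted
than production descriptions. Whole-database summary counts likewise require
a full release and are out of scope; the run manifest reports the same
per-category count columns at the scale of the configured inputs.

## Numerical and degenerate-input choices

* Ontology parsing accepts only `[Term]` stanzas with `id`, `name`,
  `namespace`, `is_a`; other tags warn and are skipped. Cycles (detected via
  igraph's DAG test, including self-loops) and unresolvable parents are
  structured errors, since downstream meaning depends on a valid hierarchy.
* GAF rows with unknown term ids, or whose aspect letter contradicts the
  term's namespace, are dropped with a counted warning — annotation files in
  the wild routinely lag their ontology, and a partial parse with an audit
  count is more useful than a hard failure. Malformed rows (wrong column
  count) are errors carrying the line number.
* Record keys that do not resolve to a known gene go to a dangling-reference
  report and are excluded from indexes, never fatal.
* Empty item lists are unrepresentable (`new_statement()` rejects them), so
  realization never sees a degenerate list; a gene with no surviving
  statements yields an empty summary, which the writers drop from output by
  default.
* The manifest object carries a timestamp, but the written `manifest.json`
  omits it so that every written artifact is byte-stable across runs.

## Problem sizes used in the checks

The test-suite and the acceptance script run at fixture scale, chosen to
exercise every rule while keeping runs interactive: the four example
fixtures (1–3 genes each), random bundles of 15–50 genes, 200 random
candidate sets (≤ 10 candidates) for the ortholog-selection oracle
comparison, the full 1–999 cardinal-word range, and 8 gating states
(2 profiles × 4 data combinations).

```{r example}
dir <- tempfile()
cfg <- make_example_fixture("cjp_gid1", dir)
manifest <- run_pipeline(cfg, out_dir = file.path(dir, "out"))
attr(manifest, "summaries")$description
tidy(manifest)[tidy(manifest)$n > 0, ]
```

## Known limitations

Templates are fixed-form English with no grammatical agreement beyond the
list rules (a single domain still reads "the following domains:"), no
localization, and no attempt to vary phrasing. Exemplar order is input-file
order, not informativeness. The orthology "methods" column is trusted input;
no orthology inference is performed. The OBO/GAF readers implement the
subsets this engine needs, not the full specifications (no `relationship:`
semantics, no GPAD/OWL).
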