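# genesum

`genesum` generates short English gene summaries ("gene descriptions") for
nematode genes from structured, curated annotations. It is aimed at model-
organism database curators and bioinformaticians who want the kind of
one-paragraph functional overview shown on WormBase gene pages — readable
without any knowledge of database vocabularies — for genes that may lack
directly curated functional annotation.

## What it computes

For each gene, the engine builds candidate **statements** from up to three
sources and assembles the survivors into one paragraph:

1. **Transfer from orthologous genes.** For a *C. elegans* gene, the human
   orthologs supported by the largest number of orthology prediction methods
   are selected; their Disease Ontology annotations and GO molecular-function
   annotations become "Human ortholog(s) of this gene implicated in ..." and
   "Human *SYMBOL* enables ..." sentences. For the other nine nematode
   species, the single best ortholog is chosen by (method count, GO
   annotation count), ties resolved toward *C. elegans*, and its GO
   biological-process annotations become an "In *C. elegans*, *gene* is
   involved in ..." sentence.
2. **Large-scale data.** Collated microarray, tiling-array and RNA-seq
   records yield expression-enrichment, gene-regulation and
   chemical-regulation sentences ("Is affected by seven chemicals including
   ... based on microarray and RNA-seq studies.").
3. **Protein domains.** InterPro domain records yield "Is predicted to
   encode a protein with the following domains: ...".

Statements from sources 1–3 are **gated**: under the default `ws292` profile
they are included only for genes without curated GO annotation (ortholog
transfer, large-scale and domain statements all gate on GO); under the
`strict` profile, large-scale and domain statements additionally require the
absence of curated anatomy-ontology expression annotation. The gene's own GO,
curated-expression and orthology sentences are never gated.

Rendering uses a small controlled grammar: lists are joined as
"*a* and *b*" (two items) or "*a*; *b*; and *c*" (three or more);
truncating categories show at most 3 exemplars, prefixed by the spelled-out
total ("seven chemicals") below 10 and by "several" at 10 or more.

## Worked example

The package ships fixture generators that rebuild, in code, complete input
sets for four production-style summaries. With the `fem2` fixture:

```r
library(genesum)

dir <- tempfile()
cfg <- make_example_fixture("fem2", dir)        # writes OBO + GAF + TSVs + config.yml
manifest <- run_pipeline(cfg, out_dir = file.path(dir, "out"))
attr(manifest, "summaries")$description
```

prints the *C. briggsae* *fem-2* summary:

```
Predicted to enable protein serine/threonine phosphatase activity. Is an
ortholog of C. elegans fem-2. In C. elegans, fem-2 is involved in male sex
determination; masculinization of hermaphroditic germ-line; and nematode
male tail tip morphogenesis.
```

Sentence one is the gene's own electronically inferred (IEA) GO annotation,
hence "Predicted to enable"; sentence two names the best related-nematode
ortholog (*C. elegans* *fem-2*, which outranks the *C. remanei* candidate on
prediction-method count); sentence three transfers that source gene's three
biological-process annotations. `print(manifest)` shows the per-category
statement counts (here one each of `go_function`, `orthology`,
`elegans_process_transfer`), and `out/` contains deterministic
`summaries.txt`, `summaries.tsv`, `summaries.json` and `manifest.json`.

The same works for `"act3"`, `"abt3"` and `"cjp_gid1"`, and
`summarize_gene()` / `summarize_genes()` expose the per-gene flow on any
`build_bundle()` input. A thin CLI wraps the pipeline:

```sh
exec/genesum fixtures --out fixtures
exec/genesum generate --config fixtures/act3/config.yml --out out
exec/genesum validate --config fixtures/act3/config.yml
```

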