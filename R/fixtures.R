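# Fixture generation: all test inputs are built in code, no downloads.
# The four named example fixtures are frozen input sets whose pipeline output
# reproduces, verbatim, four production WormBase-style gene summaries
# (act-3, fem-2, abt-3, Cjp-gid-1). Quantities not visible in those
# paragraphs (extra diseases, extra enables terms, extra regulators) are
# synthetic and named as such; they are sized to trigger the printed surface
# forms ("several diseases", "several functions", "several genes",
# "seven chemicals").

EXAMPLE_FIXTURES <- c("act3", "fem2", "abt3", "cjp_gid1")

EXAMPLE_SUMMARY_TEXTS <- c(
  act3 = paste(
    "Expressed in gonad and head.",
    "Human ortholog(s) of this gene implicated in several diseases,",
    "including Baraitser-Winter syndrome 1; Baraitser-Winter syndrome 2;",
    "and autosomal dominant nonsyndromic deafness 20.",
    "Human ACTB Contributes to nucleosomal DNA binding activity.",
    "Human ACTB enables several functions, including Tat protein binding",
    "activity; enzyme binding activity; and kinesin binding activity.",
    "A structural constituent of postsynaptic actin cytoskeleton.",
    "Is predicted to encode a protein with the following domains:",
    "Phosphorylation site; Actin; Actin family; and ATPase, nucleotide",
    "binding domain.",
    "Is an ortholog of human ACTB (actin beta)."
  ),
  fem2 = paste(
    "Predicted to enable protein serine/threonine phosphatase activity.",
    "Is an ortholog of C. elegans fem-2.",
    "In C. elegans, fem-2 is involved in male sex determination;",
    "masculinization of hermaphroditic germ-line; and nematode male tail",
    "tip morphogenesis."
  ),
  abt3 = paste(
    "Enriched in male based on RNA-seq studies.",
    "Is affected by several genes including eat-2; sir-2.1; and npr-1",
    "based on RNA-seq; tiling array; and microarray studies.",
    "Is affected by seven chemicals including Tunicamycin; manganese",
    "chloride; and multi-walled carbon nanotube based on microarray and",
    "RNA-seq studies."
  ),
  cjp_gid1 = paste(
    "Is predicted to encode a protein with the following domains:",
    "SPRY domain; B30.2/SPRY domain superfamily; and Concanavalin A-like",
    "lectin/glucanase domain superfamily.",
    "Is an ortholog of C. elegans gid-1."
  )
)

#' Names and expected output of the example fixtures
#'
#' `example_fixture_names()` lists the available named fixtures;
#' `example_summary_text()` returns the reference summary paragraph that the
#' pipeline reproduces from a fixture's inputs under the `ws292` profile.
#'
#' @param name One of `"act3"`, `"fem2"`, `"abt3"`, `"cjp_gid1"`.
#' @return A character vector of names, or a single reference paragraph.
#' @export
example_fixture_names <- function() EXAMPLE_FIXTURES

#' @rdname example_fixture_names
#' @export
example_summary_text <- function(name) {
  if (!name %in% EXAMPLE_FIXTURES) {
    genesum_abort(sprintf("Unknown example fixture: '%s'.", name),
                  class = "genesum_unknown_fixture")
  }
  unname(EXAMPLE_SUMMARY_TEXTS[[name]])
}

mk_terms <- function(ids, names, namespace) {
  tibble(term_id = ids, name = names, namespace = namespace,
         parents = rep(list(character()), length(ids)))
}

write_fixture_config <- function(dir, species, inputs) {
  cfg <- list(
    species = species,
    profile = "ws292",
    inputs = inputs,
    thresholds = list(exemplar_count = 3L, several_threshold = 10L),
    outputs = list(formats = list("txt", "json", "tsv"))
  )
  path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, path)
  path
}

fixture_act3 <- function(dir) {
  # Mini molecular-function ontology carrying the transferred ACTB terms.
  enables_named <- c("Tat protein binding activity", "enzyme binding activity",
                     "kinesin binding activity")
  enables_synth <- sprintf("synthetic binding activity %d", 4:10)
  mf_names <- c(
    "nucleosomal DNA binding activity", enables_named, enables_synth,
    "structural constituent of postsynaptic actin cytoskeleton"
  )
  mf_ids <- sprintf("GO:1%06d", seq_along(mf_names))
  ontology <- new_ontology(mk_terms(mf_ids, mf_names, "molecular_function"))
  write_obo(ontology, file.path(dir, "go.obo"))

  write_annotation_tsv(tibble(
    gene_id = c("WB-act-3", "HGNC-ACTB", "HGNC-POTEE"),
    public_name = c("act-3", "ACTB", "POTEE"),
    species = c("C. elegans", "human", "human")
  ), file.path(dir, "genes.tsv"), "genes")

  # ACTB annotations to transfer: one contributes_to term, ten enables terms
  # (to reach the "several functions" form), one structural-constituent term.
  qualifiers <- c("contributes_to", rep("enables", 11))
  write_gaf(tibble(
    gene_id = "HGNC-ACTB",
    term_id = mf_ids,
    aspect = "molecular_function",
    evidence_code = "IDA",
    qualifier = qualifiers
  ), file.path(dir, "annotations.gaf"))

  write_annotation_tsv(tibble(
    gene_id = "HGNC-ACTB",
    disease_term_name = c(
      "Baraitser-Winter syndrome 1", "Baraitser-Winter syndrome 2",
      "autosomal dominant nonsyndromic deafness 20",
      sprintf("synthetic disease %d", 4:10)
    )
  ), file.path(dir, "disease.tsv"), "disease")

  write_annotation_tsv(tibble(
    gene_id = "WB-act-3",
    anatomy_term_name = c("gonad", "head")
  ), file.path(dir, "expression.tsv"), "expression")

  write_annotation_tsv(tibble(
    subject_gene_id = "WB-act-3",
    subject_species = "C. elegans",
    ortholog_gene_id = c("HGNC-ACTB", "HGNC-POTEE"),
    ortholog_symbol = c("ACTB", "POTEE"),
    ortholog_full_name = c("actin beta", "POTE ankyrin domain family member E"),
    ortholog_species = "human",
    methods = list(sprintf("method-%d", 1:5), sprintf("method-%d", 1:2))
  ), file.path(dir, "orthology.tsv"), "orthology")

  write_annotation_tsv(tibble(
    gene_id = "WB-act-3",
    domain_name = c("Phosphorylation site", "Actin", "Actin family",
                    "ATPase, nucleotide binding domain"),
    interpro_id = sprintf("IPRX%04d", 1:4)
  ), file.path(dir, "domains.tsv"), "domains")

  write_fixture_config(dir, "C. elegans", list(
    genes = "genes.tsv", go_obo = "go.obo", gaf = "annotations.gaf",
    disease = "disease.tsv", expression = "expression.tsv",
    orthology = "orthology.tsv", domains = "domains.tsv"
  ))
}

fixture_fem2 <- function(dir) {
  terms <- bind_rows(
    mk_terms("GO:2000001", "protein serine/threonine phosphatase activity",
             "molecular_function"),
    mk_terms(sprintf("GO:2%06d", 2:4),
             c("male sex determination",
               "masculinization of hermaphroditic germ-line",
               "nematode male tail tip morphogenesis"),
             "biological_process")
  )
  write_obo(new_ontology(terms), file.path(dir, "go.obo"))

  write_annotation_tsv(tibble(
    gene_id = c("WB-Cbr-fem-2", "WB-fem-2", "WB-Cre-fem-2"),
    public_name = c("fem-2", "fem-2", "fem-2"),
    species = c("C. briggsae", "C. elegans", "C. remanei")
  ), file.path(dir, "genes.tsv"), "genes")

  write_gaf(tibble(
    gene_id = c("WB-Cbr-fem-2", rep("WB-fem-2", 3)),
    term_id = sprintf("GO:2%06d", 1:4),
    aspect = c("molecular_function", rep("biological_process", 3)),
    evidence_code = c("IEA", "IMP", "IMP", "IMP"),
    qualifier = c("enables", rep("involved_in", 3))
  ), file.path(dir, "annotations.gaf"))

  # C. elegans fem-2 outranks the C. remanei candidate on method count.
  write_annotation_tsv(tibble(
    subject_gene_id = "WB-Cbr-fem-2",
    subject_species = "C. briggsae",
    ortholog_gene_id = c("WB-fem-2", "WB-Cre-fem-2"),
    ortholog_symbol = "fem-2",
    ortholog_full_name = "",
    ortholog_species = c("C. elegans", "C. remanei"),
    methods = list(sprintf("method-%d", 1:4), sprintf("method-%d", 1:2))
  ), file.path(dir, "orthology.tsv"), "orthology")

  write_fixture_config(dir, "C. briggsae", list(
    genes = "genes.tsv", go_obo = "go.obo", gaf = "annotations.gaf",
    orthology = "orthology.tsv"
  ))
}

fixture_abt3 <- function(dir) {
  write_annotation_tsv(tibble(
    gene_id = "WB-abt-3", public_name = "abt-3", species = "C. elegans"
  ), file.path(dir, "genes.tsv"), "genes")

  regulators <- c("eat-2", "sir-2.1", "npr-1",
                  sprintf("synthetic-regulator-%d", 4:10))
  chemicals <- c("Tunicamycin", "manganese chloride",
                 "multi-walled carbon nanotube",
                 sprintf("synthetic-chemical-%d", 4:7))
  write_annotation_tsv(tibble(
    gene_id = "WB-abt-3",
    kind = c("expression_enrichment", rep("gene_regulation", 10),
             rep("chemical_regulation", 7)),
    object_name = c("male", regulators, chemicals),
    study_types = c(
      list("RNA-seq"),
      list(c("RNA-seq", "tiling array", "microarray")),
      rep(list("RNA-seq"), 9),
      list(c("microarray", "RNA-seq")),
      rep(list("microarray"), 6)
    )
  ), file.path(dir, "large_scale.tsv"), "large_scale")

  write_fixture_config(dir, "C. elegans", list(
    genes = "genes.tsv", large_scale = "large_scale.tsv"
  ))
}

fixture_cjp_gid1 <- function(dir) {
  write_annotation_tsv(tibble(
    gene_id = c("WB-Cjp-gid-1", "WB-gid-1"),
    public_name = c("Cjp-gid-1", "gid-1"),
    species = c("C. japonica", "C. elegans")
  ), file.path(dir, "genes.tsv"), "genes")

  write_annotation_tsv(tibble(
    gene_id = "WB-Cjp-gid-1",
    domain_name = c("SPRY domain", "B30.2/SPRY domain superfamily",
                    "Concanavalin A-like lectin/glucanase domain superfamily"),
    interpro_id = sprintf("IPRX%04d", 11:13)
  ), file.path(dir, "domains.tsv"), "domains")

  write_annotation_tsv(tibble(
    subject_gene_id = "WB-Cjp-gid-1",
    subject_species = "C. japonica",
    ortholog_gene_id = "WB-gid-1",
    ortholog_symbol = "gid-1",
    ortholog_full_name = "",
    ortholog_species = "C. elegans",
    methods = list(sprintf("method-%d", 1:3))
  ), file.path(dir, "orthology.tsv"), "orthology")

  write_fixture_config(dir, "C. japonica", list(
    genes = "genes.tsv", domains = "domains.tsv", orthology = "orthology.tsv"
  ))
}

#' Generate a named example fixture
#'
#' Writes the complete input file set (genes table, mini ontology, GAF,
#' annotation TSVs, and a `config.yml`) for one of the four worked examples
#' into `dir`. Running [run_pipeline()] on the returned config path under the
#' default `ws292` profile reproduces the corresponding reference paragraph
#' (see [example_summary_text()]) verbatim. Fixtures are constant — no
#' randomness is involved.
#'
#' @param name One of `"act3"`, `"fem2"`, `"abt3"`, `"cjp_gid1"`.
#' @param dir Output directory (created if absent).
#' @return The path to the written `config.yml`, invisibly.
#' @export
#' @examples
#' dir <- tempfile()
#' cfg <- make_example_fixture("fem2", dir)
#' manifest <- run_pipeline(cfg, out_dir = tempfile())
#' attr(manifest, "summaries")$description
make_example_fixture <- function(name, dir) {
  if (!name %in% EXAMPLE_FIXTURES) {
    genesum_abort(sprintf("Unknown example fixture: '%s'.", name),
                  class = "genesum_unknown_fixture")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- switch(name,
    act3 = fixture_act3(dir),
    fem2 = fixture_fem2(dir),
    abt3 = fixture_abt3(dir),
    cjp_gid1 = fixture_cjp_gid1(dir)
  )
  invisible(path)
}

with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random annotation bundle
#'
#' Builds a reproducible bundle with small random ontologies (parent links
#' drawn only towards earlier terms, so the graph is acyclic by
#' construction), genes across species, and records in every annotation
#' category. The same seed always yields an identical bundle. Intended for
#' property tests; it emulates the shape of curated inputs, not their
#' biological content.
#'
#' @param seed Integer seed.
#' @param n_genes Number of nematode genes (default 20); human ortholog
#'   genes are added on top.
#' @param n_terms Terms per GO namespace (default 8).
#' @return A `genesum_bundle`.
#' @export
make_random_bundle <- function(seed, n_genes = 20, n_terms = 8) {
  with_preserved_seed(seed, {
    if (n_genes == 0) return(build_bundle())

    namespaces <- unname(GO_ASPECTS)
    terms <- bind_rows(map(seq_along(namespaces), function(k) {
      ids <- sprintf("GO:%d%06d", k, seq_len(n_terms))
      parents <- map(seq_len(n_terms), function(i) {
        if (i == 1 || stats::runif(1) < 0.3) character()
        else sample(ids[seq_len(i - 1)], sample(1:min(2, i - 1), 1))
      })
      tibble(term_id = ids,
             name = sprintf("random %s term %d", gsub("_", " ", namespaces[[k]]),
                            seq_len(n_terms)),
             namespace = namespaces[[k]], parents = parents)
    }))
    ontology <- new_ontology(terms)

    n_human <- max(2L, n_genes %/% 5L)
    genes <- tibble(
      gene_id = c(sprintf("WBGene-%04d", seq_len(n_genes)),
                  sprintf("HGene-%04d", seq_len(n_human))),
      public_name = c(sprintf("gene-%d", seq_len(n_genes)),
                      sprintf("HGENE%d", seq_len(n_human))),
      species = c(sample(GENESUM_SPECIES, n_genes, replace = TRUE),
                  rep("human", n_human))
    )

    random_rows <- function(ids, n_range) {
      unlist(map(ids, function(g) rep(g, sample(n_range, 1))))
    }

    go_genes <- random_rows(sample(genes$gene_id, max(1, nrow(genes) %/% 2)),
                            1:4)
    picked <- terms[sample(nrow(terms), length(go_genes), replace = TRUE), ]
    go_annotations <- tibble(
      gene_id = go_genes,
      term_id = picked$term_id,
      term_name = picked$name,
      aspect = picked$namespace,
      evidence_code = sample(c("IEA", "ISS", "IDA", "IMP"), length(go_genes),
                             replace = TRUE),
      qualifier = ifelse(
        picked$namespace == "molecular_function",
        sample(c("enables", "contributes_to"), length(go_genes),
               replace = TRUE, prob = c(0.8, 0.2)),
        unname(DEFAULT_QUALIFIER[picked$namespace])
      )
    )

    human_ids <- genes$gene_id[genes$species == "human"]
    nematode_ids <- genes$gene_id[genes$species != "human"]
    elegans_ids <- genes$gene_id[genes$species == "C. elegans"]

    disease <- tibble(
      gene_id = random_rows(human_ids, 1:3),
    )
    disease$disease_term_name <- sprintf("random disease %d",
                                         seq_len(nrow(disease)))

    expr_genes <- random_rows(sample(nematode_ids,
                                     max(1, length(nematode_ids) %/% 3)), 1:3)
    expression <- tibble(
      gene_id = expr_genes,
      anatomy_term_name = sprintf("tissue-%d",
                                  sample(1:6, length(expr_genes), replace = TRUE))
    )
    expression <- distinct(expression)

    ortho_subjects <- sample(nematode_ids,
                             max(1, length(nematode_ids) %/% 2))
    orthology <- bind_rows(map(ortho_subjects, function(g) {
      sp <- genes$species[genes$gene_id == g]
      pool <- if (sp == "C. elegans") human_ids else
        setdiff(c(elegans_ids, nematode_ids), g)
      if (length(pool) == 0) return(NULL)
      targets <- sample(pool, sample(1:min(3, length(pool)), 1))
      tibble(
        subject_gene_id = g,
        subject_species = sp,
        ortholog_gene_id = targets,
        ortholog_symbol = genes$public_name[match(targets, genes$gene_id)],
        ortholog_full_name = "",
        ortholog_species = genes$species[match(targets, genes$gene_id)],
        methods = map(seq_along(targets),
                      ~ sprintf("method-%d", seq_len(sample(1:6, 1))))
      )
    }))

    ls_genes <- random_rows(sample(nematode_ids,
                                   max(1, length(nematode_ids) %/% 3)), 1:4)
    large_scale <- tibble(
      gene_id = ls_genes,
      kind = sample(LARGE_SCALE_KINDS, length(ls_genes), replace = TRUE),
      object_name = sprintf("object-%d",
                            sample(1:12, length(ls_genes), replace = TRUE)),
      study_types = map(seq_along(ls_genes),
                        ~ sample(STUDY_TYPES, sample(1:3, 1)))
    )
    large_scale <- large_scale[!duplicated(large_scale[, 1:3]), ]

    dom_genes <- random_rows(sample(nematode_ids,
                                    max(1, length(nematode_ids) %/% 3)), 1:3)
    domains <- tibble(
      gene_id = dom_genes,
      domain_name = sprintf("random domain %d",
                            sample(1:10, length(dom_genes), replace = TRUE)),
      interpro_id = sprintf("IPRX%04d",
                            sample(1:10, length(dom_genes), replace = TRUE))
    )
    domains <- distinct(domains)

    build_bundle(
      genes = genes,
      ontologies = list(go = ontology),
      go_annotations = go_annotations,
      disease_annotations = distinct(disease),
      expression_annotations = expression,
      ortholog_records = orthology,
      large_scale_records = large_scale,
      domain_records = domains
    )
  })
}
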