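# Shared test helpers: in-code fixture builders and independent oracles.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

mini_go_terms <- function() {
  tibble::tibble(
    term_id = sprintf("GO:%07d", 1:6),
    name = c("binding", "protein binding", "kinase activity",
             "cell cycle", "nucleus", "cytoplasm"),
    namespace = c("molecular_function", "molecular_function",
                  "molecular_function", "biological_process",
                  "cellular_component", "cellular_component"),
    parents = list(character(), "GO:0000001", character(), character(),
                   character(), character())
  )
}

mini_ontology <- function() new_ontology(mini_go_terms())

gaf_row <- function(gene_id, term_id, qualifier = "", evidence = "IEA",
                    aspect = "F") {
  paste(c("WB", gene_id, gene_id, qualifier, term_id, "PMID:0", evidence, "",
          aspect, "", "", "gene", "taxon:6239", "20240101", "WB", "", ""),
        collapse = "\t")
}

# A configurable one-gene bundle exercising every statement category.
# `with_go` / `with_expression` toggle the subject gene's own curated data.
combo_bundle <- function(with_go = FALSE, with_expression = FALSE,
                         species = "C. elegans") {
  terms <- tibble::tibble(
    term_id = sprintf("GO:%07d", 1:4),
    name = c("subject function", "ortholog activity A", "ortholog activity B",
             "source process"),
    namespace = c("molecular_function", "molecular_function",
                  "molecular_function", "biological_process"),
    parents = list(character(), character(), character(), character())
  )
  genes <- tibble::tibble(
    gene_id = c("subject", "human-1", "elegans-1"),
    public_name = c("subj-1", "HGENE1", "src-1"),
    species = c(species, "human", "C. elegans")
  )
  go <- tibble::tibble(
    gene_id = c(if (with_go) "subject", "human-1", "human-1", "elegans-1"),
    term_id = c(if (with_go) "GO:0000001", "GO:0000002", "GO:0000003",
                "GO:0000004"),
    term_name = c(if (with_go) "subject function", "ortholog activity A",
                  "ortholog activity B", "source process"),
    aspect = c(if (with_go) "molecular_function", "molecular_function",
               "molecular_function", "biological_process"),
    evidence_code = "IDA",
    qualifier = c(if (with_go) "enables", "enables", "contributes_to",
                  "involved_in")
  )
  expression <- if (with_expression) {
    tibble::tibble(gene_id = "subject", anatomy_term_name = c("gonad"))
  } else {
    empty_annotation_tbl("expression")
  }
  target <- if (species == "C. elegans") "human-1" else "elegans-1"
  build_bundle(
    genes = genes,
    ontologies = list(go = new_ontology(terms)),
    go_annotations = go,
    disease_annotations = tibble::tibble(
      gene_id = "human-1", disease_term_name = c("disease one", "disease two")
    ),
    expression_annotations = expression,
    ortholog_records = tibble::tibble(
      subject_gene_id = "subject", subject_species = species,
      ortholog_gene_id = target,
      ortholog_symbol = genes$public_name[genes$gene_id == target],
      ortholog_full_name = if (target == "human-1") "human gene one" else "",
      ortholog_species = genes$species[genes$gene_id == target],
      methods = list(c("m1", "m2"))
    ),
    large_scale_records = tibble::tibble(
      gene_id = "subject",
      kind = c("expression_enrichment", "gene_regulation",
               "chemical_regulation"),
      object_name = c("male", "reg-1", "chem-1"),
      study_types = list("RNA-seq", "RNA-seq", "microarray")
    ),
    domain_records = tibble::tibble(
      gene_id = "subject", domain_name = "test domain",
      interpro_id = "IPRX0001"
    )
  )
}

# ---- independent ortholog-selection oracles (brute force) -------------------

oracle_human <- function(candidates) {
  humans <- candidates[candidates$ortholog_species == "human", , drop = FALSE]
  if (nrow(humans) == 0) return(humans)
  best <- 0L
  for (i in seq_len(nrow(humans))) {
    best <- max(best, length(humans$methods[[i]]))
  }
  keep <- vapply(humans$methods, function(m) length(m) == best, logical(1))
  humans <- humans[keep, , drop = FALSE]
  humans[order(humans$ortholog_symbol), , drop = FALSE]
}

# Pairwise comparator on (methods desc, GO count desc, elegans first,
# species asc, symbol asc); returns TRUE when a beats b.
oracle_nematode_beats <- function(a, b, counts) {
  lookup <- function(id) {
    if (id %in% names(counts)) as.numeric(counts[[id]]) else 0
  }
  ka <- c(-length(a$methods[[1]]), -lookup(a$ortholog_gene_id),
          as.integer(a$ortholog_species != "C. elegans"))
  kb <- c(-length(b$methods[[1]]), -lookup(b$ortholog_gene_id),
          as.integer(b$ortholog_species != "C. elegans"))
  for (j in seq_along(ka)) {
    if (ka[j] < kb[j]) return(TRUE)
    if (ka[j] > kb[j]) return(FALSE)
  }
  if (a$ortholog_species != b$ortholog_species) {
    return(a$ortholog_species < b$ortholog_species)
  }
  a$ortholog_symbol < b$ortholog_symbol
}

oracle_nematode <- function(candidates, counts) {
  if (nrow(candidates) == 0) return(candidates)
  best <- candidates[1, , drop = FALSE]
  for (i in seq_len(nrow(candidates))[-1]) {
    row <- candidates[i, , drop = FALSE]
    if (oracle_nematode_beats(row, best, counts)) best <- row
  }
  best
}

random_candidates <- function(n) {
  symbols <- sample(sprintf("sym-%02d", 1:20), n)
  tibble::tibble(
    subject_gene_id = "subject",
    subject_species = "C. briggsae",
    ortholog_gene_id = sprintf("og-%02d", seq_len(n)),
    ortholog_symbol = symbols,
    ortholog_full_name = "",
    ortholog_species = sample(c("human", "C. elegans", "C. remanei",
                                "C. brenneri"), n, replace = TRUE),
    methods = lapply(seq_len(n),
                     function(i) sprintf("m%d", seq_len(sample(1:10, 1))))
  )
}

candidates_bundle <- function(candidates, species = "C. briggsae") {
  genes <- tibble::tibble(
    gene_id = c("subject", candidates$ortholog_gene_id),
    public_name = c("subj", candidates$ortholog_symbol),
    species = c(species, candidates$ortholog_species)
  )
  genes$species[genes$species == "human"] <- "human"
  build_bundle(genes = genes, ortholog_records = candidates)
}

# Inverse of count_word for round-trip checks, built by enumeration.
word_to_count <- local({
  tbl <- NULL
  function(word) {
    if (is.null(tbl)) {
      tbl <<- stats::setNames(1:999, vapply(1:999, count_word, character(1)))
    }
    unname(tbl[[word]])
  }
})

run_example <- function(name, profile = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- make_example_fixture(name, dir)
  manifest <- suppressWarnings(
    run_pipeline(cfg, out_dir = file.path(dir, "out"), profile = profile)
  )
  manifest
}
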