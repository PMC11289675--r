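test_that("GO statements group by aspect, qualifier and evidence class", {
  # grouping oracle: brute-force group-by on the raw annotation table
  withr::local_seed(7)
  terms <- sprintf("term %d", 1:12)
  ann <- tibble::tibble(
    gene_id = "g1",
    term_id = sprintf("GO:%07d", 1:12),
    term_name = terms,
    aspect = sample(c("molecular_function", "biological_process"), 12,
                    replace = TRUE),
    evidence_code = sample(c("IEA", "IDA"), 12, replace = TRUE),
    qualifier = ifelse(
      sample(c(TRUE, FALSE), 12, replace = TRUE, prob = c(.2, .8)),
      "contributes_to",
      NA
    )
  )
  ann$qualifier[is.na(ann$qualifier)] <-
    ifelse(ann$aspect[is.na(ann$qualifier)] == "molecular_function",
           "enables", "involved_in")
  bundle <- build_bundle(
    genes = tibble::tibble(gene_id = "g1", public_name = "g-1",
                           species = "C. elegans"),
    go_annotations = ann
  )
  stmts <- build_go_statements(bundle, "g1")

  expected_groups <- unique(ann[, c("aspect", "qualifier", "evidence_code")])
  expected_groups$class <- ifelse(expected_groups$evidence_code == "IEA",
                                  "predicted", "experimental")
  # contributes_to collapses evidence classes into one template
  key <- function(a, q, cl) paste(a, q, ifelse(q == "contributes_to", "", cl))
  expect_equal(nrow(stmts),
               length(unique(key(expected_groups$aspect,
                                 expected_groups$qualifier,
                                 expected_groups$class))))
  # every annotated term appears exactly once across statements of its group
  expect_setequal(unlist(stmts$items), unique(ann$term_name))
  expect_true(all(stmts$total_count == lengths(stmts$items)))
})

test_that("five same-group annotations produce one statement with total count five", {
  ann <- tibble::tibble(
    gene_id = "g1",
    term_id = sprintf("GO:%07d", 1:5),
    term_name = sprintf("activity %d", 1:5),
    aspect = "molecular_function",
    evidence_code = "IEA",
    qualifier = "enables"
  )
  bundle <- build_bundle(
    genes = tibble::tibble(gene_id = "g1", public_name = "g-1",
                           species = "C. elegans"),
    go_annotations = ann
  )
  stmts <- build_go_statements(bundle, "g1")
  expect_equal(nrow(stmts), 1)
  expect_equal(stmts$total_count, 5L)
  expect_equal(stmts$template_id, "go_predicted_enables")
})

test_that("curated expression statements deduplicate anatomy terms in input order", {
  bundle <- build_bundle(
    genes = tibble::tibble(gene_id = "g1", public_name = "g-1",
                           species = "C. elegans"),
    expression_annotations = tibble::tibble(
      gene_id = "g1",
      anatomy_term_name = c("gonad", "head", "gonad")
    )
  )
  stmt <- build_curated_expression_statement(bundle, "g1")
  expect_equal(stmt$items[[1]], c("gonad", "head"))

  empty <- combo_bundle()
  expect_equal(nrow(build_curated_expression_statement(empty, "subject")), 0)
})

test_that("tied human orthologs contribute the deduplicated union of their diseases", {
  genes <- tibble::tibble(
    gene_id = c("subject", "h1", "h2"),
    public_name = c("subj-1", "HG1", "HG2"),
    species = c("C. elegans", "human", "human")
  )
  bundle <- build_bundle(
    genes = genes,
    disease_annotations = tibble::tibble(
      gene_id = c("h1", "h1", "h2", "h2"),
      disease_term_name = c("disease A", "disease B", "disease B", "disease C")
    ),
    ortholog_records = tibble::tibble(
      subject_gene_id = "subject", subject_species = "C. elegans",
      ortholog_gene_id = c("h1", "h2"), ortholog_symbol = c("HG1", "HG2"),
      ortholog_full_name = "", ortholog_species = "human",
      methods = list(c("m1", "m2"), c("m1", "m2"))
    )
  )
  ranked <- select_best_human_orthologs(bundle, "subject")
  expect_equal(nrow(ranked$selected), 2)
  stmts <- build_ortholog_transfer_statements(bundle, "subject", ranked)
  disease <- stmts[stmts$category == "ortholog_disease", ]
  expect_equal(disease$items[[1]], c("disease A", "disease B", "disease C"))

  empty_ranked <- select_best_human_orthologs(combo_bundle(), "elegans-1")
  expect_equal(
    nrow(build_ortholog_transfer_statements(bundle, "subject", empty_ranked)),
    0
  )
})

test_that("transferred structural-constituent terms split into their own statement", {
  bundle <- combo_bundle()
  # give the human ortholog a structural-constituent enables term
  bundle$go_annotations <- dplyr::bind_rows(
    bundle$go_annotations,
    tibble::tibble(
      gene_id = "human-1", term_id = "GO:0000009",
      term_name = "structural constituent of test cytoskeleton",
      aspect = "molecular_function", evidence_code = "IDA",
      qualifier = "enables"
    )
  )
  ranked <- select_best_human_orthologs(bundle, "subject")
  stmts <- build_ortholog_transfer_statements(bundle, "subject", ranked)
  expect_equal(
    stmts$template_id,
    c("ortholog_disease", "transfer_contributes", "transfer_enables",
      "transfer_structural")
  )
  structural <- stmts[stmts$template_id == "transfer_structural", ]
  expect_equal(structural$items[[1]],
               "structural constituent of test cytoskeleton")
  enables <- stmts[stmts$template_id == "transfer_enables", ]
  expect_false(any(grepl("structural constituent", enables$items[[1]])))
})

test_that("large-scale statements aggregate objects and study types per kind", {
  bundle <- build_bundle(
    genes = tibble::tibble(gene_id = "g1", public_name = "g-1",
                           species = "C. elegans"),
    large_scale_records = tibble::tibble(
      gene_id = "g1",
      kind = c("expression_enrichment", "chemical_regulation",
               "chemical_regulation", "chemical_regulation"),
      object_name = c("male", "chem-1", "chem-2", "chem-1"),
      study_types = list("RNA-seq", c("microarray", "RNA-seq"),
                         "microarray", "RNA-seq")
    )
  )
  stmts <- build_large_scale_statements(bundle, "g1")
  expect_equal(nrow(stmts), 2)
  enr <- stmts[stmts$category == "largescale_enrichment", ]
  expect_equal(enr$items[[1]], "male")
  chem <- stmts[stmts$category == "largescale_chemical_regulation", ]
  expect_equal(chem$total_count, 2L)  # distinct chemicals
  expect_equal(chem$qualifiers[[1]]$study_types, c("microarray", "RNA-seq"))
})

test_that("orthology statements format human and nematode orthologs differently", {
  elegans <- combo_bundle(species = "C. elegans")
  ranked_h <- select_best_human_orthologs(elegans, "subject")
  stmt_h <- build_orthology_statement(elegans, "subject", ranked_h)
  expect_equal(stmt_h$items[[1]], "human HGENE1 (human gene one)")

  briggsae <- combo_bundle(species = "C. briggsae")
  ranked_n <- select_best_nematode_ortholog(briggsae, "subject")
  stmt_n <- build_orthology_statement(briggsae, "subject", ranked_n)
  expect_equal(stmt_n$items[[1]], "C. elegans src-1")
})

test_that("process transfer uses the source gene's biological-process terms", {
  bundle <- combo_bundle(species = "C. briggsae")
  ranked <- select_best_nematode_ortholog(bundle, "subject")
  stmt <- build_elegans_transfer_statement(bundle, "subject", ranked)
  expect_equal(stmt$category, "elegans_process_transfer")
  expect_equal(stmt$items[[1]], "source process")
  expect_equal(stmt$qualifiers[[1]]$species, "C. elegans")

  # source without process annotations -> no statement
  no_bp <- bundle
  no_bp$go_annotations <-
    no_bp$go_annotations[no_bp$go_annotations$aspect != "biological_process", ]
  expect_equal(nrow(build_elegans_transfer_statement(no_bp, "subject", ranked)),
               0)
})

test_that("no builder ever emits a statement with empty items", {
  for (seed in c(5, 23)) {
    bundle <- make_random_bundle(seed = seed, n_genes = 20)
    for (gid in bundle$genes$gene_id) {
      stmts <- build_statements(bundle, gid)
      expect_true(all(lengths(stmts$items) > 0))
      expect_true(all(stmts$total_count >= lengths(stmts$items)))
    }
  }
})
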