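test_that("list realization follows the one/two/many conjunction rules", {
  expect_equal(realize_list("x"), "x")
  expect_equal(realize_list(c("gonad", "head")), "gonad and head")
  expect_equal(realize_list(c("RNA-seq", "tiling array", "microarray")),
               "RNA-seq; tiling array; and microarray")
  expect_equal(realize_list(c("a", "b", "c", "d")), "a; b; c; and d")
  expect_error(realize_list(character()), class = "genesum_empty_items")
})

test_that("count words spell standard English cardinals", {
  expect_equal(count_word(7), "seven")
  expect_equal(count_word(2), "two")
  expect_equal(count_word(21), "twenty-one")
  expect_equal(count_word(15), "fifteen")
  expect_equal(count_word(40), "forty")
  expect_equal(count_word(100), "one hundred")
  expect_equal(count_word(101), "one hundred one")
  expect_equal(count_word(999), "nine hundred ninety-nine")
  expect_error(count_word(0), class = "genesum_count_out_of_range")
  expect_error(count_word(1000), class = "genesum_count_out_of_range")
})

test_that("count words invert uniquely over the whole supported range", {
  words <- vapply(1:999, count_word, character(1))
  expect_equal(anyDuplicated(words), 0)
  expect_equal(vapply(words, word_to_count, numeric(1), USE.NAMES = FALSE),
               as.numeric(1:999))
})

test_that("truncation follows the exemplar/count-word/several rule table", {
  config <- realization_config(exemplar_count = 3, several_threshold = 10)
  # brute-force enumeration of the rule for totals 1..15
  for (total in 1:15) {
    stmt <- new_statement("g", "largescale_chemical_regulation",
                          "largescale_chemical_regulation",
                          sprintf("chem-%d", seq_len(total)),
                          qualifiers = list(study_types = "RNA-seq"))
    out <- truncate_items(stmt, config)
    if (total <= 3) {
      expect_equal(out$prefix, "")
      expect_equal(length(out$shown), total)
    } else {
      expect_equal(out$prefix,
                   if (total >= 10) "several" else count_word(total))
      expect_equal(out$shown, sprintf("chem-%d", 1:3))
    }
  }
  # non-truncating categories never truncate
  domain <- new_statement("g", "protein_domain", "domains",
                          sprintf("dom-%d", 1:4))
  out <- truncate_items(domain, config)
  expect_equal(out$prefix, "")
  expect_equal(length(out$shown), 4)
})

test_that("statements render their full sentences", {
  chem <- new_statement(
    "g", "largescale_chemical_regulation", "largescale_chemical_regulation",
    c("Tunicamycin", "manganese chloride", "multi-walled carbon nanotube",
      sprintf("chem-%d", 4:7)),
    qualifiers = list(study_types = c("microarray", "RNA-seq"))
  )
  expect_equal(
    realize_statement(chem),
    paste("Is affected by seven chemicals including Tunicamycin; manganese",
          "chloride; and multi-walled carbon nanotube based on microarray",
          "and RNA-seq studies.")
  )

  go <- new_statement("g", "go_function", "go_predicted_enables",
                      "protein serine/threonine phosphatase activity")
  expect_equal(realize_statement(go),
               "Predicted to enable protein serine/threonine phosphatase activity.")

  dom <- new_statement("g", "protein_domain", "domains",
                       c("SPRY domain", "B30.2/SPRY domain superfamily",
                         "Concanavalin A-like lectin/glucanase domain superfamily"))
  expect_equal(
    realize_statement(dom),
    paste("Is predicted to encode a protein with the following domains:",
          "SPRY domain; B30.2/SPRY domain superfamily; and Concanavalin",
          "A-like lectin/glucanase domain superfamily.")
  )

  disease <- new_statement("g", "ortholog_disease", "ortholog_disease",
                           sprintf("disease %d", 1:12))
  expect_equal(
    realize_statement(disease),
    paste("Human ortholog(s) of this gene implicated in several diseases,",
          "including disease 1; disease 2; and disease 3.")
  )

  expect_error(
    realize_statement(new_statement("g", "orthology", "no_such_template", "x")),
    class = "genesum_unknown_template"
  )
})

test_that("rendered grammar matches item counts on random statements", {
  withr::local_seed(31)
  config <- realization_config()
  for (i in 1:60) {
    n <- sample(1:12, 1)
    category <- sample(c("protein_domain", "curated_expression",
                         "largescale_gene_regulation", "ortholog_disease"), 1)
    template <- c(protein_domain = "domains",
                  curated_expression = "expressed_in",
                  largescale_gene_regulation = "largescale_gene_regulation",
                  ortholog_disease = "ortholog_disease")[[category]]
    qualifiers <- if (category == "largescale_gene_regulation") {
      list(study_types = sample(c("RNA-seq", "microarray"),
                                sample(1:2, 1)))
    } else {
      list()
    }
    items <- sprintf("item %02d", sample(1:50, n))
    stmt <- new_statement("g", category, template, items,
                          qualifiers = qualifiers)
    sentence <- realize_statement(stmt, config)
    shown <- truncate_items(stmt, config)$shown
    truncating <- category %in% config$truncating_categories
    if (truncating) expect_lte(length(shown), config$exemplar_count)
    else expect_equal(length(shown), n)

    # conjunction rules apply to the item list; study-type suffixes can add
    # their own "and"/"; and", so check statements without a suffix strictly
    if (category != "largescale_gene_regulation") {
      expect_equal(grepl("; and ", sentence, fixed = TRUE),
                   length(shown) >= 3)
      if (length(shown) == 2) expect_true(grepl(" and ", sentence, fixed = TRUE))
      if (length(shown) <= 2) expect_false(grepl(";", sentence, fixed = TRUE))
    }
    expect_true(endsWith(sentence, "."))
    expect_true(grepl("^[A-Z]", sentence))
    # count-word prefixes invert to the statement's total count
    prefix <- truncate_items(stmt, config)$prefix
    if (nzchar(prefix) && prefix != "several") {
      expect_equal(word_to_count(prefix), n)
    }
  }
})

test_that("assembled summaries order sentences by category and ignore input order", {
  bundle <- combo_bundle(with_go = FALSE, with_expression = FALSE)
  stmts <- build_statements(bundle, "subject")
  gene <- bundle$genes[bundle$genes$gene_id == "subject", ]

  base <- assemble_summary(gene, stmts)
  ranks <- match(base$statements$category, statement_categories())
  expect_true(all(diff(ranks) >= 0))
  expect_equal(base$text, paste(base$sentences, collapse = " "))

  withr::local_seed(5)
  for (i in 1:10) {
    perm <- stmts[sample(nrow(stmts)), ]
    expect_equal(assemble_summary(gene, perm)$text, base$text)
  }

  empty <- assemble_summary(gene, stmts[0, ])
  expect_equal(empty$text, "")
  expect_equal(empty$sentences, character())
})

test_that("tidy and glance expose sentences and summary-level counts", {
  bundle <- combo_bundle(with_go = FALSE, with_expression = FALSE)
  s <- summarize_gene(bundle, "subject")
  td <- tidy(s)
  expect_equal(nrow(td), length(s$sentences))
  expect_equal(td$sentence, s$sentences)
  gl <- glance(s)
  expect_equal(gl$n_sentences, length(s$sentences))
  expect_equal(gl$n_characters, nchar(s$text))
})
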