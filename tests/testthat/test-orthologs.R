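test_that("human selection keeps every ortholog tied at the maximal method count", {
  candidates <- tibble::tibble(
    subject_gene_id = "subject",
    subject_species = "C. elegans",
    ortholog_gene_id = c("h-actb", "h-actg1", "h-potee"),
    ortholog_symbol = c("ACTB", "ACTG1", "POTEE"),
    ortholog_full_name = c("actin beta", "actin gamma 1", "POTE E"),
    ortholog_species = "human",
    methods = list(sprintf("m%d", 1:5), sprintf("m%d", 1:5), sprintf("m%d", 1:2))
  )
  bundle <- candidates_bundle(candidates, species = "C. elegans")
  ranked <- select_best_human_orthologs(bundle, "subject")
  expect_equal(ranked$selected$ortholog_symbol, c("ACTB", "ACTG1"))
  expect_equal(ranked$criterion, "human_max_methods")

  none <- candidates_bundle(candidates[0, ], species = "C. elegans")
  expect_equal(nrow(select_best_human_orthologs(none, "subject")$selected), 0)
})

test_that("nematode ranking is lexicographic: method count dominates GO count", {
  candidates <- tibble::tibble(
    subject_gene_id = "subject",
    subject_species = "C. briggsae",
    ortholog_gene_id = c("gene-A", "gene-B"),
    ortholog_symbol = c("sym-A", "sym-B"),
    ortholog_full_name = "",
    ortholog_species = "C. elegans",
    methods = list(sprintf("m%d", 1:4), sprintf("m%d", 1:5))
  )
  bundle <- candidates_bundle(candidates)
  counts <- c("gene-A" = 10L, "gene-B" = 0L)
  ranked <- select_best_nematode_ortholog(bundle, "subject", counts)
  expect_equal(ranked$selected$ortholog_gene_id, "gene-B")

  single <- candidates_bundle(candidates[1, ])
  ranked1 <- select_best_nematode_ortholog(single, "subject", counts)
  expect_equal(ranked1$selected$ortholog_gene_id, "gene-A")
  expect_equal(nrow(ranked1$selected), 1)
})

test_that("the fem-2 fixture selects C. elegans fem-2 as the transfer source", {
  dir <- withr::local_tempdir()
  cfg <- make_example_fixture("fem2", dir)
  bundle <- load_bundle(read_pipeline_config(cfg))
  ranked <- select_best_nematode_ortholog(bundle, "WB-Cbr-fem-2")
  expect_equal(ranked$selected$ortholog_symbol, "fem-2")
  expect_equal(ranked$selected$ortholog_species, "C. elegans")
})

test_that("both selections agree with the brute-force oracle on 200 random candidate sets", {
  withr::local_seed(2024)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    candidates <- random_candidates(n)
    counts_vec <- stats::setNames(sample(0:50, n, replace = TRUE),
                                  candidates$ortholog_gene_id)

    human_bundle <- candidates_bundle(candidates, species = "C. elegans")
    got_h <- select_best_human_orthologs(human_bundle, "subject")$selected
    want_h <- oracle_human(candidates)
    expect_equal(got_h$ortholog_gene_id, want_h$ortholog_gene_id)

    nem_bundle <- candidates_bundle(candidates, species = "C. briggsae")
    got_n <- select_best_nematode_ortholog(nem_bundle, "subject",
                                           counts_vec)$selected
    want_n <- oracle_nematode(candidates, counts_vec)
    expect_equal(got_n$ortholog_gene_id, want_n$ortholog_gene_id)
  }
})

test_that("selection is invariant under candidate input order", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    candidates <- random_candidates(n)
    counts_vec <- stats::setNames(sample(0:20, n, replace = TRUE),
                                  candidates$ortholog_gene_id)
    perm <- candidates[sample(n), ]

    b1 <- candidates_bundle(candidates, species = "C. elegans")
    b2 <- candidates_bundle(perm, species = "C. elegans")
    expect_equal(
      select_best_human_orthologs(b1, "subject")$selected$ortholog_gene_id,
      select_best_human_orthologs(b2, "subject")$selected$ortholog_gene_id
    )

    b3 <- candidates_bundle(candidates, species = "C. briggsae")
    b4 <- candidates_bundle(perm, species = "C. briggsae")
    expect_equal(
      select_best_nematode_ortholog(b3, "subject",
                                    counts_vec)$selected$ortholog_gene_id,
      select_best_nematode_ortholog(b4, "subject",
                                    counts_vec)$selected$ortholog_gene_id
    )
  }
})
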