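#' Assemble an annotation bundle for one run
#'
#' Collects all parsed inputs into a single indexed container keyed by gene.
#' Records whose gene key does not resolve to a row of `genes` are excluded
#' from the per-gene indexes and reported in the dangling-reference table
#' (`$dangling`); dangling references are never fatal.
#'
#' @param genes Tibble in the `genes` schema (`gene_id`, `public_name`,
#'   `species`).
#' @param ontologies Named list of `genesum_ontology` objects (e.g.
#'   `list(go = ...)`).
#' @param go_annotations Tibble from [read_gaf()].
#' @param disease_annotations,expression_annotations,ortholog_records,large_scale_records,domain_records
#'   Tibbles in the corresponding [read_annotation_tsv()] schemas.
#' @return An object of class `genesum_bundle`.
#' @export
build_bundle <- function(genes = empty_annotation_tbl("genes"),
                         ontologies = list(),
                         go_annotations = NULL,
                         disease_annotations = empty_annotation_tbl("disease"),
                         expression_annotations = empty_annotation_tbl("expression"),
                         ortholog_records = empty_annotation_tbl("orthology"),
                         large_scale_records = empty_annotation_tbl("large_scale"),
                         domain_records = empty_annotation_tbl("domains")) {
  if (is.null(go_annotations)) {
    go_annotations <- tibble(
      gene_id = character(), term_id = character(), term_name = character(),
      aspect = character(), evidence_code = character(), qualifier = character()
    )
  }
  genes <- as_tibble(genes)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    genesum_abort(sprintf("Duplicate gene id(s) in bundle: %s.",
                          paste(unique(dup), collapse = ", ")),
                  class = "genesum_duplicate_gene")
  }

  known <- genes$gene_id
  categories <- list(
    go = list(tbl = go_annotations, key = "gene_id"),
    disease = list(tbl = disease_annotations, key = "gene_id"),
    expression = list(tbl = expression_annotations, key = "gene_id"),
    orthology = list(tbl = ortholog_records, key = "subject_gene_id"),
    large_scale = list(tbl = large_scale_records, key = "gene_id"),
    domains = list(tbl = domain_records, key = "gene_id")
  )

  dangling <- list()
  indexed <- list()
  for (nm in names(categories)) {
    tbl <- as_tibble(categories[[nm]]$tbl)
    key <- categories[[nm]]$key
    ok <- tbl[[key]] %in% known
    if (any(!ok)) {
      dangling[[nm]] <- tibble(category = nm, gene_id = tbl[[key]][!ok])
    }
    indexed[[nm]] <- tbl[ok, , drop = FALSE]
  }
  dangling <- if (length(dangling) > 0) bind_rows(dangling) else
    tibble(category = character(), gene_id = character())

  structure(
    list(
      genes = genes,
      ontologies = ontologies,
      go_annotations = indexed$go,
      disease_annotations = indexed$disease,
      expression_annotations = indexed$expression,
      ortholog_records = indexed$orthology,
      large_scale_records = indexed$large_scale,
      domain_records = indexed$domains,
      dangling = dangling
    ),
    class = "genesum_bundle"
  )
}

#' @export
print.genesum_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("<genesum_bundle> %d genes | GO: %d | disease: %d | expression: %d",
           " | orthology: %d | large-scale: %d | domains: %d | dangling: %d\n"),
    nrow(x$genes), nrow(x$go_annotations), nrow(x$disease_annotations),
    nrow(x$expression_annotations), nrow(x$ortholog_records),
    nrow(x$large_scale_records), nrow(x$domain_records), nrow(x$dangling)
  ))
  invisible(x)
}

#' Per-gene record lookups
#'
#' `gene_records()` returns the indexed records of one category for one gene;
#' `has_go_data()` and `has_expression_data()` are the gating predicates:
#' whether a gene carries at least one curated GO annotation (any aspect, any
#' evidence code) or at least one curated anatomy-ontology expression
#' annotation. Large-scale expression-enrichment records do not count as
#' expression data.
#'
#' @param bundle A `genesum_bundle`.
#' @param gene_id A gene id present in the bundle.
#' @param category One of `"go"`, `"disease"`, `"expression"`, `"orthology"`,
#'   `"large_scale"`, `"domains"`.
#' @return `gene_records()`: a tibble (possibly zero rows); the predicates:
#'   a single logical.
#' @export
gene_records <- function(bundle, gene_id, category) {
  check_known_gene(bundle, gene_id)
  tbl <- switch(category,
    go = bundle$go_annotations,
    disease = bundle$disease_annotations,
    expression = bundle$expression_annotations,
    orthology = bundle$ortholog_records,
    large_scale = bundle$large_scale_records,
    domains = bundle$domain_records,
    genesum_abort(sprintf("Unknown record category: '%s'.", category),
                  class = "genesum_unknown_category")
  )
  key <- if (category == "orthology") "subject_gene_id" else "gene_id"
  tbl[tbl[[key]] == gene_id, , drop = FALSE]
}

#' @rdname gene_records
#' @export
has_go_data <- function(bundle, gene_id) {
  nrow(gene_records(bundle, gene_id, "go")) > 0
}

#' @rdname gene_records
#' @export
has_expression_data <- function(bundle, gene_id) {
  nrow(gene_records(bundle, gene_id, "expression")) > 0
}

#' GO annotation counts per gene
#'
#' Number of indexed GO annotations for every gene in the bundle (zero for
#' genes without any), used to rank nematode ortholog candidates.
#'
#' @param bundle A `genesum_bundle`.
#' @return A named integer vector keyed by gene id.
#' @export
go_annotation_counts <- function(bundle) {
  counts <- table(factor(bundle$go_annotations$gene_id,
                         levels = bundle$genes$gene_id))
  stats::setNames(as.integer(counts), bundle$genes$gene_id)
}
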