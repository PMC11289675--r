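# Shared constants and small helpers.

# Nematode species with gene summaries, plus "human" for ortholog records.
GENESUM_SPECIES <- c(
  "C. elegans", "C. brenneri", "C. briggsae", "C. japonica", "C. remanei",
  "B. malayi", "O. volvulus", "P. pacificus", "S. ratti", "T. muris"
)

GO_ASPECTS <- c(
  F = "molecular_function",
  P = "biological_process",
  C = "cellular_component"
)

ONTOLOGY_NAMESPACES <- c(unname(GO_ASPECTS), "disease", "anatomy")

GO_QUALIFIERS <- c(
  "enables", "contributes_to", "involved_in", "located_in", "expressed_in"
)

STATEMENT_CATEGORIES <- c(
  "go_function", "go_process", "go_component", "curated_expression",
  "ortholog_disease", "ortholog_function_transfer",
  "largescale_enrichment", "largescale_gene_regulation",
  "largescale_chemical_regulation", "protein_domain", "orthology",
  "elegans_process_transfer"
)

LARGE_SCALE_KINDS <- c(
  "expression_enrichment", "gene_regulation", "chemical_regulation"
)

STUDY_TYPES <- c("RNA-seq", "tiling array", "microarray")

#' Default set of non-experimental GO evidence codes
#'
#' Annotations with these evidence codes are rendered with "Predicted to"
#' phrasing; all other codes are treated as experimental support.
#'
#' @return Character vector of evidence codes.
#' @export
go_predicted_codes <- function() {
  c("IEA", "ISS", "ISO", "IBA", "RCA")
}

genesum_abort <- function(message, class, ...) {
  abort(message, class = c(class, "genesum_error"), ...)
}

check_known_gene <- function(bundle, gene_id) {
  if (!gene_id %in% bundle$genes$gene_id) {
    genesum_abort(
      sprintf("Unknown gene id: '%s'.", gene_id),
      class = "genesum_unknown_gene",
      gene_id = gene_id
    )
  }
  invisible(gene_id)
}

# Ordered union: unique values in first-occurrence order.
ordered_union <- function(x) unique(unlist(x, use.names = FALSE))
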