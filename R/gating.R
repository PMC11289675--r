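# Gating: which statement categories may enter a gene's summary given the
# curated data the gene already has.

#' Gating profiles
#'
#' A gating profile maps each gated statement category to the set of
#' conditions that block it. Two profiles are provided:
#'
#' * `strict` encodes the stated rules literally: ortholog-transferred
#'   statements (disease and molecular function) are blocked when the gene
#'   has any curated GO annotation; large-scale and protein-domain statements
#'   are blocked when the gene has curated GO *or* curated expression
#'   annotations.
#' * `ws292` (the default) matches the behaviour evidenced by production
#'   summaries, where a domain sentence can coexist with curated expression:
#'   identical to `strict` except that large-scale and protein-domain
#'   statements are blocked by curated GO data only.
#'
#' Ungated categories (the gene's own GO statements, curated expression,
#' orthology, and process transfer from a nematode ortholog) always pass.
#'
#' @param name `"ws292"` or `"strict"`.
#' @return A `genesum_gating_profile`: a named list of blocking-condition
#'   vectors (subsets of `"has_go"`, `"has_expression"`) keyed by category.
#' @export
gating_profile <- function(name = c("ws292", "strict")) {
  name <- rlang::arg_match(name)
  rules <- if (name == "strict") {
    list(
      ortholog_disease = "has_go",
      ortholog_function_transfer = "has_go",
      largescale_enrichment = c("has_go", "has_expression"),
      largescale_gene_regulation = c("has_go", "has_expression"),
      largescale_chemical_regulation = c("has_go", "has_expression"),
      protein_domain = c("has_go", "has_expression")
    )
  } else {
    list(
      ortholog_disease = "has_go",
      ortholog_function_transfer = "has_go",
      largescale_enrichment = "has_go",
      largescale_gene_regulation = "has_go",
      largescale_chemical_regulation = "has_go",
      protein_domain = "has_go"
    )
  }
  structure(list(name = name, rules = rules),
            class = "genesum_gating_profile")
}

#' @export
print.genesum_gating_profile <- function(x, ...) {
  cat(sprintf("<gating profile '%s'>\n", x$name))
  for (cat_name in names(x$rules)) {
    cat(sprintf("  %s blocked by: %s\n", cat_name,
                paste(x$rules[[cat_name]], collapse = " | ")))
  }
  invisible(x)
}

#' Filter statements by the gating rules
#'
#' Removes statements whose category is blocked for the gene under the given
#' profile. Filtering only: surviving statements are returned unchanged, in
#' their input order.
#'
#' @param statements A statement tibble (all rows for one gene).
#' @param gene_id The subject gene id.
#' @param bundle A `genesum_bundle` (consulted for the gene's curated data).
#' @param profile A `genesum_gating_profile`.
#' @return The surviving statement tibble.
#' @export
apply_gating <- function(statements, gene_id, bundle,
                         profile = gating_profile()) {
  if (nrow(statements) == 0) return(statements)
  state <- c(
    has_go = has_go_data(bundle, gene_id),
    has_expression = has_expression_data(bundle, gene_id)
  )
  blocked <- map_lgl(statements$category, function(cat_name) {
    conditions <- profile$rules[[cat_name]]
    !is.null(conditions) && any(state[conditions])
  })
  statements[!blocked, , drop = FALSE]
}
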