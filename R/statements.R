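# Statement builders: one tibble row per candidate summary sentence.
# Building and gating are separate stages; builders never consult the gating
# profile, so a statement may be built here and removed by apply_gating().

#' Construct a statement table row
#'
#' Statements are the intermediate representation between annotation records
#' and rendered sentences: category-tagged, with an ordered item list, the
#' total count behind any truncation, and template qualifiers (ortholog
#' symbol, source species, study types).
#'
#' @param gene_id Subject gene id.
#' @param category One of the summary statement categories (see
#'   [statement_categories()]).
#' @param template_id Template identifier understood by [realize_statement()].
#' @param items Ordered character vector of term/object names; must be
#'   non-empty.
#' @param total_count Total number of entities the statement covers
#'   (`>= length(items)`).
#' @param qualifiers Named list of template qualifiers.
#' @return A one-row statement tibble.
#' @export
new_statement <- function(gene_id, category, template_id, items,
                          total_count = length(items), qualifiers = list()) {
  stopifnot(length(items) > 0, total_count >= length(items))
  if (!category %in% STATEMENT_CATEGORIES) {
    genesum_abort(sprintf("Unknown statement category: '%s'.", category),
                  class = "genesum_unknown_category")
  }
  tibble(
    gene_id = gene_id,
    category = category,
    template_id = template_id,
    items = list(as.character(items)),
    total_count = as.integer(total_count),
    qualifiers = list(qualifiers),
    prefix_word = NA_character_
  )
}

#' Statement categories in default summary order
#' @return Character vector of category names.
#' @export
statement_categories <- function() STATEMENT_CATEGORIES

empty_statements <- function() {
  tibble(
    gene_id = character(), category = character(), template_id = character(),
    items = list(), total_count = integer(), qualifiers = list(),
    prefix_word = character()
  )
}

# ---- strategy: the gene's own curated GO annotations ------------------------

GO_CATEGORY_BY_ASPECT <- c(
  molecular_function = "go_function",
  biological_process = "go_process",
  cellular_component = "go_component"
)

#' Build GO statements from a gene's own annotations
#'
#' Annotations are grouped by (aspect, qualifier, evidence class); each group
#' yields one statement whose items are the distinct term names in annotation
#' order. Evidence codes in `predicted_codes` render with "Predicted to"
#' phrasing; any other code is treated as experimental. The `contributes_to`
#' qualifier always renders as "Contributes to" regardless of evidence.
#'
#' @param bundle A `genesum_bundle`.
#' @param gene_id Gene id in the bundle.
#' @param predicted_codes Evidence codes treated as non-experimental.
#' @return A statement tibble (zero rows when the gene has no GO annotations).
#' @export
build_go_statements <- function(bundle, gene_id,
                                predicted_codes = go_predicted_codes()) {
  ann <- gene_records(bundle, gene_id, "go")
  if (nrow(ann) == 0) return(empty_statements())
  ann <- mutate(ann, evidence_class = ifelse(
    evidence_code %in% predicted_codes, "predicted", "experimental"
  ))
  groups <- ann |>
    mutate(.row = row_number()) |>
    group_by(aspect, qualifier, .data$evidence_class) |>
    summarise(
      items = list(unique(term_name)),
      total_count = length(unique(term_name)),
      .first = min(.data$.row),
      .groups = "drop"
    ) |>
    arrange(.data$.first)

  bind_rows(pmap(groups, function(aspect, qualifier, evidence_class,
                                  items, total_count, .first) {
    template_id <- if (qualifier == "contributes_to") {
      "go_contributes_to"
    } else {
      paste0("go_", if (evidence_class == "predicted") "predicted_" else "",
             qualifier)
    }
    new_statement(gene_id, unname(GO_CATEGORY_BY_ASPECT[aspect]),
                  template_id, items, total_count)
  }))
}

# ---- strategy: curated anatomy-ontology expression --------------------------

#' Build the curated-expression statement
#'
#' @inheritParams build_go_statements
#' @return A statement tibble with zero or one row ("Expressed in ...");
#'   items are the distinct anatomy term names in input order.
#' @export
build_curated_expression_statement <- function(bundle, gene_id) {
  rec <- gene_records(bundle, gene_id, "expression")
  if (nrow(rec) == 0) return(empty_statements())
  new_statement(gene_id, "curated_expression", "expressed_in",
                unique(rec$anatomy_term_name))
}

# ---- strategy 1(i): transfer from best human orthologs ----------------------

#' Build disease and molecular-function statements transferred from human
#' orthologs
#'
#' From the selected human orthologs of a C. elegans gene, produces (a) one
#' disease statement from the deduplicated union of the orthologs' disease
#' annotations and (b), per ortholog, molecular-function statements: terms
#' annotated with the `contributes_to` qualifier, terms annotated with
#' `enables`, and — as a separate sentence — any transferred term whose name
#' begins with "structural constituent".
#'
#' @inheritParams build_go_statements
#' @param ranked A `genesum_ranked_orthologs` from
#'   [select_best_human_orthologs()].
#' @return A statement tibble; empty when no ortholog was selected.
#' @export
build_ortholog_transfer_statements <- function(bundle, gene_id, ranked) {
  if (nrow(ranked$selected) == 0) return(empty_statements())
  out <- list()

  diseases <- ordered_union(map(ranked$selected$ortholog_gene_id, function(og) {
    if (!og %in% bundle$genes$gene_id) return(character())
    gene_records(bundle, og, "disease")$disease_term_name
  }))
  if (length(diseases) > 0) {
    out[[length(out) + 1L]] <- new_statement(
      gene_id, "ortholog_disease", "ortholog_disease", diseases
    )
  }

  for (i in seq_len(nrow(ranked$selected))) {
    og <- ranked$selected$ortholog_gene_id[[i]]
    symbol <- ranked$selected$ortholog_symbol[[i]]
    if (!og %in% bundle$genes$gene_id) next
    ann <- gene_records(bundle, og, "go")
    ann <- filter(ann, aspect == "molecular_function")
    if (nrow(ann) == 0) next

    contributes <- unique(ann$term_name[ann$qualifier == "contributes_to"])
    enables <- unique(ann$term_name[ann$qualifier == "enables"])
    structural <- enables[str_starts(enables, "structural constituent")]
    enables <- setdiff(enables, structural)

    if (length(contributes) > 0) {
      out[[length(out) + 1L]] <- new_statement(
        gene_id, "ortholog_function_transfer", "transfer_contributes",
        contributes, qualifiers = list(symbol = symbol)
      )
    }
    if (length(enables) > 0) {
      out[[length(out) + 1L]] <- new_statement(
        gene_id, "ortholog_function_transfer", "transfer_enables",
        enables, qualifiers = list(symbol = symbol)
      )
    }
    if (length(structural) > 0) {
      out[[length(out) + 1L]] <- new_statement(
        gene_id, "ortholog_function_transfer", "transfer_structural",
        structural, qualifiers = list(symbol = symbol)
      )
    }
  }
  if (length(out) == 0) empty_statements() else bind_rows(out)
}

# ---- strategy 1(ii): process transfer from the best nematode ortholog -------

#' Build the biological-process statement transferred from the best related
#' nematode ortholog
#'
#' @inheritParams build_go_statements
#' @param ranked A `genesum_ranked_orthologs` from
#'   [select_best_nematode_ortholog()].
#' @return A statement tibble with zero or one row
#'   ("In \{species\}, \{gene\} is involved in ..."); absent when no ortholog
#'   was selected or the source gene carries no biological-process
#'   annotations.
#' @export
build_elegans_transfer_statement <- function(bundle, gene_id, ranked) {
  if (nrow(ranked$selected) == 0) return(empty_statements())
  og <- ranked$selected$ortholog_gene_id[[1]]
  if (!og %in% bundle$genes$gene_id) return(empty_statements())
  ann <- gene_records(bundle, og, "go")
  processes <- unique(ann$term_name[ann$aspect == "biological_process"])
  if (length(processes) == 0) return(empty_statements())
  new_statement(
    gene_id, "elegans_process_transfer", "process_transfer", processes,
    qualifiers = list(species = ranked$selected$ortholog_species[[1]],
                      symbol = ranked$selected$ortholog_symbol[[1]])
  )
}

# ---- strategy 2: large-scale expression / regulation records ----------------

LARGESCALE_CATEGORY <- c(
  expression_enrichment = "largescale_enrichment",
  gene_regulation = "largescale_gene_regulation",
  chemical_regulation = "largescale_chemical_regulation"
)

#' Build statements from collated large-scale study records
#'
#' Produces up to three statements per gene — expression enrichment, gene
#' regulation and chemical regulation. Objects (tissues/stages, regulator
#' genes, chemicals) are deduplicated in input order; the study-type
#' qualifier is the ordered union over the contributing records; the total
#' count is the number of distinct objects.
#'
#' @inheritParams build_go_statements
#' @return A statement tibble with zero to three rows.
#' @export
build_large_scale_statements <- function(bundle, gene_id) {
  rec <- gene_records(bundle, gene_id, "large_scale")
  if (nrow(rec) == 0) return(empty_statements())
  out <- list()
  for (k in LARGE_SCALE_KINDS) {
    sub <- rec[rec$kind == k, , drop = FALSE]
    if (nrow(sub) == 0) next
    objects <- unique(sub$object_name)
    out[[length(out) + 1L]] <- new_statement(
      gene_id, unname(LARGESCALE_CATEGORY[k]), paste0("largescale_", k),
      objects, total_count = length(objects),
      qualifiers = list(study_types = ordered_union(sub$study_types))
    )
  }
  bind_rows(out)
}

# ---- strategy 3: InterPro protein domains -----------------------------------

#' Build the protein-domain statement
#'
#' @inheritParams build_go_statements
#' @return A statement tibble with zero or one row ("Is predicted to encode a
#'   protein with the following domains: ..."); items are the distinct domain
#'   names in input order, never truncated.
#' @export
build_domain_statement <- function(bundle, gene_id) {
  rec <- gene_records(bundle, gene_id, "domains")
  if (nrow(rec) == 0) return(empty_statements())
  new_statement(gene_id, "protein_domain", "domains",
                unique(rec$domain_name))
}

# ---- orthology statement ----------------------------------------------------

#' Build the orthology statement
#'
#' Renders "Is an ortholog of \{species\} \{symbol\}". For human orthologs the
#' full gene name is appended in parentheses; tied human orthologs are all
#' listed.
#'
#' @inheritParams build_go_statements
#' @param ranked A `genesum_ranked_orthologs`.
#' @return A statement tibble with zero or one row.
#' @export
build_orthology_statement <- function(bundle, gene_id, ranked) {
  sel <- ranked$selected
  if (nrow(sel) == 0) return(empty_statements())
  items <- pmap(sel, function(ortholog_species, ortholog_symbol,
                              ortholog_full_name, ...) {
    if (ortholog_species == "human" && nzchar(ortholog_full_name)) {
      sprintf("human %s (%s)", ortholog_symbol, ortholog_full_name)
    } else {
      sprintf("%s %s", ortholog_species, ortholog_symbol)
    }
  })
  new_statement(gene_id, "orthology", "orthology", unlist(items))
}

# ---- per-gene driver --------------------------------------------------------

#' Build all candidate statements for one gene
#'
#' Runs every applicable builder for the gene: its own GO and curated
#' expression statements; for C. elegans genes, transfer from the
#' best-supported human orthologs; for other species, process transfer from
#' the best related-nematode ortholog; large-scale statements; the domain
#' statement; and the orthology statement. The result is ungated — pass it
#' through [apply_gating()] before realization.
#'
#' @inheritParams build_go_statements
#' @param go_counts Named GO-annotation counts used by nematode ortholog
#'   ranking; defaults to counts over the bundle.
#' @return A statement tibble.
#' @export
build_statements <- function(bundle, gene_id,
                             predicted_codes = go_predicted_codes(),
                             go_counts = go_annotation_counts(bundle)) {
  check_known_gene(bundle, gene_id)
  species <- bundle$genes$species[match(gene_id, bundle$genes$gene_id)]
  ranked <- if (identical(species, "C. elegans")) {
    select_best_human_orthologs(bundle, gene_id)
  } else {
    select_best_nematode_ortholog(bundle, gene_id, go_counts)
  }

  bind_rows(
    build_go_statements(bundle, gene_id, predicted_codes),
    build_curated_expression_statement(bundle, gene_id),
    if (identical(species, "C. elegans")) {
      build_ortholog_transfer_statements(bundle, gene_id, ranked)
    },
    build_large_scale_statements(bundle, gene_id),
    build_domain_statement(bundle, gene_id),
    build_orthology_statement(bundle, gene_id, ranked),
    if (!identical(species, "C. elegans")) {
      build_elegans_transfer_statement(bundle, gene_id, ranked)
    }
  )
}
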