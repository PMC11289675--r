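new_ranked_orthologs <- function(subject_gene_id, selected, criterion) {
  structure(
    list(subject_gene_id = subject_gene_id,
         selected = selected,
         criterion = criterion),
    class = "genesum_ranked_orthologs"
  )
}

#' @export
print.genesum_ranked_orthologs <- function(x, ...) {
  cat(sprintf("<ranked orthologs> subject %s, criterion %s: %s\n",
              x$subject_gene_id, x$criterion,
              if (nrow(x$selected) == 0) "(none)"
              else paste(x$selected$ortholog_symbol, collapse = ", ")))
  invisible(x)
}

#' Select the best-supported human orthologs of a C. elegans gene
#'
#' Among a gene's human ortholog candidates, keeps every record whose
#' prediction-method count equals the maximum over all candidates — when
#' several human genes tie on method support, all are retained and their
#' transferred annotations are later merged. Selected records are ordered
#' lexicographically by ortholog symbol for determinism.
#'
#' @param bundle A `genesum_bundle`.
#' @param gene_id A C. elegans gene id in the bundle.
#' @return A `genesum_ranked_orthologs` object with criterion
#'   `"human_max_methods"`; the selected table is empty when the gene has no
#'   human orthologs.
#' @export
select_best_human_orthologs <- function(bundle, gene_id) {
  check_known_gene(bundle, gene_id)
  candidates <- gene_records(bundle, gene_id, "orthology")
  candidates <- filter(candidates, ortholog_species == "human")
  if (nrow(candidates) == 0) {
    return(new_ranked_orthologs(gene_id, candidates, "human_max_methods"))
  }
  candidates <- mutate(candidates, n_methods = lengths(methods))
  selected <- filter(candidates, n_methods == max(n_methods))
  selected <- arrange(selected, ortholog_symbol)
  selected$n_methods <- NULL
  new_ranked_orthologs(gene_id, selected, "human_max_methods")
}

#' Select the single best related-nematode ortholog of a non-elegans gene
#'
#' Candidates are ranked by prediction-method count, then by the number of GO
#' annotations carried by the ortholog gene, both descending. Remaining ties
#' are broken by species priority (C. elegans first, then alphabetical
#' species tag) and finally by ortholog symbol. Exactly one candidate (or
#' none) is returned.
#'
#' @param bundle A `genesum_bundle`.
#' @param gene_id A non-elegans gene id in the bundle.
#' @param go_counts Named integer vector of GO annotation counts per gene id;
#'   defaults to [go_annotation_counts()] over the bundle. Candidates absent
#'   from the map count as zero.
#' @return A `genesum_ranked_orthologs` object with criterion
#'   `"nematode_methods_then_go"`; `selected` has at most one row.
#' @export
select_best_nematode_ortholog <- function(bundle, gene_id,
                                          go_counts = go_annotation_counts(bundle)) {
  check_known_gene(bundle, gene_id)
  candidates <- gene_records(bundle, gene_id, "orthology")
  if (nrow(candidates) == 0) {
    return(new_ranked_orthologs(gene_id, candidates, "nematode_methods_then_go"))
  }
  counts <- go_counts[candidates$ortholog_gene_id]
  counts[is.na(counts)] <- 0L
  ranked <- candidates |>
    mutate(
      n_methods = lengths(methods),
      go_count = as.integer(counts),
      species_rank = ifelse(ortholog_species == "C. elegans", 0L, 1L)
    ) |>
    arrange(desc(n_methods), desc(go_count), species_rank,
            ortholog_species, ortholog_symbol)
  selected <- ranked[1, , drop = FALSE]
  selected$n_methods <- selected$go_count <- selected$species_rank <- NULL
  new_ranked_orthologs(gene_id, selected, "nematode_methods_then_go")
}
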