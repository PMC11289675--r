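#' Generate the summary for one gene
#'
#' End-to-end per-gene flow: build all candidate statements, gate them
#' against the gene's curated data, and realize the surviving statements as
#' an ordered paragraph.
#'
#' @param bundle A `genesum_bundle`.
#' @param gene_id Gene id in the bundle.
#' @param profile A [gating_profile()] (default `"ws292"`).
#' @param config A [realization_config()].
#' @param predicted_codes Evidence codes treated as non-experimental.
#' @param go_counts GO-annotation counts used by nematode ortholog ranking.
#' @return A `genesum_summary`.
#' @export
summarize_gene <- function(bundle, gene_id,
                           profile = gating_profile(),
                           config = realization_config(),
                           predicted_codes = go_predicted_codes(),
                           go_counts = go_annotation_counts(bundle)) {
  check_known_gene(bundle, gene_id)
  statements <- build_statements(bundle, gene_id, predicted_codes, go_counts)
  statements <- apply_gating(statements, gene_id, bundle, profile)
  gene <- bundle$genes[bundle$genes$gene_id == gene_id, , drop = FALSE]
  assemble_summary(gene, statements, config)
}

#' Generate summaries for a set of genes
#'
#' @param bundle A `genesum_bundle`.
#' @param species Optional species tag; when given, only genes of that
#'   species are summarized.
#' @param keep_empty Keep genes whose summary has no sentences
#'   (default `FALSE`).
#' @inheritParams summarize_gene
#' @return A tibble with one row per summarized gene: `gene_id`,
#'   `public_name`, `species`, `description`, `n_statements`, and list-columns
#'   `sentences` and `statements`.
#' @export
summarize_genes <- function(bundle, species = NULL,
                            profile = gating_profile(),
                            config = realization_config(),
                            predicted_codes = go_predicted_codes(),
                            keep_empty = FALSE) {
  genes <- bundle$genes
  if (!is.null(species)) genes <- filter(genes, .data$species == !!species)
  go_counts <- go_annotation_counts(bundle)
  summaries <- map(genes$gene_id, function(gid) {
    summarize_gene(bundle, gid, profile, config, predicted_codes, go_counts)
  })
  out <- tibble(
    gene_id = map_chr(summaries, "gene_id"),
    public_name = map_chr(summaries, "public_name"),
    species = map_chr(summaries, "species"),
    description = map_chr(summaries, "text"),
    n_statements = map_int(summaries, ~ nrow(.x$statements)),
    sentences = map(summaries, "sentences"),
    statements = map(summaries, "statements")
  )
  if (!keep_empty) out <- filter(out, nzchar(description))
  out
}

#' Tidy a gene summary into one row per sentence
#'
#' @param x A `genesum_summary`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `position`, `category`,
#'   `sentence`.
#' @export
tidy.genesum_summary <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    position = seq_along(x$sentences),
    category = x$statements$category,
    sentence = x$sentences
  )
}

#' One-row overview of a gene summary
#'
#' @param x A `genesum_summary`.
#' @param ... Unused.
#' @return A one-row tibble with the gene, its sentence count, total item
#'   count and character length of the summary.
#' @export
glance.genesum_summary <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    public_name = x$public_name,
    species = x$species,
    n_sentences = length(x$sentences),
    n_items = sum(lengths(x$statements$items)),
    n_characters = nchar(x$text)
  )
}

#' Plot statement-category counts for a summary table
#'
#' Bar chart of how many statements each category contributed across the
#' summaries produced by [summarize_genes()] — the per-category column
#' structure of a run manifest, at whatever scale the input bundle has.
#'
#' @param object A tibble returned by [summarize_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genesum_summary_set <- function(object, ...) {
  counts <- object |>
    tidyr::unnest(statements) |>
    count(category)
  counts$category <- factor(counts$category, levels = rev(statement_categories()))
  ggplot(counts, aes(x = category, y = n)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "statements",
         title = "Statements per category")
}

#' @rdname autoplot.genesum_summary_set
#' @param summaries A tibble returned by [summarize_genes()].
#' @export
plot_statement_counts <- function(summaries, ...) {
  class(summaries) <- c("genesum_summary_set", class(summaries))
  autoplot(summaries, ...)
}
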