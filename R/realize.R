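# Text realization: statements -> English sentences -> assembled summary.

#' Realization configuration
#'
#' Controls exemplar truncation and sentence ordering.
#'
#' Truncating categories list at most `exemplar_count` exemplars when the
#' total count exceeds it; the list is prefixed by the spelled-out count
#' ("seven chemicals") for totals below `several_threshold` and by "several"
#' at or above it. Non-truncating categories always list every item.
#'
#' @param exemplar_count Number of exemplars shown when truncating
#'   (default 3).
#' @param several_threshold Totals at or above this render "several"; totals
#'   between `exemplar_count + 1` and `several_threshold - 1` render the
#'   spelled-out count word (default 10).
#' @param category_order Order in which categories appear in a summary.
#' @param truncating_categories Categories subject to exemplar truncation.
#' @return A `genesum_realization_config`.
#' @export
realization_config <- function(exemplar_count = 3,
                               several_threshold = 10,
                               category_order = statement_categories(),
                               truncating_categories = c(
                                 "ortholog_disease",
                                 "ortholog_function_transfer",
                                 "largescale_gene_regulation",
                                 "largescale_chemical_regulation"
                               )) {
  stopifnot(exemplar_count >= 1, several_threshold > exemplar_count)
  structure(
    list(exemplar_count = as.integer(exemplar_count),
         several_threshold = as.integer(several_threshold),
         category_order = category_order,
         truncating_categories = truncating_categories),
    class = "genesum_realization_config"
  )
}

#' Realize an item list as English
#'
#' One item stands alone; two are joined with "and"; three or more are
#' joined with semicolons, with "; and" before the last.
#'
#' @param items Non-empty character vector.
#' @return A single string.
#' @export
#' @examples
#' realize_list(c("gonad", "head"))
#' realize_list(c("RNA-seq", "tiling array", "microarray"))
realize_list <- function(items) {
  n <- length(items)
  if (n == 0) {
    genesum_abort("Cannot realize an empty item list.",
                  class = "genesum_empty_items")
  }
  if (n == 1) return(items[[1]])
  if (n == 2) return(paste(items[[1]], "and", items[[2]]))
  paste0(paste(items[-n], collapse = "; "), "; and ", items[[n]])
}

ONES_WORDS <- c(
  "one", "two", "three", "four", "five", "six", "seven", "eight", "nine",
  "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen", "sixteen",
  "seventeen", "eighteen", "nineteen"
)
TENS_WORDS <- c(
  "twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty", "ninety"
)

#' Spell an integer as a lowercase English cardinal
#'
#' @param n Integer between 1 and 999.
#' @return A lowercase cardinal word, hyphenating tens-ones compounds
#'   ("twenty-one").
#' @export
#' @examples
#' count_word(7)
#' count_word(21)
count_word <- function(n) {
  if (length(n) != 1 || is.na(n) || n != as.integer(n) || n < 1 || n > 999) {
    genesum_abort("count_word() requires a single integer in 1..999.",
                  class = "genesum_count_out_of_range")
  }
  n <- as.integer(n)
  below_hundred <- function(k) {
    if (k == 0) return("")
    if (k < 20) return(ONES_WORDS[[k]])
    tens <- TENS_WORDS[[k %/% 10 - 1]]
    if (k %% 10 == 0) tens else paste0(tens, "-", ONES_WORDS[[k %% 10]])
  }
  if (n < 100) return(below_hundred(n))
  rest <- below_hundred(n %% 100)
  hundreds <- paste(ONES_WORDS[[n %/% 100]], "hundred")
  if (rest == "") hundreds else paste(hundreds, rest)
}

#' Truncate a statement's item list for rendering
#'
#' For truncating categories with more entities than `exemplar_count`, keeps
#' the first `exemplar_count` items (in statement item order) and computes the
#' count prefix: the spelled-out total below `several_threshold`, "several"
#' at or above it. Other statements pass through untouched with an empty
#' prefix.
#'
#' @param statement A one-row statement tibble.
#' @param config A [realization_config()].
#' @return A list with elements `prefix` (string, possibly `""`) and `shown`
#'   (character vector of items to render).
#' @export
truncate_items <- function(statement, config = realization_config()) {
  items <- statement$items[[1]]
  total <- statement$total_count[[1]]
  truncating <- statement$category[[1]] %in% config$truncating_categories
  if (!truncating || total <= config$exemplar_count) {
    return(list(prefix = "", shown = items))
  }
  prefix <- if (total >= config$several_threshold) "several"
            else count_word(total)
  list(prefix = prefix, shown = items[seq_len(config$exemplar_count)])
}

# Template table: opening text, the noun used in truncated form, whether a
# comma precedes "including", and whether a study-type suffix applies.
template_spec <- function(template_id, qualifiers) {
  switch(template_id,
    go_predicted_enables = list(opening = "Predicted to enable"),
    go_enables = list(opening = "Enables"),
    go_contributes_to = list(opening = "Contributes to"),
    go_predicted_involved_in = list(opening = "Predicted to be involved in"),
    go_involved_in = list(opening = "Is involved in"),
    go_predicted_located_in = list(opening = "Predicted to be located in"),
    go_located_in = list(opening = "Located in"),
    go_predicted_expressed_in = list(opening = "Predicted to be expressed in"),
    go_expressed_in = list(opening = "Is expressed in"),
    expressed_in = list(opening = "Expressed in"),
    ortholog_disease = list(
      opening = "Human ortholog(s) of this gene implicated in",
      noun = "diseases", comma = TRUE
    ),
    transfer_contributes = list(
      opening = sprintf("Human %s Contributes to", qualifiers$symbol),
      noun = "functions", comma = TRUE
    ),
    transfer_enables = list(
      opening = sprintf("Human %s enables", qualifiers$symbol),
      noun = "functions", comma = TRUE
    ),
    transfer_structural = list(opening = "A"),
    largescale_expression_enrichment = list(
      opening = "Enriched in", studies = TRUE
    ),
    largescale_gene_regulation = list(
      opening = "Is affected by", noun = "genes", comma = FALSE, studies = TRUE
    ),
    largescale_chemical_regulation = list(
      opening = "Is affected by", noun = "chemicals", comma = FALSE,
      studies = TRUE
    ),
    domains = list(
      opening = "Is predicted to encode a protein with the following domains:"
    ),
    orthology = list(opening = "Is an ortholog of"),
    process_transfer = list(
      opening = sprintf("In %s, %s is involved in",
                        qualifiers$species, qualifiers$symbol)
    ),
    genesum_abort(sprintf("Unknown template id: '%s'.", template_id),
                  class = "genesum_unknown_template")
  )
}

#' Render one statement as an English sentence
#'
#' Applies the statement's template: the (possibly truncated) item list is
#' realized with [realize_list()]; truncated lists are introduced by
#' "including" (with a preceding comma for disease and transferred-function
#' templates); large-scale templates append the study-type qualifier as
#' "based on ... studies". Every sentence ends with a period.
#'
#' @param statement A one-row statement tibble.
#' @param config A [realization_config()].
#' @return A single sentence string.
#' @export
realize_statement <- function(statement, config = realization_config()) {
  qualifiers <- statement$qualifiers[[1]]
  spec <- template_spec(statement$template_id[[1]], qualifiers)
  trunc <- truncate_items(statement, config)

  body <- if (nzchar(trunc$prefix)) {
    joiner <- if (isTRUE(spec$comma)) ", including " else " including "
    paste0(trunc$prefix, " ", spec$noun, joiner, realize_list(trunc$shown))
  } else {
    realize_list(trunc$shown)
  }

  sentence <- paste(spec$opening, body)
  if (isTRUE(spec$studies)) {
    sentence <- paste0(sentence, " based on ",
                       realize_list(qualifiers$study_types), " studies")
  }
  paste0(sentence, ".")
}

# Canonical template precedence within a category (fixes sentence order no
# matter the order in which builders emitted the statements).
TEMPLATE_ORDER <- c(
  "go_enables", "go_predicted_enables", "go_contributes_to",
  "go_involved_in", "go_predicted_involved_in",
  "go_located_in", "go_predicted_located_in",
  "go_expressed_in", "go_predicted_expressed_in",
  "expressed_in", "ortholog_disease",
  "transfer_contributes", "transfer_enables", "transfer_structural",
  "largescale_expression_enrichment", "largescale_gene_regulation",
  "largescale_chemical_regulation", "domains", "orthology",
  "process_transfer"
)

#' Assemble a gene summary from gated statements
#'
#' Sentences are ordered by the configured category order (stable within a
#' category) and joined with single spaces.
#'
#' @param gene A one-row tibble (or named list) with `gene_id`,
#'   `public_name`, `species`.
#' @param statements A gated statement tibble for the gene.
#' @param config A [realization_config()].
#' @return A `genesum_summary`: list with `gene_id`, `public_name`,
#'   `species`, `sentences` (character vector) and `text` (single string,
#'   `""` when no statements survive).
#' @export
assemble_summary <- function(gene, statements,
                             config = realization_config()) {
  # category order first; within a category, a fixed template precedence and
  # the ortholog symbol break ties, so assembly is invariant to the order in
  # which statements were built
  symbol_key <- map_chr(statements$qualifiers, ~ .x$symbol %||% "")
  first_item <- map_chr(statements$items, ~ .x[[1]] %||% "")
  ord <- order(match(statements$category, config$category_order),
               match(statements$template_id, TEMPLATE_ORDER),
               symbol_key, first_item)
  statements <- statements[ord, , drop = FALSE]
  sentences <- if (nrow(statements) == 0) character() else
    map_chr(seq_len(nrow(statements)), function(i) {
      realize_statement(statements[i, , drop = FALSE], config)
    })
  structure(
    list(
      gene_id = gene$gene_id[[1]],
      public_name = gene$public_name[[1]],
      species = gene$species[[1]],
      sentences = sentences,
      text = paste(sentences, collapse = " "),
      statements = statements
    ),
    class = "genesum_summary"
  )
}

#' @export
print.genesum_summary <- function(x, ...) {
  cat(sprintf("<gene summary> %s (%s, %s)\n", x$public_name, x$gene_id,
              x$species))
  cat(if (nzchar(x$text)) x$text else "(no summary)", "\n")
  invisible(x)
}
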