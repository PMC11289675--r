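#' Read a minimal OBO ontology file
#'
#' Parses the restricted OBO dialect used by this package: `[Term]` stanzas
#' with `id`, `name`, `namespace` and `is_a` tag lines. Other stanza types
#' (e.g. `[Typedef]`) and other tags (e.g. `relationship:`) are ignored with
#' a single summarising warning. Parent links must form a directed acyclic
#' graph and every parent must resolve to a term in the file.
#'
#' @param path Path to an OBO file.
#' @return An object of class `genesum_ontology`: a list with
#'   * `terms`: a tibble with columns `term_id`, `name`, `namespace` and a
#'     list-column `parents` of parent term ids;
#'   * `namespace`: the single namespace of the file, or `"mixed"` when term
#'     namespaces differ (as in the Gene Ontology's three aspects).
#' @export
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "[Term]", "id: GO:0000001", "name: root process",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child process",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root process"
#' ), obo)
#' ont <- read_obo(obo)
#' ont$terms
read_obo <- function(path) {
  if (!file.exists(path)) {
    genesum_abort(sprintf("OBO file not found: '%s'.", path),
                  class = "genesum_file_not_found")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  in_term <- FALSE
  terms <- list()
  current <- NULL
  unknown_tags <- character()

  flush_term <- function() {
    if (!is.null(current) && !is.null(current$id)) terms[[length(terms) + 1L]] <<- current
    current <<- NULL
  }

  for (raw in lines) {
    line <- str_trim(sub("(?<!\\\\)!.*$", "", raw, perl = TRUE))
    if (line == "") next
    if (str_starts(line, "\\[")) {
      flush_term()
      in_term <- identical(line, "[Term]")
      if (in_term) current <- list(parents = character())
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) < 3) next
    tag <- m[2]
    value <- str_trim(m[3])
    switch(tag,
      id = { current$id <- value },
      name = { current$name <- value },
      namespace = { current$namespace <- value },
      is_a = { current$parents <- c(current$parents, str_trim(strsplit(value, "!", fixed = TRUE)[[1]][1])) },
      { unknown_tags <- c(unknown_tags, tag) }
    )
  }
  flush_term()

  if (length(unknown_tags) > 0) {
    warn(sprintf(
      "Ignored %d OBO tag line(s) outside the supported subset (%s).",
      length(unknown_tags), paste(unique(unknown_tags), collapse = ", ")
    ), class = "genesum_obo_unknown_tag")
  }

  terms_tbl <- tibble(
    term_id = map_chr(terms, ~ .x$id %||% NA_character_),
    name = map_chr(terms, ~ .x$name %||% NA_character_),
    namespace = map_chr(terms, ~ .x$namespace %||% NA_character_),
    parents = map(terms, ~ unique(.x$parents))
  )

  new_ontology(terms_tbl)
}

#' Construct and validate an ontology from a term table
#'
#' @param terms A tibble with columns `term_id`, `name`, `namespace` and a
#'   list-column `parents`.
#' @return A `genesum_ontology` object; errors on duplicate ids, dangling
#'   parent references, or cyclic `is_a` links.
#' @export
new_ontology <- function(terms) {
  terms <- as_tibble(terms)
  dup <- terms$term_id[duplicated(terms$term_id)]
  if (length(dup) > 0) {
    genesum_abort(sprintf("Duplicate term id(s): %s.",
                          paste(unique(dup), collapse = ", ")),
                  class = "genesum_duplicate_term")
  }
  all_parents <- unlist(terms$parents, use.names = FALSE)
  missing <- setdiff(all_parents, terms$term_id)
  if (length(missing) > 0) {
    genesum_abort(
      sprintf("is_a parent '%s' does not resolve to any term.", missing[[1]]),
      class = "genesum_dangling_parent", missing_id = missing[[1]]
    )
  }
  if (nrow(terms) > 0 && length(all_parents) > 0) {
    edges <- tidyr::unnest(terms[, c("term_id", "parents")],
                           cols = "parents")
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$term_id, to = edges$parents),
      directed = TRUE,
      vertices = data.frame(name = terms$term_id)
    )
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      big <- which(comp$csize > 1)
      member <- if (length(big) > 0) {
        names(comp$membership)[comp$membership == big[[1]]][[1]]
      } else {
        # self-loop (term is_a itself)
        igraph::ends(g, igraph::E(g)[igraph::which_loop(g)])[1, 1]
      }
      genesum_abort(
        sprintf("Cyclic is_a links detected involving term '%s'.", member),
        class = "genesum_ontology_cycle", cycle_member = member
      )
    }
  }
  ns <- unique(terms$namespace)
  structure(
    list(terms = terms,
         namespace = if (length(ns) == 1) ns else "mixed"),
    class = "genesum_ontology"
  )
}

#' @export
print.genesum_ontology <- function(x, ...) {
  cat(sprintf("<genesum_ontology> %d terms, namespace: %s\n",
              nrow(x$terms), x$namespace))
  invisible(x)
}

ontology_term_name <- function(ontology, term_id) {
  ontology$terms$name[match(term_id, ontology$terms$term_id)]
}

#' Write an ontology back to the minimal OBO dialect
#'
#' Inverse of [read_obo()] for round-trip checks and fixture generation.
#'
#' @param ontology A `genesum_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  blocks <- pmap(ontology$terms, function(term_id, name, namespace, parents) {
    c("[Term]",
      paste0("id: ", term_id),
      paste0("name: ", name),
      paste0("namespace: ", namespace),
      if (length(parents) > 0) paste0("is_a: ", parents),
      "")
  })
  writeLines(unlist(blocks), path, useBytes = TRUE)
  invisible(path)
}
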