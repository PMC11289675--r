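GAF_NCOL <- 17L

# Default qualifier by GO aspect when the GAF qualifier column is empty.
DEFAULT_QUALIFIER <- c(
  molecular_function = "enables",
  biological_process = "involved_in",
  cellular_component = "located_in"
)

#' Read GO annotations from a GAF 2.2 file
#'
#' Reads a 17-column, tab-separated Gene Association File. Comment lines start
#' with `!`. Rows whose GO term id is absent from `ontology`, or whose aspect
#' letter disagrees with the term's namespace, are dropped with a warning; the
#' number of dropped rows is available as `attr(x, "n_dropped")`.
#'
#' The GAF qualifier column (column 4) is mapped onto
#' `enables`, `contributes_to`, `involved_in`, `located_in`, `expressed_in`;
#' an empty qualifier defaults by aspect (F to `enables`, P to `involved_in`,
#' C to `located_in`).
#'
#' @param path Path to a GAF 2.2 file.
#' @param ontology A `genesum_ontology` containing the GO terms (all aspects).
#' @return A tibble of GO annotations with columns `gene_id`, `term_id`,
#'   `term_name`, `aspect`, `evidence_code`, `qualifier`.
#' @export
read_gaf <- function(path, ontology) {
  if (!file.exists(path)) {
    genesum_abort(sprintf("GAF file not found: '%s'.", path),
                  class = "genesum_file_not_found")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(str_trim(lines))
  rows <- which(keep)

  ann <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[[i]]
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(fields) < GAF_NCOL && endsWith(lines[[ln]], "\t")) {
      fields <- c(fields, rep("", GAF_NCOL - length(fields)))
    }
    if (length(fields) != GAF_NCOL) {
      genesum_abort(
        sprintf("GAF line %d has %d columns; expected %d.",
                ln, length(fields), GAF_NCOL),
        class = "genesum_gaf_columns", line = ln
      )
    }
    fields <- str_trim(fields)
    ann[[i]] <- tibble(
      gene_id = fields[[2]],
      qualifier_raw = fields[[4]],
      term_id = fields[[5]],
      evidence_code = fields[[7]],
      aspect_letter = fields[[9]]
    )
  }
  ann <- if (length(ann) > 0) bind_rows(ann) else tibble(
    gene_id = character(), qualifier_raw = character(),
    term_id = character(), evidence_code = character(),
    aspect_letter = character()
  )

  ann$aspect <- unname(GO_ASPECTS[ann$aspect_letter])
  ann$term_name <- ontology_term_name(ontology, ann$term_id)
  ann$term_namespace <-
    ontology$terms$namespace[match(ann$term_id, ontology$terms$term_id)]

  unknown <- is.na(ann$term_name)
  mismatch <- !unknown & !is.na(ann$aspect) & ann$aspect != ann$term_namespace
  n_dropped <- sum(unknown | mismatch)
  if (n_dropped > 0) {
    warn(sprintf(
      "Dropped %d GAF row(s): %d with term ids absent from the ontology, %d with aspect/namespace mismatch.",
      n_dropped, sum(unknown), sum(mismatch)
    ), class = "genesum_gaf_dropped")
  }
  ann <- ann[!(unknown | mismatch), , drop = FALSE]

  qualifier <- str_trim(sub("^NOT\\|", "", ann$qualifier_raw))
  qualifier <- ifelse(qualifier %in% GO_QUALIFIERS, qualifier,
                      unname(DEFAULT_QUALIFIER[ann$aspect]))

  out <- tibble(
    gene_id = ann$gene_id,
    term_id = ann$term_id,
    term_name = ann$term_name,
    aspect = ann$aspect,
    evidence_code = ann$evidence_code,
    qualifier = qualifier
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GO annotations as a GAF 2.2 file
#'
#' Inverse of [read_gaf()] for round-trip checks and fixture generation.
#' Columns not represented in the annotation tibble are filled with
#' placeholder values.
#'
#' @param annotations A tibble as returned by [read_gaf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  header <- "!gaf-version: 2.2"
  aspect_letter <- names(GO_ASPECTS)[match(annotations$aspect, GO_ASPECTS)]
  rows <- sprintf(
    "WB\t%s\t%s\t%s\t%s\tPMID:0\t%s\t\t%s\t\t\tgene\ttaxon:6239\t20240101\tWB\t\t",
    annotations$gene_id, annotations$gene_id, annotations$qualifier,
    annotations$term_id, annotations$evidence_code, aspect_letter
  )
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
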