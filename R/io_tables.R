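TSV_SCHEMAS <- list(
  genes = c("gene_id", "public_name", "species"),
  disease = c("gene_id", "disease_term_name"),
  expression = c("gene_id", "anatomy_term_name"),
  orthology = c("subject_gene_id", "subject_species", "ortholog_gene_id",
                "ortholog_symbol", "ortholog_full_name", "ortholog_species",
                "methods"),
  large_scale = c("gene_id", "kind", "object_name", "study_types"),
  domains = c("gene_id", "domain_name", "interpro_id")
)

# Columns holding comma-separated sets, split into list-columns on read.
TSV_SET_COLUMNS <- list(orthology = "methods", large_scale = "study_types")

#' Empty annotation table for a schema
#'
#' @param schema One of `"genes"`, `"disease"`, `"expression"`, `"orthology"`,
#'   `"large_scale"`, `"domains"`.
#' @return A zero-row tibble with the schema's columns (set-valued columns as
#'   empty list-columns).
#' @export
empty_annotation_tbl <- function(schema) {
  cols <- TSV_SCHEMAS[[schema]]
  if (is.null(cols)) {
    genesum_abort(sprintf("Unknown table schema: '%s'.", schema),
                  class = "genesum_unknown_schema")
  }
  out <- as_tibble(stats::setNames(
    rep(list(character()), length(cols)), cols
  ))
  for (set_col in TSV_SET_COLUMNS[[schema]]) out[[set_col]] <- list()
  out
}

#' Read an annotation table in one of the fixed TSV schemas
#'
#' Reads a header-bearing, tab-separated annotation table. The supported
#' schemas and their required columns are:
#'
#' * `genes`: `gene_id`, `public_name`, `species`
#' * `disease`: `gene_id` (the human gene), `disease_term_name`
#' * `expression`: `gene_id`, `anatomy_term_name`
#' * `orthology`: `subject_gene_id`, `subject_species`, `ortholog_gene_id`,
#'   `ortholog_symbol`, `ortholog_full_name`, `ortholog_species`, `methods`
#' * `large_scale`: `gene_id`, `kind`, `object_name`, `study_types`
#' * `domains`: `gene_id`, `domain_name`, `interpro_id`
#'
#' `methods` and `study_types` are comma-separated in the file and become
#' list-columns of character sets. All values are whitespace-trimmed and
#' case-sensitive; fully duplicated rows are dropped (first occurrence kept,
#' order otherwise preserved).
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Schema name, see above.
#' @return A tibble of typed records.
#' @export
read_annotation_tsv <- function(path, schema) {
  cols <- TSV_SCHEMAS[[schema]]
  if (is.null(cols)) {
    genesum_abort(sprintf("Unknown table schema: '%s'.", schema),
                  class = "genesum_unknown_schema")
  }
  if (!file.exists(path)) {
    genesum_abort(sprintf("Annotation table not found: '%s'.", path),
                  class = "genesum_file_not_found")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    genesum_abort(
      sprintf("Table '%s' is missing required column '%s' for schema '%s'.",
              path, missing[[1]], schema),
      class = "genesum_missing_column", column = missing[[1]]
    )
  }
  tbl <- tbl[, cols, drop = FALSE]
  tbl <- mutate(tbl, across(all_of(cols), str_trim))
  tbl <- distinct(tbl)

  if (schema == "large_scale") {
    bad <- setdiff(unique(tbl$kind), LARGE_SCALE_KINDS)
    if (length(bad) > 0) {
      genesum_abort(sprintf("Unknown large-scale record kind: '%s'.", bad[[1]]),
                    class = "genesum_unknown_kind")
    }
  }
  for (set_col in TSV_SET_COLUMNS[[schema]]) {
    tbl[[set_col]] <- map(
      str_split(tbl[[set_col]], ","),
      ~ unique(str_trim(.x[nzchar(str_trim(.x))]))
    )
    if (any(lengths(tbl[[set_col]]) == 0)) {
      genesum_abort(
        sprintf("Column '%s' must contain at least one value per row.", set_col),
        class = "genesum_empty_set"
      )
    }
  }
  tbl
}

#' Write an annotation table back to its TSV schema
#'
#' Inverse of [read_annotation_tsv()]: set-valued list-columns are collapsed
#' to comma-separated strings. Re-reading the written file yields an equal
#' record table.
#'
#' @param records A tibble in one of the annotation schemas.
#' @param path Output file path.
#' @param schema Schema name, see [read_annotation_tsv()].
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(records, path, schema) {
  cols <- TSV_SCHEMAS[[schema]]
  if (is.null(cols)) {
    genesum_abort(sprintf("Unknown table schema: '%s'.", schema),
                  class = "genesum_unknown_schema")
  }
  out <- records[, cols, drop = FALSE]
  for (set_col in TSV_SET_COLUMNS[[schema]]) {
    out[[set_col]] <- map_chr(out[[set_col]], paste, collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
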