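# Serialization of summaries to txt / json / tsv, plus the run manifest.
# All writers are byte-deterministic: UTF-8, "\n" newlines, gene_id order.

#' Write gene summaries to disk
#'
#' Writes the requested formats into `out_dir`, plus a `manifest.json`
#' sidecar:
#'
#' * `summaries.txt`: one block per gene — a `gene_id<TAB>public_name` line,
#'   the summary paragraph, and a blank line;
#' * `summaries.tsv`: header `gene_id, public_name, species, description`;
#' * `summaries.json`: an array of objects with those four keys.
#'
#' Rows are sorted by `gene_id`, so runs on identical input produce
#' byte-identical files.
#'
#' @param summaries A tibble from [summarize_genes()] (or any tibble with
#'   columns `gene_id`, `public_name`, `species`, `description`, and
#'   optionally a `statements` list-column for manifest category counts).
#' @param out_dir Output directory (created if absent).
#' @param formats Subset of `c("txt", "json", "tsv")`.
#' @param inputs Character vector of input file paths recorded in the
#'   manifest.
#' @param config_digest Digest string recorded in the manifest.
#' @param n_genes Number of candidate genes of the run (defaults to the
#'   number of summary rows).
#' @return A `genesum_manifest`, invisibly a list with the config digest,
#'   input list, gene and summary counts, per-category statement counts, and
#'   a timestamp. The written `manifest.json` omits the timestamp so that all
#'   written files are deterministic.
#' @export
write_summary_outputs <- function(summaries, out_dir,
                                  formats = c("txt", "json", "tsv"),
                                  inputs = character(),
                                  config_digest = "",
                                  n_genes = nrow(summaries)) {
  formats <- match.arg(formats, c("txt", "json", "tsv"), several.ok = TRUE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      genesum_abort(sprintf("Cannot create output directory '%s'.", out_dir),
                    class = "genesum_unwritable_dir")
    }
  }
  summaries <- arrange(summaries, gene_id)

  if ("txt" %in% formats) {
    blocks <- map_chr(seq_len(nrow(summaries)), function(i) {
      sprintf("%s\t%s\n%s\n\n", summaries$gene_id[[i]],
              summaries$public_name[[i]], summaries$description[[i]])
    })
    body <- paste0(blocks, collapse = "")
    con <- file(file.path(out_dir, "summaries.txt"), "wb")
    if (nzchar(body)) writeChar(body, con, eos = NULL)
    close(con)
  }
  if ("tsv" %in% formats) {
    readr::write_tsv(
      summaries[, c("gene_id", "public_name", "species", "description")],
      file.path(out_dir, "summaries.tsv"), progress = FALSE
    )
  }
  if ("json" %in% formats) {
    json <- jsonlite::toJSON(
      summaries[, c("gene_id", "public_name", "species", "description")],
      dataframe = "rows", pretty = TRUE
    )
    writeLines(json, file.path(out_dir, "summaries.json"), useBytes = TRUE)
  }

  category_counts <- stats::setNames(
    rep(0L, length(statement_categories())), statement_categories()
  )
  if ("statements" %in% names(summaries)) {
    observed <- table(unlist(map(summaries$statements, "category")))
    category_counts[names(observed)] <- as.integer(observed)
  }

  manifest <- structure(
    list(
      config_digest = config_digest,
      inputs = inputs,
      gene_count = n_genes,
      summary_count = sum(nzchar(summaries$description)),
      statement_counts = as.list(category_counts),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    class = "genesum_manifest"
  )
  persisted <- manifest[setdiff(names(manifest), "timestamp")]
  writeLines(
    jsonlite::toJSON(persisted, auto_unbox = TRUE, pretty = TRUE),
    file.path(out_dir, "manifest.json"), useBytes = TRUE
  )
  invisible(manifest)
}

#' @export
print.genesum_manifest <- function(x, ...) {
  cat(sprintf("<run manifest> %d gene(s), %d summary(ies)\n",
              x$gene_count, x$summary_count))
  nonzero <- x$statement_counts[unlist(x$statement_counts) > 0]
  for (nm in names(nonzero)) cat(sprintf("  %s: %d\n", nm, nonzero[[nm]]))
  invisible(x)
}

#' Tidy a run manifest into a per-category count table
#'
#' Mirrors the column structure of a whole-database statement-count table at
#' the scale of the current run.
#'
#' @param x A `genesum_manifest`.
#' @param ... Unused.
#' @return A tibble with columns `category` and `n`.
#' @export
tidy.genesum_manifest <- function(x, ...) {
  tibble(category = names(x$statement_counts),
         n = unlist(x$statement_counts, use.names = FALSE))
}

#' @rdname tidy.genesum_manifest
#' @export
glance.genesum_manifest <- function(x, ...) {
  tibble(gene_count = x$gene_count, summary_count = x$summary_count,
         statement_total = sum(unlist(x$statement_counts)))
}
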