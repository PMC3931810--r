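#' Tabular and FASTA input/output
#'
#' All tables produced or consumed by the package use one dialect:
#' tab-separated, header row, UTF-8, "." for missing values.  FASTA output
#' wraps at 60 columns.
#'
#' @name io
NULL

#' Read a package-dialect TSV, checking required columns
#'
#' @param path file path.
#' @param required column names that must be present.
#' @return data.frame ("." read as NA, `#` lines skipped).
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = ".",
                         check.names = FALSE, comment.char = "#")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("file '", path, "': missing required column(s): ",
         paste(miss, collapse = ","))
  x
}

#' Write a data.frame as package-dialect TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed lines (used to record seeds and provenance in reports).
#' @export
write_tsv <- function(x, path, header_comments = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.numeric(col)) col <- sprintf("%.15g", col)
    col[is.na(df[[j]])] <- "."
    df[[j]] <- col
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write acceptor contexts as FASTA
#'
#' @param contexts list of [acceptor_context()] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contexts_fasta <- function(contexts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(contexts, `[[`, "", "seq"))
  names(seqs) <- vapply(contexts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Write the exon-start table matching a context collection
#'
#' @param contexts list of [acceptor_context()] objects.
#' @param path output TSV path.
#' @export
write_exon_starts <- function(contexts, path) {
  write_tsv(data.frame(
    context_id = vapply(contexts, `[[`, "", "id"),
    exon_start = vapply(contexts, `[[`, 0L, "exon_start")), path)
}

#' Write an evaluation summary as JSON
#'
#' @param x named list of scalars / simple vectors.
#' @param path output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
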