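#' Acceptor-site context objects
#'
#' An `acceptor_context` holds one acceptor region: the 3'-terminal part of
#' an intron (ending in the invariant AG dinucleotide) followed by the first
#' bases of the downstream exon, on the transcribed sense strand.  All
#' intronic distance features are measured from the intron/exon boundary
#' using 1-based negative offsets: -1 is the G of the AG, -2 the A, -3 the
#' last freely varying intronic base; +1 is the first exonic base (the E+1
#' position), +2 the second, and so on (there is no offset 0).
#'
#' @param id character scalar, record identifier.
#' @param sequence nucleotide string over A/C/G/T (case-insensitive; N is
#'   tolerated only outside the -50..+1 feature region).
#' @param exon_start 1-based index of the first exonic base within
#'   `sequence`.
#' @return An object of class `acceptor_context` with elements `id`, `seq`
#'   (upper case), `exon_start`, `intron_length` and `partial` (TRUE when
#'   fewer than 50 intronic bases are available, in which case window
#'   features report partial coverage).
#' @examples
#' ctx <- acceptor_context("x", "aaaaacttttttcagGTT", exon_start = 16)
#' ctx$intron_length
#' @export
acceptor_context <- function(id, sequence, exon_start) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  exon_start <- as.integer(exon_start)
  seq <- toupper(sequence)
  n <- nchar(seq)
  if (is.na(exon_start) || exon_start <= 2L || exon_start > n)
    stop("context '", id, "': exon_start must satisfy 2 < exon_start <= sequence length")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop("context '", id, "': non-ACGTN characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  if (substr(seq, exon_start - 2L, exon_start - 1L) != "AG")
    stop("context '", id, "': invariant AG dinucleotide absent at offsets -2/-1 ",
         "(found '", substr(seq, exon_start - 2L, exon_start - 1L), "')")
  # N is undefined inside the feature region (offsets -50..+1)
  feat <- substr(seq, max(1L, exon_start - 50L), exon_start)
  if (grepl("N", feat, fixed = TRUE))
    stop("context '", id, "': ambiguity code N inside the -50..+1 feature region")
  structure(
    list(id = id, seq = seq, exon_start = exon_start,
         intron_length = exon_start - 1L,
         partial = (exon_start - 1L) < 50L),
    class = "acceptor_context")
}

#' @export
print.acceptor_context <- function(x, ...) {
  intr <- substr(x$seq, max(1L, x$exon_start - 30L), x$exon_start - 1L)
  exo <- substr(x$seq, x$exon_start, min(nchar(x$seq), x$exon_start + 7L))
  cat("<acceptor_context> ", x$id, ": ...", tolower(intr), "|", exo,
      "  (intron tail ", x$intron_length, " nt",
      if (x$partial) ", partial" else "", ")\n", sep = "")
  invisible(x)
}

# sequence position of a boundary offset (negative = intronic, positive = exonic)
offset_to_pos <- function(ctx, offset) {
  ifelse(offset < 0L, ctx$exon_start + offset, ctx$exon_start + offset - 1L)
}

# base at a boundary offset, NA when outside the sequence
base_at <- function(ctx, offset) {
  pos <- offset_to_pos(ctx, offset)
  ifelse(pos >= 1L & pos <= nchar(ctx$seq), substring(ctx$seq, pos, pos), NA_character_)
}

#' Read acceptor contexts from FASTA plus an exon-start table
#'
#' @param fasta path to a multi-record FASTA file of acceptor regions.
#' @param exon_starts either a data.frame with columns `context_id` and
#'   `exon_start`, or a path to a tab-separated file with that header.
#' @return Named list of [acceptor_context()] objects, in FASTA order.
#' @export
parse_contexts <- function(fasta, exon_starts) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ", paste(ids[duplicated(ids)], collapse = ","))
  if (is.character(exon_starts)) exon_starts <- read_tsv_checked(
    exon_starts, c("context_id", "exon_start"))
  stopifnot(all(c("context_id", "exon_start") %in% names(exon_starts)))
  missing <- setdiff(ids, exon_starts$context_id)
  if (length(missing))
    stop("no exon_start given for record(s): ", paste(missing, collapse = ","))
  es <- exon_starts$exon_start[match(ids, exon_starts$context_id)]
  ctxs <- mapply(acceptor_context, ids, as.character(seqs), es, SIMPLIFY = FALSE)
  names(ctxs) <- ids
  ctxs
}

#' Read a variant table
#'
#' Expects a tab-separated file (or data.frame) with columns `variant_id`,
#' `context_id`, `ref_base`, `alt_base` and optionally `label` (one of
#' `affecting`, `non_affecting`, `unknown`; missing values become
#' `unknown`).  When `contexts` is supplied, each variant's `ref_base` is
#' checked against the base at the exon start of its context.
#'
#' @param variants path or data.frame.
#' @param contexts optional named list of contexts for validation.
#' @return data.frame of validated variant records.
#' @export
read_variants <- function(variants, contexts = NULL) {
  if (is.character(variants)) variants <- read_tsv_checked(
    variants, c("variant_id", "context_id", "ref_base", "alt_base"))
  req <- c("variant_id", "context_id", "ref_base", "alt_base")
  stopifnot(all(req %in% names(variants)))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v$ref_base <- toupper(v$ref_base); v$alt_base <- toupper(v$alt_base)
  if (is.null(v$label)) v$label <- "unknown"
  v$label[is.na(v$label) | v$label == "."] <- "unknown"
  ok <- v$label %in% c("affecting", "non_affecting", "unknown")
  if (!all(ok)) stop("bad label(s): ", paste(unique(v$label[!ok]), collapse = ","))
  if (any(v$ref_base == v$alt_base))
    stop("alt_base equal to ref_base for: ",
         paste(v$variant_id[v$ref_base == v$alt_base], collapse = ","))
  if (anyDuplicated(v$variant_id))
    stop("duplicate variant_id: ", paste(unique(v$variant_id[duplicated(v$variant_id)]), collapse = ","))
  if (!is.null(contexts)) {
    for (i in seq_len(nrow(v))) {
      ctx <- contexts[[v$context_id[i]]]
      if (is.null(ctx)) stop("variant '", v$variant_id[i], "': unknown context '",
                             v$context_id[i], "'")
      have <- base_at(ctx, 1L)
      if (have != v$ref_base[i])
        stop("variant '", v$variant_id[i], "': ref_base '", v$ref_base[i],
             "' does not match context base '", have, "' at the exon start")
    }
  }
  v[, c("variant_id", "context_id", "ref_base", "alt_base", "label")]
}

#' Apply an E+1 substitution to a context
#'
#' Returns a new context identical to `context` except for the base at the
#' exon start; the input is left untouched.  The variant's `ref_base` must
#' match the context.
#'
#' @param context an [acceptor_context()].
#' @param variant one row of a variant table (list or one-row data.frame
#'   with `ref_base` and `alt_base`).
#' @return Mutant `acceptor_context` (id suffixed with `:mut`).
#' @export
apply_variant <- function(context, variant) {
  stopifnot(inherits(context, "acceptor_context"))
  ref <- toupper(as.character(variant$ref_base))
  alt <- toupper(as.character(variant$alt_base))
  have <- base_at(context, 1L)
  if (have != ref)
    stop("ref mismatch for context '", context$id, "': variant says '", ref,
         "' but context has '", have, "' at the exon start")
  s <- context$seq
  substr(s, context$exon_start, context$exon_start) <- alt
  acceptor_context(paste0(context$id, ":mut"), s, context$exon_start)
}
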