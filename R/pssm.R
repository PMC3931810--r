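#' Position-specific scoring matrix for acceptor sites
#'
#' The classical acceptor-strength score: per-position base frequencies
#' over a window spanning the 3' end of the intron and the first exonic
#' base, summed additively and min-max normalised to a 0-100 percent
#' scale, in the tradition of the Shapiro-Senapathy consensus-value
#' score.  The bundled default matrix is an approximate transcription of
#' published human acceptor-site base frequencies (percent); columns for
#' the invariant AG are degenerate by construction.  The matrix is a
#' config asset: it can be written, edited and reloaded with
#' [write_pssm()] / [read_pssm()].
#'
#' @return list with `freq` (4 x width percent matrix, rows A,C,G,T),
#'   `offsets` (boundary offsets of the columns, default -14..+1).
#' @export
default_pssm <- function() {
  freq <- matrix(c(
    # -14 -13 -12 -11 -10  -9  -8  -7  -6  -5  -4  -3  -2  -1  +1
      11, 10, 10,  9,  9,  9,  9,  8,  7,  6, 23,  3, 100,  0, 24,  # A
      31, 32, 31, 33, 32, 33, 35, 37, 38, 39, 30, 64,   0,  0, 15,  # C
      15, 12, 11, 10, 10,  9,  8,  8,  7,  6, 21,  2,   0,100, 49,  # G
      43, 46, 48, 48, 49, 49, 48, 47, 48, 49, 26, 31,   0,  0, 12), # T
    nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  new_pssm(freq, offsets = c(-14:-1, 1L))
}

new_pssm <- function(freq, offsets) {
  stopifnot(nrow(freq) == 4L, ncol(freq) == length(offsets))
  sums <- colSums(freq)
  if (any(abs(sums - 100) > 0.1))
    stop("PSSM column frequencies must sum to 100 (+/- 0.1); got ",
         paste(round(sums[abs(sums - 100) > 0.1], 2), collapse = ","))
  if (!all(c(-2L, -1L, 1L) %in% offsets))
    stop("PSSM window must cover the AG (-2,-1) and the +1 exonic base")
  structure(list(freq = freq, offsets = as.integer(offsets)), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> acceptor frequency matrix, window ",
      min(x$offsets), "..+", max(x$offsets), " (", ncol(x$freq),
      " positions)\n", sep = "")
  invisible(x)
}

#' Score an acceptor context with a PSSM
#'
#' Adds the frequency of the observed base at every window position and
#' rescales so that the best-possible window sequence scores 100 and the
#' worst-possible scores 0.
#'
#' @param model a `pssm` object, see [default_pssm()].
#' @param context an [acceptor_context()], or a character window of the
#'   model's width.
#' @return numeric score in 0..100.
#' @export
pssm_score <- function(model, context) {
  stopifnot(inherits(model, "pssm"))
  bases <- window_bases(context, model$offsets)
  idx <- match(bases, rownames(model$freq))
  if (anyNA(idx))
    stop("context does not cover the PSSM window or contains non-ACGT bases")
  raw <- sum(model$freq[cbind(idx, seq_along(idx))])
  lo <- sum(apply(model$freq, 2, min))
  hi <- sum(apply(model$freq, 2, max))
  100 * (raw - lo) / (hi - lo)
}

# bases of a context at given boundary offsets (error if outside sequence)
window_bases <- function(context, offsets) {
  if (is.character(context)) {
    bases <- strsplit(toupper(context), "")[[1]]
    if (length(bases) != length(offsets))
      stop("window string has length ", length(bases), ", model expects ",
           length(offsets))
    return(bases)
  }
  stopifnot(inherits(context, "acceptor_context"))
  pos <- offset_to_pos(context, offsets)
  if (any(pos < 1L) || any(pos > nchar(context$seq)))
    stop("context '", context$id, "' does not cover window offsets ",
         min(offsets), "..", max(offsets))
  substring(context$seq, pos, pos)
}

#' Write / read a PSSM as a human-readable config table
#'
#' The on-disk format is the package TSV dialect: one row per window
#' offset with columns `offset`, `A`, `C`, `G`, `T` (percent).
#'
#' @param model a `pssm` object.
#' @param path file path.
#' @export
write_pssm <- function(model, path) {
  write_tsv(data.frame(offset = model$offsets, t(model$freq)), path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  x <- read_tsv_checked(path, c("offset", "A", "C", "G", "T"))
  new_pssm(t(as.matrix(x[, c("A", "C", "G", "T")])), x$offset)
}
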