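#' Intronic acceptor-site features
#'
#' These functions measure the pyrimidine structure of the intron tail of an
#' acceptor context.  All are functions of the intron only, so they are
#' identical for the wild-type and mutant contexts of an E+1 variant.
#'
#' @name intron-features
NULL

PYRIMIDINES <- c("C", "T")

is_py <- function(bases) bases %in% PYRIMIDINES

# logical pyrimidine mask of the intron tail, index = sequence position
intron_py_mask <- function(ctx) {
  is_py(strsplit(substr(ctx$seq, 1L, ctx$exon_start - 1L), "")[[1]])
}

#' Longest qualifying polypyrimidine stretch (PPS)
#'
#' The PPS is the longest uninterrupted run of pyrimidines (C/T) in the
#' intron tail that is at least 4 nt long and has at least one base at an
#' intronic offset between -20 and -3 inclusive.  Runs may extend beyond
#' -20 as long as one base falls inside the window; the invariant AG at
#' -2/-1 is purine and so never belongs to a run.  Ties in length are
#' broken towards the run closest to the 3' splice site.
#'
#' @param context an [acceptor_context()].
#' @param min_length minimum run length to qualify (default 4, the minimal
#'   U2AF65-domain binding footprint).
#' @param window inclusive offset window at least one run base must touch.
#' @return list with `length` (0 when no run qualifies), `start_offset`,
#'   `end_offset` (NA when none) and `qualifying`.
#' @export
find_pps <- function(context, min_length = 4L, window = c(-20L, -3L)) {
  mask <- intron_py_mask(context)
  es <- context$exon_start
  empty <- list(length = 0L, start_offset = NA_integer_,
                end_offset = NA_integer_, qualifying = FALSE)
  if (!length(mask) || !any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) return(empty)
  so <- starts[keep] - es   # offsets are position - exon_start for intronic bases
  eo <- ends[keep] - es
  in_win <- pmax(so, window[1]) <= pmin(eo, window[2])
  if (!any(in_win)) return(empty)
  len <- (eo - so + 1L)[in_win]; so <- so[in_win]; eo <- eo[in_win]
  best <- which(len == max(len))
  best <- best[which.max(eo[best])]   # tie: closest to the 3'ss
  list(length = len[best], start_offset = so[best], end_offset = eo[best],
       qualifying = TRUE)
}

#' Pyrimidine count in a fixed window upstream of the 3' splice site
#'
#' Counts C/T over intronic offsets -window_nt..-1 (the AG contributes
#' nothing since both its bases are purines).  When the intron tail is
#' shorter than the window the count covers what is available and
#' `covered` is FALSE.
#'
#' @param context an [acceptor_context()].
#' @param window_nt window width in nucleotides, conventionally 25 or 50.
#' @return list with `count`, `window_nt`, `covered`.
#' @export
count_py <- function(context, window_nt = 25L) {
  es <- context$exon_start
  lo <- max(1L, es - window_nt)
  bases <- strsplit(substr(context$seq, lo, es - 1L), "")[[1]]
  list(count = sum(is_py(bases)), window_nt = as.integer(window_nt),
       covered = (es - 1L) >= window_nt)
}

#' Polypyrimidine tract (PPT) by maximal-scoring segment
#'
#' Finds the contiguous segment within intronic offsets -50..-3 that
#' maximises a per-base score of +1 per pyrimidine and -1.5 per purine.
#' Ties are broken towards the longer segment, then towards the segment
#' closer to the 3' splice site.  A tail whose best segment scores <= 0
#' (e.g. all purine) yields length 0.
#'
#' @param context an [acceptor_context()].
#' @param region inclusive offset window searched.
#' @param py_score,pu_score per-base scores.
#' @return list with `length`, `distance_to_3ss` (offset of the segment's
#'   last base, negated; NA when length 0), `start_offset`, `end_offset`,
#'   `py_fraction`, `score` and `covered` (FALSE when the intron tail does
#'   not span the full search region).
#' @export
find_ppt <- function(context, region = c(-50L, -3L),
                     py_score = 1, pu_score = -1.5) {
  es <- context$exon_start
  lo <- max(1L, es + region[1])
  hi <- es + region[2]
  empty <- list(length = 0L, distance_to_3ss = NA_integer_,
                start_offset = NA_integer_, end_offset = NA_integer_,
                py_fraction = NA_real_, score = 0,
                covered = (es + region[1]) >= 1L)
  if (hi < lo) return(empty)
  mask <- is_py(strsplit(substr(context$seq, lo, hi), "")[[1]])
  sc <- ifelse(mask, py_score, pu_score)
  m <- length(sc)
  cum <- c(0, cumsum(sc))
  cpy <- c(0L, cumsum(mask))
  best <- NULL
  for (i in seq_len(m)) {        # segment start
    # all segment ends >= i at once
    scores <- cum[(i + 1L):(m + 1L)] - cum[i]
    j <- which(scores == max(scores))
    j <- j[length(j)]            # furthest end: longer, and closer to 3'ss
    cand <- list(score = scores[j], start = i, end = i + j - 1L)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score &&
         (cand$end - cand$start) > (best$end - best$start)) ||
        (cand$score == best$score &&
         (cand$end - cand$start) == (best$end - best$start) &&
         cand$end > best$end)) best <- cand
  }
  if (best$score <= 0) return(empty)
  s_pos <- lo + best$start - 1L
  e_pos <- lo + best$end - 1L
  npy <- cpy[best$end + 1L] - cpy[best$start]
  list(length = best$end - best$start + 1L,
       distance_to_3ss = es - e_pos,
       start_offset = s_pos - es, end_offset = e_pos - es,
       py_fraction = npy / (best$end - best$start + 1L),
       score = best$score, covered = (es + region[1]) >= 1L)
}

#' Default branch-site weight matrix
#'
#' A 4 x 7 base-frequency matrix over a heptamer with the branch adenine in
#' column 6, encoding the degenerate human branch-point consensus
#' (yyCTrAc-like, branch A nearly invariant).  The frequencies are a
#' synthetic consensus constructed for this package; the matrix is
#' pluggable, so a user-derived matrix can be supplied instead.
#'
#' @return list with `freq` (rows A,C,G,T; columns sum to 1), `branch_col`.
#' @export
default_bs_matrix <- function() {
  freq <- matrix(c(
    # pos1  pos2  pos3  pos4  pos5  pos6(A) pos7
    0.15, 0.12, 0.06, 0.05, 0.45, 0.97, 0.08,   # A
    0.28, 0.30, 0.60, 0.12, 0.06, 0.01, 0.52,   # C
    0.12, 0.10, 0.06, 0.05, 0.42, 0.01, 0.10,   # G
    0.45, 0.48, 0.28, 0.78, 0.07, 0.01, 0.30),  # T
    nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  list(freq = freq, branch_col = 6L)
}

#' Branch-site search by weight-matrix scan
#'
#' Scans heptamer windows whose branch-adenine column lies at intronic
#' offsets -150..-10 (truncated with a flag on shorter tails), keeping the
#' highest log2-odds scoring window among those with an A in the branch
#' column.  Ties go to the window closest to the 3' splice site.
#'
#' @param context an [acceptor_context()].
#' @param bs_matrix matrix description as from [default_bs_matrix()].
#' @param search inclusive offset range for the branch adenine.
#' @param ppt optional precomputed [find_ppt()] result used for the
#'   branch-to-PPT distance; computed when NULL.
#' @return list with `score`, `position` (branch adenine offset),
#'   `distance_to_3ss`, `distance_to_ppt` (signed; NA when no PPT),
#'   `found`, `truncated`.
#' @export
find_branch_site <- function(context, bs_matrix = default_bs_matrix(),
                             search = c(-150L, -10L), ppt = NULL) {
  es <- context$exon_start
  freq <- bs_matrix$freq
  bc <- bs_matrix$branch_col
  w <- ncol(freq)
  lw <- log2(pmax(freq, 1e-3) / 0.25)
  # candidate branch offsets, window must fit in the sequence
  offs <- seq.int(search[1], search[2])
  first_pos <- es + offs - (bc - 1L)
  keep <- first_pos >= 1L
  truncated <- any(!keep)
  offs <- offs[keep]
  best <- list(score = -Inf, position = NA_integer_)
  for (a in offs) {
    start <- es + a - (bc - 1L)
    kmer <- strsplit(substr(context$seq, start, start + w - 1L), "")[[1]]
    if (kmer[bc] != "A" || anyNA(match(kmer, rownames(lw)))) next
    sc <- sum(lw[cbind(match(kmer, rownames(lw)), seq_len(w))])
    if (sc > best$score || (sc == best$score && a > best$position)) {
      best <- list(score = sc, position = a)
    }
  }
  if (!is.finite(best$score))
    return(list(score = NA_real_, position = NA_integer_,
                distance_to_3ss = NA_integer_, distance_to_ppt = NA_integer_,
                found = FALSE, truncated = truncated))
  if (is.null(ppt)) ppt <- find_ppt(context)
  dpp <- if (ppt$length > 0L) (ppt$start_offset - best$position) - 1L else NA_integer_
  list(score = best$score, position = best$position,
       distance_to_3ss = -best$position, distance_to_ppt = dpp,
       found = TRUE, truncated = truncated)
}

#' Feature vector of one context
#'
#' Convenience wrapper returning the intronic features used by the
#' classifier and the group comparisons as a one-row data.frame.
#'
#' @param context an [acceptor_context()].
#' @param bs_matrix branch-site matrix, see [find_branch_site()].
#' @return one-row data.frame with columns `context_id`, `pps`, `py25`,
#'   `py50`, `ppt_length`, `ppt_dist`, `ppt_score`, `ppt_py_fraction`,
#'   `bs_score`, `bs_dist`, `bs_to_ppt`.
#' @export
intron_features <- function(context, bs_matrix = default_bs_matrix()) {
  pps <- find_pps(context)
  ppt <- find_ppt(context)
  bs <- find_branch_site(context, bs_matrix, ppt = ppt)
  data.frame(
    context_id = context$id,
    pps = pps$length,
    py25 = count_py(context, 25L)$count,
    py50 = count_py(context, 50L)$count,
    ppt_length = ppt$length,
    ppt_dist = if (ppt$length) ppt$distance_to_3ss else NA_integer_,
    ppt_score = ppt$score,
    ppt_py_fraction = ppt$py_fraction,
    bs_score = bs$score,
    bs_dist = bs$distance_to_3ss,
    bs_to_ppt = bs$distance_to_ppt,
    stringsAsFactors = FALSE)
}
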