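#' Percentiles and wild-type/mutant score bundles
#'
#' Scores from either backend can be ranked against a background set of
#' acceptor-site scores (a stand-in for ranking within a large collection
#' of constitutive exons).  Changes between wild type and mutant are
#' expressed as relative differences, (wt - mut) / wt, applied to scores
#' and to percentiles.
#'
#' @name scoring
NULL

#' Mid-rank percentile of a score within a background
#'
#' @param score numeric scalar or vector.
#' @param background_scores non-empty numeric vector.
#' @return fraction(s) in 0..1: `(count below + 0.5 * count equal) / N`.
#' @export
percentile <- function(score, background_scores) {
  if (!length(background_scores)) stop("empty background score set")
  vapply(score, function(s)
    (sum(background_scores < s) + 0.5 * sum(background_scores == s)) /
      length(background_scores), 0)
}

relative_diff <- function(wt, mut) {
  if (!is.finite(wt) || wt == 0) return(NA_real_)
  (wt - mut) / wt
}

#' Score a variant's wild-type and mutant contexts
#'
#' Applies every configured backend to the wild-type context and to the
#' mutant produced by [apply_variant()], on identical windows, and
#' populates relative differences of scores and (when a background is
#' available) of percentiles.  A wild-type score of exactly 0 leaves that
#' backend's relative difference undefined (`NA`, flagged), since the
#' ratio is not defined there.
#'
#' @param context an [acceptor_context()].
#' @param variant one variant record (row of [read_variants()] output).
#' @param backends named list of scoring models; names become the backend
#'   labels (conventionally `pssm` and `maxent`), values are `pssm` or
#'   `maxent_model` objects.
#' @param background optional named list (same names) of numeric
#'   background score vectors used for percentile ranking.
#' @return data.frame with one row per backend: `variant_id`, `backend`,
#'   `wt_score`, `mut_score`, `wt_percentile`, `mut_percentile`,
#'   `score_diff`, `percentile_diff`, `undefined`.
#' @export
score_variant <- function(context, variant, backends, background = NULL) {
  if (!length(backends)) stop("at least one scoring backend is required")
  mut <- apply_variant(context, variant)
  rows <- lapply(names(backends), function(nm) {
    model <- backends[[nm]]
    scorer <- if (inherits(model, "pssm")) pssm_score
    else if (inherits(model, "maxent_model")) maxent_score
    else stop("backend '", nm, "' is neither a pssm nor a maxent_model")
    wt_s <- scorer(model, context)
    mut_s <- scorer(model, mut)
    bg <- background[[nm]]
    wt_p <- if (is.null(bg)) NA_real_ else percentile(wt_s, bg)
    mut_p <- if (is.null(bg)) NA_real_ else percentile(mut_s, bg)
    data.frame(variant_id = as.character(variant$variant_id), backend = nm,
               wt_score = wt_s, mut_score = mut_s,
               wt_percentile = wt_p, mut_percentile = mut_p,
               score_diff = relative_diff(wt_s, mut_s),
               percentile_diff = if (is.null(bg)) NA_real_
                                 else relative_diff(wt_p, mut_p),
               undefined = (wt_s == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load externally computed wild-type/mutant scores
#'
#' Supports tools that are not reimplemented here (e.g. neural-network
#' splice-site scores): a TSV with columns `variant_id`, `wt_score`,
#' `mut_score` is turned into score bundles on the external channel, with
#' relative differences computed by the same (wt - mut)/wt formula.
#'
#' @param tsv path to the score table (or a data.frame).
#' @param name channel name; the backend label becomes `external:<name>`.
#' @return data.frame in the same shape as [score_variant()] output
#'   (percentiles absent).
#' @export
load_external_scores <- function(tsv, name = "scores") {
  x <- if (is.character(tsv))
    read_tsv_checked(tsv, c("variant_id", "wt_score", "mut_score"))
  else tsv
  stopifnot(all(c("variant_id", "wt_score", "mut_score") %in% names(x)))
  if (anyDuplicated(x$variant_id))
    stop("duplicate variant_id in external scores: ",
         paste(unique(x$variant_id[duplicated(x$variant_id)]), collapse = ","))
  wt <- suppressWarnings(as.numeric(x$wt_score))
  mut <- suppressWarnings(as.numeric(x$mut_score))
  if (anyNA(wt) || anyNA(mut)) stop("non-numeric wt_score/mut_score values")
  data.frame(variant_id = as.character(x$variant_id),
             backend = paste0("external:", name),
             wt_score = wt, mut_score = mut,
             wt_percentile = NA_real_, mut_percentile = NA_real_,
             score_diff = mapply(relative_diff, wt, mut),
             percentile_diff = NA_real_,
             undefined = (wt == 0),
             stringsAsFactors = FALSE)
}
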