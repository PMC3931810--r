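#' Cut-off classification of E+1 variants
#'
#' Each predicted parameter carries a threshold and a direction: raw
#' scores, percentiles and pyrimidine-count features call a variant
#' affecting when the value falls *below* the cut-off, while relative
#' wild-type/mutant differences call it affecting when the value rises
#' *above* the cut-off.  Exact equality is conservatively non-affecting.
#' Combined predictions take three parameters and are positive when at
#' least two of the three individual calls are affecting.
#'
#' @name cutoffs
NULL

#' Bundled default cut-off table
#'
#' The package's default thresholds for discriminating E+1-dependent from
#' E+1-independent acceptor sites.  Relative differences are stored as
#' fractions (a printed 20.00% is 0.20).  `integral` marks count-valued
#' parameters whose cut-off is itself an observed value.
#'
#' @return data.frame with columns `parameter`, `threshold`, `direction`
#'   (`below_is_affecting` / `above_is_affecting`), `integral`.
#' @export
default_cutoffs <- function() {
  data.frame(
    parameter = c("pps", "py25", "nnsplice_score_diff",
                  "maxent_mut_score", "maxent_mut_percentile",
                  "maxent_score_diff", "maxent_percentile_diff",
                  "pssm_score_diff", "pssm_percentile_diff"),
    threshold = c(12, 18, 0.0683, 8.07, 0.38, 0.20, 0.4376, 0.0243, 0.3043),
    direction = c("below_is_affecting", "below_is_affecting",
                  "above_is_affecting", "below_is_affecting",
                  "below_is_affecting", "above_is_affecting",
                  "above_is_affecting", "above_is_affecting",
                  "above_is_affecting"),
    integral = c(TRUE, TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE)
}

#' The three bundled parameter combinations
#'
#' @return named list of character triples.
#' @export
combo_parameters <- function() {
  list(A = c("py25", "maxent_score_diff", "maxent_percentile_diff"),
       B = c("py25", "maxent_score_diff", "pssm_score_diff"),
       C = c("py25", "maxent_percentile_diff", "pssm_score_diff"))
}

#' Classify a single parameter value
#'
#' @param value numeric; NA yields `"unavailable"`.
#' @param parameter parameter name present in `table`.
#' @param table a cut-off table, see [default_cutoffs()].
#' @return `"affecting"`, `"non_affecting"` or `"unavailable"`.
#' @export
classify_single <- function(value, parameter, table = default_cutoffs()) {
  row <- table[table$parameter == parameter, ]
  if (nrow(row) != 1L) stop("unknown parameter: ", parameter)
  vapply(value, function(v) {
    if (is.na(v)) return("unavailable")
    hit <- if (row$direction == "below_is_affecting") v < row$threshold
           else v > row$threshold
    if (hit) "affecting" else "non_affecting"
  }, "")
}

#' Combine three parameter calls by the two-of-three rule
#'
#' Positive (affecting) when at least two member calls are affecting;
#' non-affecting when at least two are non-affecting; otherwise (too many
#' unavailable members to decide) unavailable.
#'
#' @param calls character vector of three calls, or a named vector from
#'   which `combo`'s members are taken.
#' @param combo `"A"`, `"B"`, `"C"` or a character triple of parameter
#'   names (only used when `calls` is named).
#' @return combined call.
#' @export
classify_combined <- function(calls, combo = NULL) {
  if (!is.null(combo) && !is.null(names(calls))) {
    members <- if (is.character(combo) && length(combo) == 3L) combo
               else combo_parameters()[[combo]]
    if (is.null(members)) stop("unknown combo: ", combo)
    calls <- calls[members]
  }
  if (length(calls) != 3L) stop("a combined call needs exactly 3 member calls")
  n_aff <- sum(calls == "affecting", na.rm = TRUE)
  n_non <- sum(calls == "non_affecting", na.rm = TRUE)
  if (n_aff >= 2L) "affecting"
  else if (n_non >= 2L) "non_affecting"
  else "unavailable"
}

#' Classify a table of per-variant parameter values
#'
#' @param values data.frame with a `variant_id` column and one column per
#'   parameter named as in the cut-off table (missing parameters abstain).
#' @param table cut-off table.
#' @param combos named list of parameter triples (default the bundled
#'   A/B/C combinations).
#' @return data.frame with per-parameter calls (`call_<parameter>`) and
#'   combined calls (`combined_<combo>`).
#' @export
classify_table <- function(values, table = default_cutoffs(),
                           combos = combo_parameters()) {
  stopifnot("variant_id" %in% names(values))
  out <- data.frame(variant_id = values$variant_id, stringsAsFactors = FALSE)
  present <- intersect(table$parameter, names(values))
  for (p in present)
    out[[paste0("call_", p)]] <- classify_single(values[[p]], p, table)
  for (cn in names(combos)) {
    members <- combos[[cn]]
    cols <- paste0("call_", members)
    missing_cols <- setdiff(cols, names(out))
    for (mc in missing_cols) out[[mc]] <- "unavailable"
    out[[paste0("combined_", cn)]] <- vapply(seq_len(nrow(out)), function(i) {
      calls <- unlist(out[i, cols])
      names(calls) <- members
      classify_combined(calls)
    }, "")
    for (mc in missing_cols) out[[mc]] <- NULL
  }
  out
}

#' Derive a cut-off from labelled training values
#'
#' Two-step procedure: (1) scan candidate thresholds (midpoints of the
#' pooled sorted values, plus sentinels beyond both extremes) and keep
#' those maximising classification success under the parameter's
#' direction; ties prefer the boundary with the widest separating gap.
#' (2) At the best boundary, take the closest affecting-group value on
#' the affecting side and the closest non-affecting-group value on the
#' other side and return their arithmetic mean.  Count-valued (integral)
#' parameters instead return the observed non-affecting-side value
#' itself, so that the strict below/above rule still classifies separable
#' training data perfectly.
#'
#' @param values_affecting,values_non_affecting numeric vectors.
#' @param direction `"below_is_affecting"` or `"above_is_affecting"`.
#' @param integral logical, see above.
#' @return list with `threshold`, `success` (training values correctly
#'   classified at the threshold), `n`, `zero_margin` (TRUE when the
#'   groups could not be separated at all and the threshold is a
#'   degenerate boundary).
#' @export
derive_cutoff <- function(values_affecting, values_non_affecting,
                          direction = c("below_is_affecting",
                                        "above_is_affecting"),
                          integral = FALSE) {
  direction <- match.arg(direction)
  aff <- sort(values_affecting); non <- sort(values_non_affecting)
  if (!length(aff) || !length(non)) stop("both groups must be non-empty")
  u <- sort(unique(c(aff, non)))
  cands <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric()
  cands <- c(u[1] - 1, cands, u[length(u)] + 1)
  success <- vapply(cands, function(thr) {
    if (direction == "below_is_affecting")
      sum(aff < thr) + sum(non >= thr)
    else sum(aff > thr) + sum(non <= thr)
  }, 0)
  best <- which(success == max(success))
  gap <- vapply(cands[best], function(m) {
    lo <- u[u < m]; hi <- u[u > m]
    if (!length(lo) || !length(hi)) 0 else min(hi) - max(lo)
  }, 0)
  m <- cands[best][which.max(gap)]
  if (direction == "below_is_affecting") {
    v_aff <- suppressWarnings(max(aff[aff < m]))
    v_non <- suppressWarnings(min(non[non > m]))
  } else {
    v_aff <- suppressWarnings(min(aff[aff > m]))
    v_non <- suppressWarnings(max(non[non < m]))
  }
  if (!is.finite(v_aff) || !is.finite(v_non)) {
    warning("groups overlap entirely; zero-margin threshold at the shared boundary")
    return(list(threshold = m, success = max(success),
                n = length(aff) + length(non), zero_margin = TRUE))
  }
  thr <- if (integral) v_non else (v_aff + v_non) / 2
  list(threshold = thr, success = max(success),
       n = length(aff) + length(non), zero_margin = FALSE)
}

#' Derive a whole cut-off table from a labelled value table
#'
#' Runs [derive_cutoff()] for every parameter of `template` present in
#' `values`, keeping each parameter's direction and integral flag.
#'
#' @param values data.frame of per-variant parameter values with a
#'   `label` column (`affecting` / `non_affecting`).
#' @param template cut-off table supplying directions (default bundled).
#' @return cut-off table with re-derived thresholds.
#' @export
derive_cutoff_table <- function(values, template = default_cutoffs()) {
  stopifnot("label" %in% names(values))
  present <- intersect(template$parameter, names(values))
  tab <- template[template$parameter %in% present, ]
  for (i in seq_len(nrow(tab))) {
    p <- tab$parameter[i]
    v <- values[[p]]
    d <- derive_cutoff(v[values$label == "affecting" & !is.na(v)],
                       v[values$label == "non_affecting" & !is.na(v)],
                       tab$direction[i], tab$integral[i])
    tab$threshold[i] <- d$threshold
  }
  tab
}
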