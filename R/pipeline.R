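#' End-to-end benchmark pipeline
#'
#' Convenience layer tying the stages together: build scoring backends,
#' compute per-variant parameter values (intronic features plus wild-type
#' /mutant score bundles), classify them against a cut-off table and
#' evaluate the calls against the labels.  The analysis scripts and the
#' acceptance checks are thin drivers over these functions.
#'
#' @name pipeline
NULL

#' Build the default scoring backends and percentile background
#'
#' Trains the maximum-entropy model on synthetic strong acceptor sites
#' against weak (pyrimidine-poor) decoys and pairs it with the bundled
#' PSSM.  Background score vectors for percentile ranking are computed
#' from an independent draw of strong sites, standing in for a
#' constitutive-exon score collection.
#'
#' @param seed integer seed for the synthetic training material.
#' @param n_train sites per training set.
#' @param n_background contexts in the percentile-ranking background.
#' @return list with `backends` (named list: `pssm`, `maxent`) and
#'   `background` (named list of score vectors).
#' @export
default_backends <- function(seed, n_train = 300L, n_background = 300L) {
  strong <- generate_background(n_train, py_density = 0.85, seed = seed + 1L)
  weak <- generate_background(n_train, py_density = 0.35, seed = seed + 2L)
  win <- function(ctxs, offsets) vapply(
    ctxs, function(cx) paste(window_bases(cx, offsets), collapse = ""), "")
  off23 <- window_offsets(c(-20L, 3L))
  maxent <- maxent_train(win(strong, off23), win(weak, off23), seed = seed)
  backends <- list(pssm = default_pssm(), maxent = maxent)
  rank_set <- generate_background(n_background, py_density = 0.85,
                                  seed = seed + 3L)
  background <- list(
    pssm = vapply(rank_set, function(cx) pssm_score(backends$pssm, cx), 0),
    maxent = maxent_score(maxent, win(rank_set, off23)))
  list(backends = backends, background = background)
}

#' Per-variant parameter values for a benchmark
#'
#' For every variant: the intronic features of its (wild-type) context
#' and the score bundles of every backend, flattened into the wide
#' parameter columns the cut-off table refers to
#' (`pps`, `py25`, `maxent_mut_score`, `maxent_mut_percentile`,
#' `maxent_score_diff`, `maxent_percentile_diff`, `pssm_score_diff`,
#' `pssm_percentile_diff`, ...).  Externally computed channels (e.g.
#' `nnsplice_score_diff`) can be merged in via `external`.
#'
#' @param contexts named list of [acceptor_context()]s.
#' @param variants variant data.frame (see [read_variants()]).
#' @param backends,background as returned by [default_backends()].
#' @param external optional data.frame from [load_external_scores()].
#' @return data.frame, one row per variant, with a `label` column.
#' @export
benchmark_values <- function(contexts, variants, backends, background = NULL,
                             external = NULL) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ctx <- contexts[[v$context_id]]
    if (is.null(ctx)) stop("variant '", v$variant_id, "': unknown context")
    feat <- intron_features(ctx)
    sc <- score_variant(ctx, v, backends, background)
    out <- data.frame(variant_id = v$variant_id, label = v$label,
                      alt_base = v$alt_base,
                      pps = feat$pps, py25 = feat$py25, py50 = feat$py50,
                      bs_dist = feat$bs_dist, ppt_length = feat$ppt_length,
                      stringsAsFactors = FALSE)
    for (b in seq_len(nrow(sc))) {
      nm <- sc$backend[b]
      out[[paste0(nm, "_wt_score")]] <- sc$wt_score[b]
      out[[paste0(nm, "_mut_score")]] <- sc$mut_score[b]
      out[[paste0(nm, "_mut_percentile")]] <- sc$mut_percentile[b]
      out[[paste0(nm, "_score_diff")]] <- sc$score_diff[b]
      out[[paste0(nm, "_percentile_diff")]] <- sc$percentile_diff[b]
    }
    out
  })
  values <- do.call(rbind, rows)
  if (!is.null(external)) {
    ext <- external
    nm <- sub("^external:", "", ext$backend[1])
    keep <- data.frame(variant_id = ext$variant_id, stringsAsFactors = FALSE)
    keep[[paste0(nm, "_score_diff")]] <- ext$score_diff
    values <- merge(values, keep, by = "variant_id", all.x = TRUE, sort = FALSE)
  }
  values
}

#' Classify and evaluate a benchmark in one step
#'
#' @param values output of [benchmark_values()].
#' @param cutoffs cut-off table, default the bundled one.
#' @param combos combined-prediction definitions.
#' @return list with `predictions` (calls per variant), and `evaluation`:
#'   one [evaluate_calls()] result per parameter and per combo.
#' @export
evaluate_benchmark <- function(values, cutoffs = default_cutoffs(),
                               combos = combo_parameters()) {
  preds <- classify_table(values, cutoffs, combos)
  call_cols <- grep("^(call|combined)_", names(preds), value = TRUE)
  evaluation <- lapply(call_cols, function(cc)
    evaluate_calls(preds[[cc]], values$label))
  names(evaluation) <- sub("^(call|combined)_", "", call_cols)
  list(predictions = cbind(preds, label = values$label), evaluation = evaluation)
}
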