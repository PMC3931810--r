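#' Maximum-entropy acceptor-site model
#'
#' Models the distribution of fixed-width acceptor windows (default
#' offsets -20..+3, a 23-mer with the invariant AG fixed at -2/-1) for a
#' signal set and a background set, under marginal constraints on chosen
#' position subsets (default: every position plus every pair of adjacent
#' variable positions, capturing first-order composition and nearest
#' dependencies).  The fit is by iterative proportional scaling: starting
#' from the uniform distribution, each constrained marginal is rescaled to
#' its (pseudocount-smoothed) empirical value until all constrained
#' marginals match within `tolerance`.  For tractability the variable
#' positions are split into overlapping fragments of at most 9 positions;
#' the full-window probability is the product of fragment probabilities
#' divided by the product of overlap marginals (ratio rule), which is
#' exact whenever no constrained subset spans two fragments - the default
#' adjacent-pair family satisfies this by construction.  A sequence is
#' scored as log2(P_signal / P_background).
#'
#' @name maxent
NULL

BASES <- c("A", "C", "G", "T")

# offsets covered by a boundary window c(lo, hi); no offset 0 exists
window_offsets <- function(window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  off <- seq.int(window[1], window[2])
  off[off != 0L]
}

# split variable-position indices into overlapping fragments of <= 9
maxent_fragments <- function(n_var, max_size = 9L, overlap = 3L) {
  if (n_var <= max_size) return(list(seq_len(n_var)))
  step <- max_size - overlap
  starts <- seq.int(1L, n_var - max_size, by = step)
  if (starts[length(starts)] + max_size - 1L < n_var)
    starts <- c(starts, n_var - max_size + 1L)
  lapply(starts, function(s) seq.int(s, s + max_size - 1L))
}

# default constraint family over variable positions (indices 1..n_var):
# singletons, optionally adjacent pairs
maxent_constraints <- function(n_var, order = c("first_and_pairs", "first_order")) {
  order <- match.arg(order)
  subsets <- as.list(seq_len(n_var))
  if (order == "first_and_pairs" && n_var > 1L)
    subsets <- c(subsets, lapply(seq_len(n_var - 1L), function(i) c(i, i + 1L)))
  subsets
}

# encode sequences (character vector) into integer code matrix 1..4
encode_seqs <- function(seqs, width) {
  if (any(nchar(seqs) != width))
    stop("all training sites must be ", width, " nt wide")
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")), BASES),
              ncol = width, byrow = TRUE)
  if (anyNA(m)) stop("training sites must contain only A/C/G/T")
  m
}

# cell index (1-based) of each row of a code matrix over 4^k cells
cell_index <- function(codes) {
  k <- ncol(codes)
  as.integer(1L + (codes - 1L) %*% (4^(seq_len(k) - 1L)))
}

# map from joint cell to marginal cell for subset S (relative indices)
marginal_map <- function(k, S) {
  cells0 <- 0:(4^k - 1)
  idx <- numeric(length(cells0))
  for (j in seq_along(S)) {
    digit <- (cells0 %/% 4^(S[j] - 1L)) %% 4
    idx <- idx + digit * 4^(j - 1L)
  }
  as.integer(idx + 1L)
}

# iterative proportional fit of one fragment distribution
fit_fragment <- function(codes_sub, subsets_rel, tolerance, max_iter, pseudocount) {
  k <- ncol(codes_sub)
  cells <- 4^k
  counts <- tabulate(cell_index(codes_sub), nbins = cells)
  p_emp <- (counts + pseudocount / cells)
  p_emp <- p_emp / sum(p_emp)
  maps <- lapply(subsets_rel, function(S) marginal_map(k, S))
  targets <- lapply(maps, function(m) as.vector(rowsum(p_emp, m)))
  q <- rep(1 / cells, cells)
  for (iter in seq_len(max_iter)) {
    for (s in seq_along(maps)) {
      qm <- as.vector(rowsum(q, maps[[s]]))
      q <- q * (targets[[s]] / qm)[maps[[s]]]
    }
    gaps <- vapply(seq_along(maps), function(s)
      max(abs(as.vector(rowsum(q, maps[[s]])) - targets[[s]])), 0)
    if (max(gaps) < tolerance)
      return(list(dist = q, iterations = iter, max_gap = max(gaps)))
  }
  stop("maximum-entropy fit did not converge in ", max_iter,
       " sweeps; worst marginal gap ", signif(max(gaps), 4))
}

#' Train a maximum-entropy acceptor model
#'
#' @param signal_sites,background_sites character vectors of aligned
#'   window sequences (width = number of offsets in `window`).
#' @param window inclusive boundary-offset window, default `c(-20, 3)`;
#'   when it covers offsets -2/-1 those positions are required to be the
#'   invariant A and G and are excluded from the model.
#' @param order constraint family: `"first_and_pairs"` (default) or
#'   `"first_order"` (independent positions; the fit then reduces to the
#'   product of position frequencies).
#' @param tolerance maximal allowed gap between fitted and empirical
#'   constrained marginals.
#' @param max_iter maximal scaling sweeps per fragment.
#' @param pseudocount total pseudo-mass added to each empirical fragment
#'   distribution before fitting.
#' @param seed recorded in the model metadata; the fit itself is
#'   deterministic.
#' @return object of class `maxent_model`.
#' @export
maxent_train <- function(signal_sites, background_sites, window = c(-20L, 3L),
                         order = c("first_and_pairs", "first_order"),
                         tolerance = 1e-6, max_iter = 200L,
                         pseudocount = 0.5, seed = NULL) {
  order <- match.arg(order)
  off <- window_offsets(window)
  width <- length(off)
  fixed <- which(off %in% c(-2L, -1L))
  sig <- encode_seqs(signal_sites, width)
  bg <- encode_seqs(background_sites, width)
  if (length(fixed) == 2L) {
    want <- match(c("A", "G"), BASES)
    for (m in list(sig, bg))
      if (!all(m[, fixed[1]] == want[1] & m[, fixed[2]] == want[2]))
        stop("all training sites must carry the invariant AG at offsets -2/-1")
  }
  var_pos <- setdiff(seq_len(width), fixed)
  frags_rel <- maxent_fragments(length(var_pos))
  frags <- lapply(frags_rel, function(f) var_pos[f])
  subsets_var <- maxent_constraints(length(var_pos), order)
  subsets <- lapply(subsets_var, function(S) var_pos[S])
  fit_side <- function(codes) {
    dists <- vector("list", length(frags))
    iters <- integer(length(frags))
    for (i in seq_along(frags)) {
      fr <- frags[[i]]
      in_frag <- vapply(subsets, function(S) all(S %in% fr), TRUE)
      rel <- lapply(subsets[in_frag], function(S) match(S, fr))
      fit <- fit_fragment(codes[, fr, drop = FALSE], rel,
                          tolerance, max_iter, pseudocount)
      dists[[i]] <- fit$dist
      iters[i] <- fit$iterations
    }
    # overlap marginals between consecutive fragments, taken from the
    # 5'-most fragment containing the overlap (ratio rule denominator)
    ovs <- list()
    if (length(frags) > 1L) for (i in seq_len(length(frags) - 1L)) {
      ov <- intersect(frags[[i]], frags[[i + 1L]])
      m <- marginal_map(length(frags[[i]]), match(ov, frags[[i]]))
      ovs[[i]] <- list(positions = ov,
                       marg = as.vector(rowsum(dists[[i]], m)))
    }
    list(dists = dists, overlaps = ovs, iterations = iters)
  }
  structure(list(
    window = window, offsets = off, fixed = fixed, var_pos = var_pos,
    fragments = frags, order = order,
    signal = fit_side(sig), background = fit_side(bg),
    meta = list(n_signal = nrow(sig), n_background = nrow(bg),
                tolerance = tolerance, max_iter = max_iter,
                pseudocount = pseudocount, seed = seed)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> window ", x$window[1], "..+", x$window[2], ", ",
      length(x$var_pos), " variable positions in ", length(x$fragments),
      " fragment(s), constraints: ", x$order, "\n",
      "  trained on ", x$meta$n_signal, " signal / ", x$meta$n_background,
      " background sites\n", sep = "")
  invisible(x)
}

# log2 probability of coded windows (matrix) under one fitted side
side_log2p <- function(side, frags, codes) {
  lp <- rep(0, nrow(codes))
  for (i in seq_along(frags)) {
    ci <- cell_index(codes[, frags[[i]], drop = FALSE])
    lp <- lp + log2(side$dists[[i]][ci])
  }
  for (ov in side$overlaps) {
    k <- length(ov$positions)
    ci <- cell_index(codes[, ov$positions, drop = FALSE])
    lp <- lp - log2(ov$marg[ci])
  }
  lp
}

#' Score acceptor windows with a trained maximum-entropy model
#'
#' @param model a `maxent_model` from [maxent_train()].
#' @param context an [acceptor_context()] covering the model window, or a
#'   character vector of window sequences of the model's width.
#' @return log2-odds score(s), `log2(P_signal / P_background)`.
#' @export
maxent_score <- function(model, context) {
  stopifnot(inherits(model, "maxent_model"))
  if (inherits(context, "acceptor_context")) {
    seqs <- paste(window_bases(context, model$offsets), collapse = "")
  } else seqs <- as.character(context)
  codes <- encode_seqs(seqs, length(model$offsets))
  if (length(model$fixed) == 2L) {
    want <- match(c("A", "G"), BASES)
    if (!all(codes[, model$fixed[1]] == want[1] &
             codes[, model$fixed[2]] == want[2]))
      stop("window lacks the invariant AG at offsets -2/-1")
  }
  side_log2p(model$signal, model$fragments, codes) -
    side_log2p(model$background, model$fragments, codes)
}

# audit helper: worst |fitted - empirical| marginal gap over all
# constrained subsets of a fitted model side, against the smoothed
# empirical marginals recomputed from the given training sites
maxent_marginal_gaps <- function(model, sites, side = c("signal", "background")) {
  side_name <- match.arg(side)
  sd <- model[[side_name]]
  codes <- encode_seqs(sites, length(model$offsets))
  pc <- model$meta$pseudocount
  gaps <- c()
  subsets_var <- maxent_constraints(length(model$var_pos), model$order)
  subsets <- lapply(subsets_var, function(S) model$var_pos[S])
  for (S in subsets) {
    i <- which(vapply(model$fragments, function(f) all(S %in% f), TRUE))[1]
    fr <- model$fragments[[i]]
    k <- length(fr)
    counts <- tabulate(cell_index(codes[, fr, drop = FALSE]), nbins = 4^k)
    p_emp <- counts + pc / 4^k; p_emp <- p_emp / sum(p_emp)
    m <- marginal_map(k, match(S, fr))
    emp <- as.vector(rowsum(p_emp, m))
    fit <- as.vector(rowsum(sd$dists[[i]], m))
    gaps <- c(gaps, max(abs(emp - fit)))
  }
  max(gaps)
}
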