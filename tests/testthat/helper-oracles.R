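# Independent brute-force oracles used to cross-check the scanners, plus
# small fixture builders.  Oracles deliberately avoid the implementation's
# code paths (no rle, no cumulative best-segment scan).

PY <- c("C", "T")

# random acceptor context with a valid AG boundary; total length 60-200
rand_context <- function(id = "r") {
  n <- sample(60:200, 1)
  exon_len <- sample(4:10, 1)
  es <- n - exon_len + 1
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.25, 0.25, 0.2, 0.3))
  s[es - 2] <- "A"; s[es - 1] <- "G"
  acceptor_context(id, paste(s, collapse = ""), es)
}

# --- PPS oracle: enumerate every maximal all-pyrimidine interval --------
oracle_pps <- function(ctx, min_length = 4, window = c(-20, -3)) {
  b <- strsplit(ctx$seq, "")[[1]]
  es <- ctx$exon_start
  best <- NULL
  for (s in seq_len(es - 1)) {
    if (!(b[s] %in% PY)) next
    if (s > 1 && b[s - 1] %in% PY) next          # not maximal on the left
    e <- s
    while (e + 1 <= es - 1 && b[e + 1] %in% PY) e <- e + 1
    len <- e - s + 1
    if (len < min_length) next
    offs <- (s:e) - es
    if (!any(offs >= window[1] & offs <= window[2])) next
    cand <- list(length = len, start_offset = s - es, end_offset = e - es)
    if (is.null(cand)) next
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$end_offset > best$end_offset))
      best <- cand
  }
  if (is.null(best))
    return(list(length = 0L, start_offset = NA_integer_,
                end_offset = NA_integer_, qualifying = FALSE))
  c(best, list(qualifying = TRUE))
}

# --- PPT oracle: score every segment in the region ----------------------
oracle_ppt <- function(ctx, region = c(-50, -3), py_score = 1, pu_score = -1.5) {
  b <- strsplit(ctx$seq, "")[[1]]
  es <- ctx$exon_start
  lo <- max(1, es + region[1]); hi <- es + region[2]
  best <- NULL
  if (hi >= lo) for (s in lo:hi) for (e in s:hi) {
    seg <- b[s:e]
    sc <- sum(ifelse(seg %in% PY, py_score, pu_score))
    cand <- list(score = sc, len = e - s + 1, s = s, e = e)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && cand$len > best$len) ||
        (sc == best$score && cand$len == best$len && e > best$e)) best <- cand
  }
  if (is.null(best) || best$score <= 0)
    return(list(length = 0L, score = 0))
  list(length = best$len, score = best$score,
       distance_to_3ss = es - best$e,
       start_offset = best$s - es, end_offset = best$e - es,
       py_fraction = mean(b[best$s:best$e] %in% PY))
}

# --- branch-site oracle: rescan every candidate window ------------------
oracle_bs <- function(ctx, mat = default_bs_matrix(), search = c(-150, -10)) {
  b <- strsplit(ctx$seq, "")[[1]]
  es <- ctx$exon_start
  lw <- log2(pmax(mat$freq, 1e-3) / 0.25)
  bc <- mat$branch_col; w <- ncol(mat$freq)
  best <- NULL
  for (a in search[1]:search[2]) {
    s <- es + a - (bc - 1)
    if (s < 1) next
    kmer <- b[s:(s + w - 1)]
    if (kmer[bc] != "A" || any(!kmer %in% rownames(lw))) next
    sc <- 0
    for (j in seq_len(w)) sc <- sc + unname(lw[kmer[j], j])
    if (is.null(best) || sc > best$score ||
        (sc == best$score && a > best$position))
      best <- list(score = sc, position = a)
  }
  best
}

# --- SRE delta oracle: diff the occurrence sets window by window --------
oracle_sre <- function(wt, mut, sets, mode) {
  es <- wt$exon_start; n <- nchar(wt$seq)
  out <- list(ESE = c(gains = 0, losses = 0), ESS = c(gains = 0, losses = 0),
              unspecified = c(gains = 0, losses = 0))
  for (set in sets) {
    k <- set$width
    for (s in seq_len(n - k + 1)) {
      covers <- s <= es && es <= s + k - 1
      if (!covers) next
      if (mode == "borders_kept" && set$applicability == "exonic_only" &&
          s < es) next
      in_wt <- substr(wt$seq, s, s + k - 1) %in% set$kmers
      in_mut <- substr(mut$seq, s, s + k - 1) %in% set$kmers
      if (in_mut && !in_wt)
        out[[set$element_class]]["gains"] <- out[[set$element_class]]["gains"] + 1
      if (in_wt && !in_mut)
        out[[set$element_class]]["losses"] <- out[[set$element_class]]["losses"] + 1
    }
  }
  out
}

# --- exact Mann-Whitney p by enumeration of group assignments -----------
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# --- Fisher oracle: enumerate all tables with the observed margins ------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# toy exonic motif sets used across SRE tests
toy_ess <- function() motif_set("toy_ess", "ESS",
                                kmers = c("TAGGGA", "TTAGGG"),
                                applicability = "exonic_only")
toy_ese <- function() motif_set("toy_ese", "ESE",
                                kmers = c("GAAGAA", "TAAGAA"),
                                applicability = "exonic_only")
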