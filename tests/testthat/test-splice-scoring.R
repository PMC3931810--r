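make_ctx_covering <- function(window_seq, offsets) {
  # embed a window string into a context so that window_bases recovers it
  stopifnot(nchar(window_seq) == length(offsets))
  lead <- strrep("a", 40)
  intron_part <- paste(substr(window_seq, 1, sum(offsets < 0)), collapse = "")
  exon_part <- substr(window_seq, sum(offsets < 0) + 1, nchar(window_seq))
  acceptor_context("w", paste0(lead, intron_part, exon_part, "AAA"),
                   exon_start = 40 + sum(offsets < 0) + 1)
}

test_that("PSSM scores are min-max normalised to 0..100", {
  m <- default_pssm()
  consensus <- paste(rownames(m$freq)[apply(m$freq, 2, which.max)], collapse = "")
  worst <- paste(rownames(m$freq)[apply(m$freq, 2, which.min)], collapse = "")
  expect_equal(pssm_score(m, consensus), 100)
  expect_equal(pssm_score(m, worst), 0)
  set.seed(1)
  for (i in 1:50) {
    w <- paste(sample(c("A", "C", "G", "T"), ncol(m$freq), TRUE), collapse = "")
    s <- pssm_score(m, w)
    expect_gte(s, 0); expect_lte(s, 100)
  }
})

test_that("PSSM score equals direct application of the additive formula", {
  m <- default_pssm()
  w <- "TTCTTTCTTTAGAGG"   # 15-mer over the -14..+1 window
  bases <- strsplit(w, "")[[1]]
  raw <- 0
  for (j in seq_along(bases)) raw <- raw + unname(m$freq[bases[j], j])
  lo <- sum(apply(m$freq, 2, min)); hi <- sum(apply(m$freq, 2, max))
  expect_equal(pssm_score(m, w), 100 * (raw - lo) / (hi - lo))
  # and through a full context covering the window
  ctx <- make_ctx_covering(w, m$offsets)
  expect_equal(pssm_score(m, ctx), pssm_score(m, w))
})

test_that("PSSM config round-trips through its on-disk table", {
  m <- default_pssm()
  f <- tempfile(fileext = ".tsv")
  write_pssm(m, f)
  m2 <- read_pssm(f)
  expect_equal(m2$freq, m$freq, ignore_attr = TRUE)
  expect_equal(m2$offsets, m$offsets)
  expect_equal(pssm_score(m2, "TTCTTTCTTTAGAGG"), pssm_score(m, "TTCTTTCTTTAGAGG"))
})

rand_sites <- function(n, width, py = 0.5) {
  vapply(seq_len(n), function(i) paste(
    sample(c("A", "C", "G", "T"), width, TRUE,
           prob = c((1 - py) / 2, py / 2, (1 - py) / 2, py / 2)),
    collapse = ""), "")
}

test_that("first-order maximum entropy reduces to the closed-form log-odds sum", {
  set.seed(3)
  sig <- rand_sites(80, 5, py = 0.8)
  bg <- rand_sites(80, 5, py = 0.3)
  m <- maxent_train(sig, bg, window = c(-9, -5), order = "first_order",
                    pseudocount = 0.5)
  closed_form <- function(x, sites) {
    pc <- 0.5
    codes <- do.call(rbind, strsplit(sites, ""))
    sum(vapply(1:5, function(i) {
      f <- (sum(codes[, i] == substr(x, i, i)) + pc / 4) / (length(sites) + pc)
      log2(f)
    }, 0))
  }
  for (x in c("TTTTT", "ACGTA", "CCCCC", "GAGAG"))
    expect_equal(maxent_score(m, x),
                 closed_form(x, sig) - closed_form(x, bg), tolerance = 1e-6)
})

test_that("identical signal and background distributions score zero", {
  set.seed(4)
  sites <- rand_sites(60, 5, py = 0.6)
  m <- maxent_train(sites, sites, window = c(-9, -5))
  expect_equal(maxent_score(m, c("TTTTT", "ACGTA", "GGGGG")), rep(0, 3),
               tolerance = 1e-9)
})

test_that("fitted marginals match training marginals within tolerance", {
  set.seed(5)
  strong <- generate_background(200, py_density = 0.85, seed = 51)
  weak <- generate_background(200, py_density = 0.35, seed = 52)
  off <- setdiff(seq(-20, 3), 0)
  win <- function(ctxs) vapply(ctxs, function(cx)
    paste(substring(cx$seq, ifelse(off < 0, cx$exon_start + off,
                                   cx$exon_start + off - 1),
                    ifelse(off < 0, cx$exon_start + off,
                           cx$exon_start + off - 1)), collapse = ""), "")
  m <- maxent_train(win(strong), win(weak), tolerance = 1e-6)
  expect_lt(maxent_marginal_gaps(m, win(strong), "signal"), 1e-6)
  expect_lt(maxent_marginal_gaps(m, win(weak), "background"), 1e-6)
  # signal-like sequences outscore background-like ones on average
  expect_gt(mean(maxent_score(m, win(strong))), mean(maxent_score(m, win(weak))))
})

test_that("maxent training is reproducible and requires the invariant AG", {
  set.seed(6)
  sig <- rand_sites(40, 5, py = 0.7); bg <- rand_sites(40, 5, py = 0.3)
  m1 <- maxent_train(sig, bg, window = c(-9, -5), seed = 1)
  m2 <- maxent_train(sig, bg, window = c(-9, -5), seed = 1)
  expect_identical(m1, m2)
  # 23-mer window demands AG at -2/-1
  bad <- vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"), 23, TRUE),
                                       collapse = ""), "")
  expect_error(maxent_train(bad, bad), "invariant AG")
})

test_that("improving one base's signal/background ratio never lowers a first-order score", {
  set.seed(8)
  sig <- rand_sites(100, 5, py = 0.8); bg <- rand_sites(100, 5, py = 0.3)
  m <- maxent_train(sig, bg, window = c(-9, -5), order = "first_order")
  ratio <- function(base, i) {
    f <- function(sites) (sum(substr(sites, i, i) == base) + 0.125) /
      (length(sites) + 0.5)
    f(sig) / f(bg)
  }
  for (rep in 1:30) {
    x <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
    i <- sample(5, 1)
    cur <- substr(x, i, i)
    better <- names(which.max(vapply(c("A", "C", "G", "T"), ratio, 0, i = i)))
    y <- x; substr(y, i, i) <- better
    expect_gte(maxent_score(m, y) + 1e-12, maxent_score(m, x))
  }
})

test_that("percentile is the mid-rank fraction with documented edge cases", {
  bg <- c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(percentile(0, bg), 0)
  expect_equal(percentile(100, bg), 1)
  expect_equal(percentile(2, bg), 0.25)  # 1 below, 3 equal: (1 + 1.5)/10
  # equal to 3 background values, above 4 others -> (4 + 1.5)/10
  expect_equal(percentile(3, c(0, 1, 2, 2.5, 3, 3, 3, 6, 7, 8)), 0.55)
  expect_error(percentile(1, numeric()), "empty background")
  # monotone in score, invariant under background permutation
  set.seed(9)
  bg2 <- rnorm(50)
  xs <- sort(rnorm(20))
  ps <- percentile(xs, bg2)
  expect_true(all(diff(ps) >= 0))
  expect_equal(percentile(xs, sample(bg2)), ps)
})

test_that("score_variant computes relative differences with a division guard", {
  ctx <- acceptor_context("x", paste0(strrep("t", 40), "agGTTACA"), 43)
  backends <- list(pssm = default_pssm())
  v <- list(variant_id = "v", ref_base = "G", alt_base = "T")
  sb <- score_variant(ctx, v, backends)
  expect_equal(sb$score_diff, (sb$wt_score - sb$mut_score) / sb$wt_score)
  expect_false(sb$undefined)
  # alt equal to ref yields zero difference on every backend
  same <- score_variant(ctx, list(variant_id = "v0", ref_base = "G",
                                  alt_base = "G"), backends)
  expect_equal(same$score_diff, 0)
  expect_equal(same$wt_score, same$mut_score)
  # percentile channel appears when a background is supplied
  sb2 <- score_variant(ctx, v, backends,
                       background = list(pssm = c(50, 60, 70, 80, 90)))
  expect_false(is.na(sb2$percentile_diff))
})

test_that("relative-difference formula matches hand values", {
  ext <- load_external_scores(data.frame(
    variant_id = c("a", "b"), wt_score = c(0.96, 0.98),
    mut_score = c(0.82, 0.98)), name = "nnsplice")
  expect_equal(ext$backend, rep("external:nnsplice", 2))
  expect_equal(ext$score_diff[1], (0.96 - 0.82) / 0.96)
  expect_equal(round(ext$score_diff[1], 3), 0.146)
  expect_equal(ext$score_diff[2], 0)
  # wt of zero is flagged undefined
  z <- load_external_scores(data.frame(variant_id = "z", wt_score = 0,
                                       mut_score = 0.5))
  expect_true(z$undefined)
  expect_true(is.na(z$score_diff))
})

test_that("external score tables are validated", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\twt_score", "a\t0.9"), f)
  expect_error(load_external_scores(f), "missing required column")
  writeLines(c("variant_id\twt_score\tmut_score", "a\t0.9\t0.5", "a\t0.8\t0.4"), f)
  expect_error(load_external_scores(f), "duplicate")
  writeLines(c("variant_id\twt_score\tmut_score", "a\tx\t0.5"), f)
  expect_error(load_external_scores(f), "non-numeric")
})
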