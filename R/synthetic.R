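#' Synthetic acceptor-site benchmark generator
#'
#' Generates two classes of acceptor contexts mirroring the pyrimidine
#' structure of E+1-dependent (splicing-affecting) and E+1-independent
#' (non-affecting) 3' splice sites: a planted longest polypyrimidine
#' stretch (PPS) whose length distribution is centred on each class
#' median (8 vs 14 nt) within the class ranges (4-11 vs 6-17 nt), a
#' per-class target for the pyrimidine count in the 25 nt upstream of the
#' splice site (centred 16 vs 19), a planted branch-site heptamer placed
#' 24 vs 34 nt from the 3' splice site on average, an optional secondary
#' (>= 4 nt) pyrimidine stretch for the independent class, and a
#' class-conditioned substituting-base spectrum (T-biased among affecting
#' variants, A-biased among non-affecting ones).  Outside planted
#' elements, pyrimidine runs are capped at 3 nt so the planted PPS is the
#' unique qualifying longest stretch.  Labels equal class membership,
#' optionally flipped at a configurable noise rate.
#'
#' @name synthetic
NULL

#' Generator configuration
#'
#' Defaults encode the benchmark conditions described above; `seed` is
#' mandatory and drives every random choice.
#'
#' @param n_dependent,n_independent class sizes (defaults 13 and 12, the
#'   size of a typical curated test set).
#' @param pps_range_dependent,pps_range_independent inclusive PPS length
#'   ranges per class.
#' @param pps_mode_dependent,pps_mode_independent centres of the
#'   discretised normal PPS length distributions.
#' @param pps_sd spread of the PPS length distributions.
#' @param py25_mean_dependent,py25_mean_independent,py25_sd pyrimidine
#'   count targets for the 25-nt window.
#' @param bs_dist_mean_dependent,bs_dist_mean_independent,bs_dist_sd
#'   branch-adenine distance distributions (nt from the 3'ss).
#' @param second_stretch_prob probability that an independent-class
#'   context receives a secondary >= 4 nt pyrimidine stretch.
#' @param alt_probs_dependent,alt_probs_independent named probabilities
#'   over substituting bases A/C/T.
#' @param label_noise probability of flipping a class label.
#' @param sre_exception_rate fraction of independent-class contexts
#'   turned into SRE exceptions: an exonic silencer gain (toy motif
#'   `TAGGGA` created by G>T at E+1) relabels them affecting although
#'   their pyrimidine tract is strong.
#' @param intron_length,exon_length context geometry in nt.
#' @param seed integer seed (mandatory).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_dependent = 13L, n_independent = 12L,
                             pps_range_dependent = c(4L, 11L),
                             pps_range_independent = c(6L, 17L),
                             pps_mode_dependent = 8,
                             pps_mode_independent = 14,
                             pps_sd = 2,
                             py25_mean_dependent = 16,
                             py25_mean_independent = 19,
                             py25_sd = 1.5,
                             bs_dist_mean_dependent = 24,
                             bs_dist_mean_independent = 34,
                             bs_dist_sd = 3,
                             second_stretch_prob = 0.8,
                             alt_probs_dependent = c(A = 0.15, C = 0.15, T = 0.7),
                             alt_probs_independent = c(A = 0.7, C = 0.15, T = 0.15),
                             label_noise = 0,
                             sre_exception_rate = 0,
                             intron_length = 160L, exon_length = 8L,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("generator seed is mandatory")
  cfg <- list(n_dependent = as.integer(n_dependent),
              n_independent = as.integer(n_independent),
              pps_range_dependent = as.integer(pps_range_dependent),
              pps_range_independent = as.integer(pps_range_independent),
              pps_mode_dependent = pps_mode_dependent,
              pps_mode_independent = pps_mode_independent,
              pps_sd = pps_sd,
              py25_mean_dependent = py25_mean_dependent,
              py25_mean_independent = py25_mean_independent,
              py25_sd = py25_sd,
              bs_dist_mean_dependent = bs_dist_mean_dependent,
              bs_dist_mean_independent = bs_dist_mean_independent,
              bs_dist_sd = bs_dist_sd,
              second_stretch_prob = second_stretch_prob,
              alt_probs_dependent = alt_probs_dependent,
              alt_probs_independent = alt_probs_independent,
              label_noise = label_noise,
              sre_exception_rate = sre_exception_rate,
              intron_length = as.integer(intron_length),
              exon_length = as.integer(exon_length),
              seed = as.integer(seed))
  stopifnot(cfg$n_dependent >= 0, cfg$n_independent >= 0,
            cfg$exon_length >= 3L, cfg$intron_length >= 55L,
            cfg$pps_range_dependent[1] >= 4L,
            cfg$pps_range_dependent[1] <= cfg$pps_range_dependent[2],
            cfg$pps_range_independent[1] >= 4L,
            cfg$pps_range_independent[1] <= cfg$pps_range_independent[2],
            cfg$label_noise >= 0, cfg$label_noise <= 1,
            cfg$sre_exception_rate >= 0, cfg$sre_exception_rate <= 1)
  for (p in list(cfg$alt_probs_dependent, cfg$alt_probs_independent)) {
    stopifnot(setequal(names(p), c("A", "C", "T")), abs(sum(p) - 1) < 1e-8)
  }
  if (max(cfg$pps_range_dependent[2], cfg$pps_range_independent[2]) + 5L >
      cfg$intron_length)
    stop("infeasible config: PPS longer than the intron tail")
  class(cfg) <- "generator_config"
  cfg
}

# discretised truncated normal over lo..hi centred at mode
sample_int_normal <- function(n, lo, hi, mode, sd) {
  support <- lo:hi
  w <- stats::dnorm(support, mode, sd)
  support[sample.int(length(support), n, replace = TRUE, prob = w)]
}

pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

sample_base <- function(n, py, t_bias = 0.6) {
  ifelse(stats::runif(n) < py,
         ifelse(stats::runif(n) < t_bias, "T", "C"),
         ifelse(stats::runif(n) < 0.5, "A", "G"))
}

# maximal pyrimidine run length through position i given a base vector
local_py_run <- function(bases, i) {
  if (!is_py(bases[i])) return(0L)
  l <- i; while (l > 1L && is_py(bases[l - 1L])) l <- l - 1L
  r <- i; while (r < length(bases) && is_py(bases[r + 1L])) r <- r + 1L
  r - l + 1L
}

# one intron tail; offsets -L..-1 map to vector indices 1..L
build_intron <- function(L, pps_len, py25_target, bs_dist, second_len) {
  intron <- sample_base(L, py = 0)           # purine scaffold
  occupied <- logical(L)
  at <- function(off) L + 1L + off           # offset -> index
  set <- function(off, base, occ = TRUE) {
    intron[at(off)] <<- base
    occupied[at(off)] <<- occ
  }
  set(-1L, "G"); set(-2L, "A")
  # planted PPS, end 3-5 nt from the boundary, purine flanks
  pps_end <- -3L - sample.int(3L, 1L) + 1L   # -3, -4 or -5
  pps_start <- pps_end - pps_len + 1L
  for (o in pps_start:pps_end) set(o, if (stats::runif(1) < 0.6) "T" else "C")
  if (pps_end < -3L) set(pps_end + 1L, sample(c("A", "G"), 1L))
  set(pps_start - 1L, sample(c("A", "G"), 1L))
  # optional secondary stretch, two purines upstream of the PPS
  if (!is.na(second_len) && second_len >= 4L) {
    set(pps_start - 2L, sample(c("A", "G"), 1L))
    s2_end <- pps_start - 3L
    s2_start <- s2_end - second_len + 1L
    for (o in s2_start:s2_end) set(o, if (stats::runif(1) < 0.6) "T" else "C")
    set(s2_start - 1L, sample(c("A", "G"), 1L))
  }
  # branch-site heptamer GTCTAAC (branch A at column 6), shifted
  # upstream until it does not collide with planted pyrimidine elements
  a <- -as.integer(bs_dist)
  repeat {
    win <- (a - 5L):(a + 1L)
    if (min(win) - 1L < -L) break
    if (!any(occupied[at(win)]) && !occupied[at(min(win) - 1L)] &&
        !occupied[at(max(win) + 1L)]) {
      kmer <- c("G", "T", "C", "T", "A", "A", "C")
      for (j in seq_along(win)) set(win[j], kmer[j])
      set(min(win) - 1L, sample(c("A", "G"), 1L))
      if (max(win) + 1L <= -1L) set(max(win) + 1L, sample(c("A", "G"), 1L))
      break
    }
    a <- a - 1L
  }
  # background fill outside planted elements: pyrimidine runs capped at 3
  for (i in seq_len(L)) {
    if (occupied[i]) next
    run <- if (i >= 4L && all(is_py(intron[(i - 3L):(i - 1L)]))) 3L else 0L
    intron[i] <- if (run >= 3L) sample(c("A", "G"), 1L)
    else sample_base(1L, py = 0.3)
  }
  # steer the 25-nt window pyrimidine count towards its target without
  # creating runs of 4+ outside the planted stretches
  win25 <- at(-25L:-1L)
  free25 <- which(!occupied[at(-25L:-3L)]) + at(-25L) - 1L
  count <- sum(is_py(intron[win25]))
  if (count < py25_target) {
    for (i in sample(free25)) {
      if (count >= py25_target) break
      if (is_py(intron[i])) next
      old <- intron[i]
      intron[i] <- if (stats::runif(1) < 0.6) "T" else "C"
      if (local_py_run(intron, i) > 3L) intron[i] <- old
      else count <- count + 1L
    }
  } else if (count > py25_target) {
    for (i in sample(free25)) {
      if (count <= py25_target) break
      if (!is_py(intron[i])) next
      intron[i] <- sample(c("A", "G"), 1L)
      count <- count - 1L
    }
  }
  intron
}

#' Generate a labelled synthetic benchmark
#'
#' @param config a [generator_config()].
#' @return list with `contexts` (named list of [acceptor_context()]s),
#'   `variants` (data.frame: `variant_id`, `context_id`, `ref_base`,
#'   `alt_base`, `label`, `class`) and `config`.
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  classes <- c(rep("dependent", config$n_dependent),
               rep("independent", config$n_independent))
  n <- length(classes)
  sre_exc <- classes == "independent" &
    stats::runif(n) < config$sre_exception_rate
  contexts <- vector("list", n)
  variants <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    dep <- cl == "dependent"
    pps_len <- sample_int_normal(1L,
      if (dep) config$pps_range_dependent[1] else config$pps_range_independent[1],
      if (dep) config$pps_range_dependent[2] else config$pps_range_independent[2],
      if (dep) config$pps_mode_dependent else config$pps_mode_independent,
      config$pps_sd)
    py25 <- sample_int_normal(1L, max(pps_len + 1L, 11L), 22L,
      if (dep) config$py25_mean_dependent else config$py25_mean_independent,
      config$py25_sd)
    bs_dist <- max(12L, round(stats::rnorm(1L,
      if (dep) config$bs_dist_mean_dependent else config$bs_dist_mean_independent,
      config$bs_dist_sd)))
    second <- if (!dep && stats::runif(1) < config$second_stretch_prob)
      pick1(4L:min(6L, pps_len - 1L)) else NA_integer_
    intron <- build_intron(config$intron_length, pps_len, py25, bs_dist, second)
    exon <- c("G", sample(BASES, config$exon_length - 1L, replace = TRUE,
                          prob = c(0.27, 0.25, 0.26, 0.22)))
    if (sre_exc[i]) exon[2:6] <- c("A", "G", "G", "G", "A")
    id <- sprintf("%s_%03d", if (dep) "dep" else "ind", i)
    contexts[[i]] <- acceptor_context(
      id, paste(c(intron, exon), collapse = ""),
      exon_start = config$intron_length + 1L)
    probs <- if (dep) config$alt_probs_dependent else config$alt_probs_independent
    alt <- if (sre_exc[i]) "T"
           else sample(names(probs), 1L, prob = as.numeric(probs))
    truth <- if (dep || sre_exc[i]) "affecting" else "non_affecting"
    if (stats::runif(1) < config$label_noise)
      truth <- setdiff(c("affecting", "non_affecting"), truth)
    variants[[i]] <- data.frame(
      variant_id = paste0(id, "_G>", alt), context_id = id,
      ref_base = "G", alt_base = alt, label = truth, class = cl,
      stringsAsFactors = FALSE)
  }
  names(contexts) <- vapply(contexts, `[[`, "", "id")
  list(contexts = contexts, variants = do.call(rbind, variants),
       config = config)
}

#' Generate a background set of acceptor-like contexts
#'
#' Used as the score-ranking background (a synthetic stand-in for a large
#' constitutive-exon collection) and as maximum-entropy training
#' material.  Higher `py_density` gives stronger sites: a denser
#' pyrimidine tract upstream of the AG and a consensus-biased first
#' exonic base.
#'
#' @param n number of contexts.
#' @param py_density pyrimidine density of the 25-nt tract (default 0.85,
#'   a strong-site composition).
#' @param seed integer seed (mandatory).
#' @param intron_length,exon_length context geometry.
#' @return named list of [acceptor_context()]s.
#' @export
generate_background <- function(n, py_density = 0.85, seed,
                                intron_length = 60L, exon_length = 6L) {
  stopifnot(n >= 1)
  if (missing(seed) || is.null(seed)) stop("background seed is mandatory")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  lapply_named <- function(ids, f) { out <- lapply(ids, f); names(out) <- ids; out }
  ids <- sprintf("bg_%04d", seq_len(n))
  lapply_named(ids, function(id) {
    L <- intron_length
    intron <- sample_base(L, py = 0.4)
    # dense tract at -25..-3, consensus C at -3
    intron[(L - 24L):(L - 2L)] <- sample_base(23L, py = py_density)
    intron[L - 2L] <- sample(c("C", "T", "A", "G"), 1L,
                             prob = c(0.64, 0.31, 0.03, 0.02))
    intron[L - 1L] <- "A"; intron[L] <- "G"
    exon <- c(sample(BASES, 1L, prob = c(0.24, 0.15, 0.49, 0.12)),
              sample(BASES, exon_length - 1L, replace = TRUE))
    acceptor_context(id, paste(c(intron, exon), collapse = ""), L + 1L)
  })
}
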