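#!/usr/bin/env Rscript

# Stage 2: extract features and splice-site strength scores.
#
# Reads the simulated sets back through the package's FASTA/TSV readers,
# measures the intronic features (longest pyrimidine stretch, Py25/Py50
# counts, tract segment, branch site) and scores every wild-type/mutant
# pair with the PSSM and the maximum-entropy model, ranking against the
# background set.  Writes the per-variant value tables and the
# affecting/non-affecting group comparison (Mann-Whitney, analogous to
# the per-parameter comparisons one would tabulate for a real variant
# panel) under results/.

suppressPackageStartupMessages(library(eplusone))

SEED <- 20140221L
dat <- file.path("results", "data")

load_set <- function(nm) {
  ctxs <- parse_contexts(file.path(dat, paste0(nm, "_contexts.fa")),
                         file.path(dat, paste0(nm, "_exon_starts.tsv")))
  vars <- read_variants(file.path(dat, paste0(nm, "_variants.tsv")), ctxs)
  list(contexts = ctxs, variants = vars)
}

test_like <- load_set("test")
eval_set <- load_set("eval")

dbk <- default_backends(seed = SEED + 3L)
for (pair in list(list("test", test_like), list("eval", eval_set))) {
  nm <- pair[[1]]; s <- pair[[2]]
  vals <- benchmark_values(s$contexts, s$variants, dbk$backends, dbk$background)
  write_tsv(vals, file.path("results", paste0(nm, "_values.tsv")),
            header_comments = paste("backends seed:", SEED + 3L))
  assign(paste0(nm, "_vals"), vals)
}

# group comparison on the test-like set, one row per parameter
params <- c("pps", "py25", "py50", "bs_dist", "ppt_length",
            "maxent_wt_score", "maxent_mut_score", "maxent_score_diff",
            "maxent_percentile_diff", "pssm_mut_score", "pssm_score_diff",
            "pssm_percentile_diff")
aff <- test_vals$label == "affecting"
cmp <- do.call(rbind, lapply(params, function(p) {
  v <- test_vals[[p]]
  ok <- !is.na(v)
  mw <- compare_groups(v[aff & ok], v[!aff & ok])
  data.frame(parameter = p,
             median_affecting = stats::median(v[aff & ok]),
             median_non_affecting = stats::median(v[!aff & ok]),
             mw_u = mw$statistic, mw_p = mw$p_value)
}))
write_tsv(cmp, file.path("results", "group_comparison.tsv"))

cat("group comparison (test-like set, n=25):\n")
print(cmp, row.names = FALSE, digits = 3)
cat("\nsignificant at 0.05:",
    paste(cmp$parameter[cmp$mw_p < 0.05], collapse = ", "), "\n")
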