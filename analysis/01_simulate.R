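#!/usr/bin/env Rscript

# Stage 1: simulate the study material.
#
# Draws a labelled benchmark of E+1 (G+1) variants in two classes of
# acceptor sites -- E+1-dependent (weak pyrimidine tract, short longest
# stretch) and E+1-independent (strong tract) -- at the curated-set size
# (13 affecting / 12 non-affecting), a larger evaluation benchmark
# (50/50), and a strong-site background collection used for percentile
# ranking.  Everything is written as FASTA + TSV under results/data/ so
# later stages exercise the package's own readers.

suppressPackageStartupMessages(library(eplusone))

SEED <- 20140221L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

test_like <- generate_benchmark(generator_config(seed = SEED))
eval_set <- generate_benchmark(generator_config(
  n_dependent = 50L, n_independent = 50L, seed = SEED + 1L))
background <- generate_background(300L, seed = SEED + 2L)

for (pair in list(list("test", test_like), list("eval", eval_set))) {
  nm <- pair[[1]]; b <- pair[[2]]
  write_contexts_fasta(b$contexts, file.path(out, paste0(nm, "_contexts.fa")))
  write_exon_starts(b$contexts, file.path(out, paste0(nm, "_exon_starts.tsv")))
  write_tsv(b$variants, file.path(out, paste0(nm, "_variants.tsv")),
            header_comments = c(paste("seed:", b$config$seed),
                                "generator: eplusone::generate_benchmark"))
}
write_contexts_fasta(background, file.path(out, "background_contexts.fa"))
write_exon_starts(background, file.path(out, "background_exon_starts.tsv"))

cat(sprintf(
  "wrote %d + %d benchmark variants and %d background contexts to %s\n",
  nrow(test_like$variants), nrow(eval_set$variants), length(background), out))
cat(sprintf("test-like set: %d affecting / %d non-affecting\n",
            sum(test_like$variants$label == "affecting"),
            sum(test_like$variants$label == "non_affecting")))
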