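#!/usr/bin/env Rscript

# Stage 3: derive discriminative cut-off values.
#
# Applies the two-step cut-off procedure (scan candidate thresholds for
# maximal classification success, then average the two closest
# non-overlapping group values; integral count features keep the observed
# boundary value) to the small test-like set, parameter by parameter, and
# records how the derived thresholds compare with the bundled defaults.

suppressPackageStartupMessages(library(eplusone))

test_vals <- read_tsv_checked(file.path("results", "test_values.tsv"),
                              c("variant_id", "label", "pps", "py25"))
derived <- derive_cutoff_table(test_vals)
bundled <- default_cutoffs()
merged <- merge(derived, bundled[, c("parameter", "threshold")],
                by = "parameter", suffixes = c("_derived", "_bundled"))
write_tsv(derived, file.path("results", "derived_cutoffs.tsv"))

cat("derived vs bundled cut-offs:\n")
print(merged[, c("parameter", "direction", "threshold_derived",
                 "threshold_bundled")], row.names = FALSE, digits = 4)
cat("\nNote: score-channel thresholds live on this package's synthetic\n",
    "score scales and are not expected to coincide with the bundled\n",
    "defaults, which are calibrated for the original web tools.\n", sep = "")
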