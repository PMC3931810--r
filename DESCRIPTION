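Package: eplusone
Title: Splicing Impact of Exon First-Nucleotide Substitutions at Acceptor Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decides whether a substitution at the first nucleotide of an
    exon (E+1, typically G+1) is likely to disrupt pre-mRNA splicing.
    Extracts acceptor-site features from the 3' end of the upstream intron
    (longest polypyrimidine stretch, pyrimidine window counts,
    polypyrimidine tract, branch site), scores 3' splice-site strength for
    wild-type and mutant sequences with a position-specific scoring matrix
    and a maximum-entropy sequence model, counts gains and losses of
    exonic splicing-regulatory motifs overlapping the mutated position,
    applies per-parameter cut-off classifiers and two-of-three combined
    predictions, and evaluates performance with sensitivity/specificity
    and continuity-corrected Wilson confidence intervals.  A synthetic
    benchmark generator emulates the pyrimidine-tract structure of
    E+1-dependent and E+1-independent acceptor sites so that every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
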