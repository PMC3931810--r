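---
title: "Predicting the splicing impact of exon first-nucleotide substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the splicing impact of exon first-nucleotide substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplusone)
```

## The problem

The last bases of an intron end in a nearly invariant AG dinucleotide; the
first base of the downstream exon (the E+1 position) is most often a G.
Substitutions at E+1 sometimes abolish correct splicing and sometimes do
nothing, and which of the two happens depends largely on the quality of the
upstream polypyrimidine tract (PPT).  Acceptor sites with short, degenerate
tracts need the intact AG (and its E+1 context) already for the first
catalytic step — their splicing collapses when E+1 mutates — whereas sites
with long, dense tracts tolerate the change.  `eplusone` implements an
end-to-end in-silico procedure for this decision: sequence features of the
intron tail, two splice-site strength models scored on wild-type and mutant
sequences, motif gain/loss analysis at the mutated position, per-parameter
cut-off classifiers with combined two-of-three votes, and the statistics to
evaluate them.

## Coordinates and features

All positions are boundary offsets: -1 is the G of the invariant AG, -2 the
A, and +1 the first exonic base; there is no offset 0.

* **PPS** (`find_pps`): the longest uninterrupted run of pyrimidines (C/T)
  in the intron tail with length >= 4 nt (the minimal footprint of one
  U2AF65 RNA-binding domain) and at least one base at an offset in
  -20..-3.  "Between the third and the twentieth nucleotide" is read as
  the inclusive window -20..-3: the AG itself is purine and never counted.
  Runs may extend beyond -20 as long as one base is inside the window, so
  very long stretches are never excluded.  Equal-length runs resolve to
  the one closer to the splice site; the classifier uses only the length,
  which ties cannot change.
* **Py25 / Py50** (`count_py`): pyrimidine counts over offsets -25..-1 and
  -50..-1.  Shorter tails return the partial count plus a coverage flag —
  never a silent truncation.
* **PPT** (`find_ppt`): the maximal-scoring contiguous segment within
  -50..-3 under +1 per pyrimidine and -1.5 per purine.  The asymmetric
  penalty keeps segments from bridging long purine interruptions while
  still allowing single-base gaps, which matches how tract-finding
  heuristics in the literature behave.  Ties prefer the longer segment,
  then the one closer to the splice site; an all-purine region yields
  length 0.  This scheme is this package's own documented reimplementation
  of the tract idea — bit parity with any specific published tool is not a
  goal.
* **Branch site** (`find_branch_site`): a pluggable 4 x 7 base-frequency
  matrix with a designated branch-adenine column, scanned over branch
  offsets -150..-10; the score is the log2 ratio to the uniform base
  distribution, and only windows with an A in the branch column compete.
  The bundled default matrix is a synthetic consensus (yyCTrAc-like) built
  for this package.  The branch-to-PPT distance is signed:
  `(5'-most PPT offset - branch offset) - 1` is negative when the branch
  adenine lies inside the tract.

`N` is tolerated only outside the -50..+1 feature region, because every
feature above is undefined under ambiguity there.

## Splice-site strength models

**PSSM.** The classical additive consensus score: per-position base
frequencies over offsets -14..+1, summed and min–max normalised so the
best-possible window scores 100 and the worst 0.  The bundled matrix is an
approximate transcription of published human acceptor-site frequencies
(the Shapiro–Senapathy tradition); it ships as an editable table
(`inst/extdata/acceptor_pssm.tsv`) and any matrix whose columns sum to
100% and whose window covers the AG and +1 can be loaded in its place.

**Maximum entropy.** A joint model of the 23-mer window -20..+3 with the
AG fixed.  The model maximises entropy subject to matching the empirical
marginals of chosen position subsets; the default constraint family is
every single position plus every adjacent pair of variable positions,
capturing first-order composition and nearest-neighbour dependence.  The
fit is iterative proportional scaling from the uniform distribution until
every constrained marginal matches within `tolerance` (default 1e-6, an
error reports the worst gap if `max_iter` sweeps do not suffice).  For
tractability the 21 variable positions are split into three overlapping
fragments of 9; the full-window probability is the product of fragment
probabilities divided by the overlap marginals.  Because every constrained
subset lies within a single fragment, this ratio rule is exact for the
default family.  With singleton constraints only, the model collapses to
the product of position frequencies, giving a closed form the tests check
against.  A sequence scores `log2(P_signal / P_background)`.  Training is
deterministic; the `seed` argument is only recorded as metadata.
Empirical fragment distributions are smoothed with a total pseudo-mass of
0.5 so that unseen window sequences keep finite scores.

**Percentiles and relative differences.**  Scores can be ranked against a
background score collection as mid-rank fractions,
`(below + 0.5 * equal) / N` — a tie-neutral convention chosen here; the
original percentile source ranks within tens of thousands of constitutive
exons whose tie handling is unknown, so absolute percentile parity is not
claimed.  Changes upon mutation are relative differences
`(wt - mut) / wt`, for scores and for percentiles; a wild-type score of
exactly 0 leaves the ratio undefined and the variant abstains from that
channel rather than voting.

## Motif gains and losses at E+1

An E+1 change can also create an exonic splicing silencer (ESS) or destroy
an enhancer (ESE) whose window overlaps the mutated base.  `scan_deltas`
counts, for each motif set, occurrences overlapping E+1 that appear or
disappear upon mutation, in two modes: `borders_kept` restricts
exonic-only sets to windows fully inside the exon, and `all_exonic`
treats the whole sequence as exonic (regulatory proteins may bind before
the borders are defined, and exonic collections are better characterised
than intronic ones).  A prediction is positive when ESS gains outnumber
ESS losses *or* ESE losses outnumber ESE gains — the per-class reading of
"the respective elements"; pooling both classes into one inequality was
considered and rejected, since a silencer gain and an enhancer gain do not
cancel mechanistically.  Bundled motif sets are toy fixtures; real
collections load through the documented plain-text format.

## Cut-off classification

Each parameter carries a threshold and a direction: raw scores,
percentiles and count features call *affecting* strictly below their
cut-off, relative differences strictly above.  Exact equality is
conservatively *non-affecting* — the rule is stated with strict
"below"/"above".  The bundled defaults are: PPS 12 and Py25 18 (integral
counts), external neural-network score difference 6.83%, maximum-entropy
mutant score 8.07, mutant percentile 0.38, score difference 20.00%,
percentile difference 43.76%, PSSM score difference 2.43% and percentile
difference 30.43%.  Three combined predictions — A: (Py25, ME score diff,
ME percentile diff), B: (Py25, ME score diff, PSSM score diff), C: (Py25,
ME percentile diff, PSSM score diff) — call affecting when at least two of
the three member calls do; an unavailable member abstains, and the vote
stands whenever two members already decide it.

`derive_cutoff` reconstructs thresholds from labelled values in two
steps: scan candidate thresholds (midpoints of the pooled sorted values)
for maximal classification success, then return the arithmetic mean of
the closest affecting-group and non-affecting-group values that the best
boundary separates.  Ties between equally successful boundaries prefer
the widest margin.  For integral count parameters the observed value
itself is the cut-off; it is taken from the non-affecting side of the
boundary so that the strict below/above rule still classifies separable
training data perfectly (taking the affecting-side value would misclassify
that very observation under a strict inequality).  Entirely overlapping
groups return the shared boundary with a zero-margin warning.

## Evaluation statistics

Sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` are reported with
95% confidence limits from the Wilson score interval with continuity
correction (z = 1.96), clamped to [0, 1] and rounded half-up to two
decimals for reporting.  This interval was identified by reproduction:
among common binomial interval methods it is the one that regenerates,
cell for cell, the published bounds this package's acceptance suite checks
— the original analysis cited only a web calculator, so the method is an
inference recorded here as an assumption.  Group comparisons use the
Mann-Whitney test (exact enumeration when both groups have at most 8
untied values, otherwise the tie-corrected normal approximation with
continuity correction), Fisher's exact test for 2 x 2 tables, and
mid-rank Spearman correlation with a t-approximation p value.  No
multiple-testing correction is applied; the working significance level is
0.05 throughout, matching the analysis the package reproduces.

## The synthetic benchmark

No sequence set is bundled, so every stage is exercised on generated
material (`generate_benchmark`).  The generator plants, per context:

* a PPS of class-sampled length — dependent class range 4–11 nt centred
  on 8, independent range 6–17 nt centred on 14.  The centres are the
  reported class medians and the ranges the reported class extremes; a
  discretised truncated normal (sd 2 nt) interpolates between them, since
  only medians and ranges are known and a unimodal shape around the
  median is the natural completion (a uniform over the range would
  contradict the reported medians).
* a Py25 target centred at 16 vs 19 (sd 1.5, truncated to the observed
  11–21 span) reached by steering free window positions;
* a branch-site heptamer placed 24 vs 34 nt upstream on average (sd 3);
* for the independent class, a secondary >= 4 nt stretch with probability
  0.8 — shorter-PPS independent sites typically carry more than one
  stretch in their tract;
* a substituting base drawn T-biased (0.7) for the dependent class and
  A-biased (0.7) for the independent class, echoing the observation that
  mutations to T usually disrupt splicing while mutations to A usually do
  not.

Outside planted elements, pyrimidine runs are capped at 3 nt, which makes
the planted stretch the unique qualifying PPS — the generator/extractor
round trip is exact by construction and is tested as such
(Kolmogorov–Smirnov distance of measured PPS lengths to the configured
distribution < 0.15 at n = 200).  Labels equal class membership, flipped
at a configurable noise rate (default 0); an optional injector converts a
fraction of independent-class variants into SRE exceptions (a toy
silencer gain created by G>T) to exercise the motif pathway, mirroring
the real observation that strong-tract sites can still be disrupted
through regulatory elements.  Class sizes default to 13 + 12, the size of
a typical curated panel.  `generate_background` draws strong acceptor-like
contexts (dense tracts, consensus-biased -3 and +1 positions) used both as
maximum-entropy training material and as the percentile-ranking
background — an explicit synthetic stand-in for a constitutive-exon
collection, not a copy of one.

## Problem sizes

The shipped analyses and checks use: 1,000 random contexts of length
60–200 for scanner/oracle equivalence; 200 + 200 synthetic sites for
maximum-entropy training audits; five seeds of 50 + 50 variants for
classifier recovery; and 250–300 background contexts for percentile
ranking.  These sizes give stable rates (binomial sd of a 0.9 rate at
n = 50 is ~4 points) while keeping a full run to a few minutes.

## Known limitations

* The score-difference channels are fragile on the synthetic benchmark:
  log2-odds scores of weak sites sit near zero, where the relative
  difference `(wt - mut)/wt` is numerically unstable and can flip sign.
  The published difference cut-offs were calibrated on web-tool score
  scales; on this package's synthetic scales the count channels (PPS,
  Py25) and re-derived thresholds are the meaningful comparators, and the
  two-of-three combinations recover most of the single-channel loss.
* The generator encodes the pyrimidine-tract mechanism (plus the optional
  SRE injector); real E+1 outcomes also involve factors it does not model
  — gene-specific context, cryptic splice sites, nucleosome positioning.
  Passing recovery tests therefore demonstrates internal consistency of
  the pipeline, not clinical accuracy on human variants.
* Sequence backgrounds are i.i.d. with configurable composition; no
  attempt is made to mimic real intronic base correlation beyond the
  pyrimidine structure.
* Branch-site and tract scores are documented reimplementations with a
  synthetic default matrix; their absolute values are not comparable to
  any specific published predictor, though their distances and lengths
  are.
* External neural-network scores are supported only through the
  `load_external_scores` channel; the network itself has no published
  weights and is not reimplemented.
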