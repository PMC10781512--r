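---
title: "Methods: detecting and testing A-to-I microRNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing A-to-I microRNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredit)
```

## The problem

ADAR enzymes deaminate adenosines in double-stranded RNA to inosine, which
sequencers and the cellular machinery read as guanosine.  When this happens
inside the seed region (positions 2–8) of a mature microRNA, the edited
isomiR recognises an almost entirely different set of mRNA targets than its
genomically encoded counterpart — a single base change repurposes the whole
regulatory program.  Detecting such events from small RNA-seq means finding
positions where aligned reads systematically carry `G` over a reference
`A`, at rates far above what sequencing error explains, and then asking
whether the editing *level* differs between biological groups (for example
control vs disease brain tissue).

`miredit` implements this as a chain of small, testable stages:

1. **align**: ungapped bounded-mismatch alignment of reads to hairpin
   precursors, mature-arm assignment, per-position base tallies;
2. **call-sites**: the editing-level ratio and a three-part filter
   (edited-read count, binomial sequencing-error model, minimum mean
   level);
3. **diff-edit**: per-site Welch *t*-tests between two groups with
   Benjamini–Hochberg correction, plus abundance-correlation residual
   diagnostics;
4. **target-switch**: canonical seed-match (8mer / 7mer-m8 / 7mer-A1)
   scanning of 3'UTRs for the edited and non-edited isomiRs and comparison
   of the two target pools;
5. **motif**: trinucleotide context of edited adenosines against the
   background of all adenosines in expressed matures;
6. a fully seeded **synthetic-data generator** standing in for restricted
   patient sequencing data.

## Models and statistics

### Editing level

For a site (mature miRNA, position) in one sample, the editing level is

$$\hat\theta = k / n,$$

where $k$ is the number of reads showing the alternate base (`G`) and $n$
the total reads covering the position.  With full-length reads, $n$ equals
the reads assigned to the miRNA; counting per-position coverage generalizes
this to jittered or trimmed reads.  $n = 0$ yields a *missing* level, never
zero: absence of coverage is not evidence of absence of editing.

### The binomial sequencing-error filter

Under a uniform per-base error rate $p$ (default $0.01$), the number of
mismatching reads at an unedited position is at most
$X \sim \mathrm{Binomial}(n, p)$ (substitution to one *specific* base is
rarer still, $p/3$, so the filter is conservative).  A sample supports a
site when the upper tail

$$P(X \ge k) = \sum_{j=k}^{n} \binom{n}{j} p^j (1-p)^{n-j}$$

falls below `error_alpha` (default 0.05).  The tail is evaluated through
the binomial survival function, stable up to $n \ge 10^6$.  Because the
source text of this filter does not pin down the rejection cut-off or
whether it was applied per sample or on pooled counts, both are explicit
parameters; the default (per-sample test, at least one supporting sample)
is the most permissive reading that still eliminates error-only sites —
and the specificity simulations below confirm it does.

### The three retention filters

A candidate A→G site is retained when

- (i) edited reads summed across samples $\ge$ `min_edited_reads` (10) —
  a per-sample variant is available but off by default, since requiring 10
  edited reads in *every* library would be far stricter than the observed
  yield of edited miRNAs in published brain data suggests;
- (ii) the binomial error filter passes in $\ge$ `min_samples_pass` (1)
  samples;
- (iii) the mean editing level across *all* samples (groups pooled, since
  filtering precedes the group comparison) $\ge$ `min_mean_level` (0.10) —
  editing below 10% (fewer than 1 in 10 copies edited) is generally
  considered too low for biological follow-up.

The filters are independent predicates on the site, so retention is
invariant to the order in which they are applied; a property test asserts
this.  Non-A→G substitutions are tallied and reported (flagged
`is_adar = FALSE`) but never retained: only the A-to-I chemistry is in
scope.

### Differential editing

Editing levels are compared between exactly two groups (heterogeneous
patient subgroups are treated as one group) with an unpaired two-tailed
Welch *t*-test per site:

$$t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},
\qquad
\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
           {\frac{(s_1^2/n_1)^2}{n_1-1} + \frac{(s_2^2/n_2)^2}{n_2-1}},$$

followed by Benjamini–Hochberg adjustment across all testable sites
jointly (the family is the post-filter site set).  Degenerate cases are
resolved deterministically rather than allowed to produce infinities:
zero variance in both groups with equal means gives $t = 0$, $p = 1$;
zero variance with unequal means, or fewer than two non-missing values in
a group, is flagged *untestable* and excluded from the BH family.  The
implementation is the textbook formula, vectorized over the site matrix;
tests cross-check it against `stats::t.test` to $10^{-9}$.

### Abundance-correlation residuals

A lower edited-form level in one group could merely reflect lower overall
expression of the miRNA.  `abundance_residuals()` regresses edited-form
abundance on total abundance (ordinary least squares) and reports the
Pearson correlation and per-sample residuals; proportional data sit on the
line with residuals of exactly zero, while samples whose editing exceeds
what abundance predicts sit above it.  The transform behind published
versions of this display is typically unstated; the default here is
$\log_2(\mathrm{CPM} + 1)$ with a linear option, recorded in the output,
and no published residual magnitudes are asserted against it since their
scale is not recoverable.

### Expression-correlation utilities

Cross-dataset comparisons use median-of-ratios size factors
($\mathrm{sf}_j = \mathrm{median}_i \, c_{ij} / (\prod_j c_{ij})^{1/m}$
over genes with all-positive counts), implemented directly as that formula
and cross-checked against `DESeq2::estimateSizeFactorsForMatrix`, plus
Spearman rank correlation (Pearson on mid-ranks).  Note that scaling one
sample's counts by $c$ moves its *raw* factor by $c^{1-1/m}$ (every
geometric mean absorbs $c^{1/m}$); the intuitive "factor scales by $c$"
statement is exact only for factor ratios, which is what normalization
uses.

### Seed-match target scanning

For a 7-nt seed $s$ (miRNA positions 2–8), the accepted canonical sites
are, in TargetScan convention:

| type    | UTR pattern                               |
|---------|-------------------------------------------|
| 8mer    | revcomp($s$) followed by `A`               |
| 7mer-m8 | revcomp($s$)                               |
| 7mer-A1 | revcomp(positions 2–7) followed by `A`     |

The `A` opposite miRNA position 1 is a literal adenosine in the UTR
regardless of the miRNA's first base.  Overlapping classifications at one
seed-match location resolve by the hierarchy 8mer > 7mer-m8 > 7mer-A1.
Matching is exact substring search (including overlapping occurrences); a
brute-force scan is the oracle in tests up to 50 kb.  A UTR is a *target*
if it carries at least one accepted site; pools are compared by Jaccard
overlap, with per-pool percentages also reported because published
"percent shared" figures rarely state their denominator.  No context
scoring, conservation, or trained prediction model is applied — those are
external tools, deliberately out of scope; this scanner answers the
narrower, fully reproducible question "which UTRs contain canonical sites
for each isomiR".

### Editing-context motifs

ADARs prefer a 5' `U` and 3' `G` around the substrate adenosine, i.e. the
`UAG` triplet.  `motif_table()` tabulates the trinucleotide context of
every retained edited site — using the *unedited* reference base at the
centre, because the motif question concerns the substrate, not the edited
read — against the background of all adenosines in the expressed matures,
padding mature boundaries with the flanking hairpin base (the substrate is
the hairpin, so hairpin context is the natural default at the edges).  The
primary output is the count ranking; an optional two-sided Fisher exact
enrichment per motif (BH-adjusted) is a clearly-labelled extra, off by
default.

## The synthetic-data generator

The generator emulates the study conditions of a two-group brain small
RNA-seq comparison whose raw data sit under controlled access: 8 control
and 16 case libraries; random hairpins each carrying one annotated 3p
mature arm of 21 nt; one planted A-to-I site at mature position +6 with
true editing fractions 0.85 (control) and 0.79 (case) among 50 unedited
miRNAs; a uniform per-base substitution error rate of 0.01 (errored bases
go to each other base with equal probability — the simplest model
consistent with a single error-rate parameter); and per-miRNA per-library
coverage drawn negative-binomially with mean 2000 and dispersion
(`size`) 8, the dispersion being this package's own choice to mimic
library-to-library variability on which the emulated study is silent.
Planted sites sit in a `UAG` context by default.  Reads are full-length
mature sequences; an `end_jitter` option trims or extends either end by
one base to exercise the aligner's tolerance, since 5'/3' length isomiRs
are otherwise outside the model.  Quality strings are constant (`I`) and
never used.

Two access points draw from the same model:

- `simulate_reads()` materializes FASTQ-ready reads (editing applied per
  read as an independent Bernoulli draw, then the error channel, then
  optional jitter and adapter) together with ground-truth tables;
- `simulate_position_counts()` draws the per-position base tallies
  directly from the distributional marginal of the read-level model
  (negative-binomial coverage, binomial edited counts, multinomial error
  channel per position).  Because full-length reads make positions
  conditionally independent given coverage, the two routes agree in
  distribution at the tally; with `error_rate = 0` the read-level route
  reproduces ground truth *exactly*, and a test asserts this.

Repeated-simulation studies (the 100-run power study, the pure-error
specificity study, the 1000-run all-null FDR study) use the counts-level
route; these problem sizes keep each study in the seconds-to-minutes range
on one CPU while leaving the statistical content identical.  The read
route is exercised end-to-end at smaller scale in the test suite and by
the demo pipeline.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: multi-mapping between paralogous hairpins,
non-uniform and quality-dependent error profiles, 5'/3' isomiR ladders
beyond ±1 nt, adapter read-through variants, cross-contamination, and any
cell-type composition structure.  Conclusions about the pipeline's
*statistical* behaviour transfer; conclusions about alignment robustness
on real libraries should not be over-read.

## The aligner

Published miRNA-editing work typically delegates trimming and hairpin
mapping to external web services whose internal policies are not fully
documented.  Here the stage is in-repo and explicit: ungapped alignment
only (indels are vanishingly rare in ~21-nt reads vs their own
precursor), sense strand only (small RNA libraries are stranded), best
placement by mismatch count with `max_mismatch = 2` by default, ties
within a hairpin resolved to the smallest offset, ties across distinct
hairpins discarded as ambiguous rather than fractionally assigned (no EM
re-weighting is invented).  Candidate placements are enumerated by a
pigeonhole band lookup: a read split into `max_mismatch + 1` bands must
match at least one band exactly at any placement within budget, so exact
band joins find all admissible placements; an exhaustive scan is the
oracle in tests.  Reads shorter than 15 nt after adapter trimming are
discarded.  Adapter trimming removes the longest read suffix exactly
equal to an adapter prefix of at least 6 nt.  Mismatch bases are tallied
exactly as observed — they are the signal.

## Numerical and design choices

- **Coordinates** are 1-based inclusive on each sequence's 5'→3' axis;
  editing positions are reported in *mature* coordinates ("+6" = sixth
  base of the mature), the convention used in the field.
- **Alphabet**: RNA (`U`) internally; DNA converts on read, FASTQ writes
  back as DNA.  Ambiguity codes are rejected in references and tolerated
  in reads, where they never count as a match or a tallied base.
- **BH family**: all sites surviving the filters; untestable sites are
  excluded, so their undefined p-values cannot distort neighbours'
  adjusted values.
- **Determinism**: every random draw flows from an explicit integer seed
  (`withr::with_seed`, restoring RNG state); reference, reads and counts
  use distinct fixed offsets of the one seed so regenerating any piece is
  reproducible.  `run_pipeline()` writes a manifest with parameter values
  and MD5 checksums; identical configs give identical manifests.
- **Ties in scanning** cannot arise within a site type (matches are exact
  positions); across types the 8mer > 7mer-m8 > 7mer-A1 hierarchy is a
  total order.

## Known limitations

- The Welch test on editing *proportions* is slightly liberal when the
  true level sits near the boundary (e.g. 0.85) and one group is small:
  with 8 controls the skewness of $k/n$ inflates the extreme small-p tail
  of the $t$ approximation (measured all-null family-wise rejection 0.061
  at level 0.85 vs 0.051 at level 0.5, alpha 0.05, 100 sites).  The
  package's canonical all-null validation condition is therefore the
  symmetric level 0.5; users testing many sites with very high editing and
  few samples should expect mild anti-conservatism, or pre-transform
  levels (e.g. arcsine or logit) before testing.
- Editing calls are restricted to mature spans; precursor-only editing is
  out of scope, as are non-A-to-I chemistries.
- The target scanner reports canonical site presence, not repression
  strength; agreement with trained predictors or crosslinking data is a
  question for those external resources.
- Bulk tallies mask cell-type-specific editing.

## Reproducing the validation numbers

`scripts/acceptance.R` re-runs, from scratch and at the problem sizes
stated above: the known-sequence edit localization; the 100-run power
and recovery study at the study conditions; the 20-run pure-error
specificity study; the 1000-run all-null FDR study; the target-pool
switch on a planted UTR set; and the UAG-context motif ranking.  The test
suite asserts the same properties with fixed seeds.
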