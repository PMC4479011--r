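---
title: "Allele-specific analysis of replication origins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific analysis of replication origins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriallele)
```

## The problem

Replication origins in mammalian genomes fire stochastically: each origin is
used in only a fraction of cells, and its *efficiency* — the probability of
firing in a given S phase — varies between loci.  When the genome of a donor
has been fully sequenced and phased, nascent-strand sequencing reads that
cover heterozygous SNPs can be assigned to one of the two parental
homologues, turning a bulk experiment into roughly as many paired
"knock-in" comparisons as there are informative origins.  Two questions
follow naturally.  Do the sequence features credited with origin activity —
above all G-quadruplex (G4) forming sequences — actually change efficiency
when a SNP destroys them on one homologue?  And is replication-timing
asynchrony between homologues produced by switching dormant origins on, or
by nudging the efficiency of origins active on both?

`oriallele` implements the complete analytical machinery for these
questions and, because the full-scale sequencing data cannot ship with a
package, pairs it with a synthetic diploid-genome generator whose planted
truth makes every stage testable end to end.

## Allele-specific efficiency model

For an origin peak, let `n1` and `n2` be the summed allele depths (AD) of
the phased heterozygous SNPs inside the peak, assigned to homologues P1 and
P2.  Under the null of equal efficiency, `n1 ~ Binomial(n1 + n2, 1/2)`.
The caller (`test_allele_bias()`) works as follows:

* peaks with `n1 + n2 < 50` are *non-analysable* and excluded before any
  testing (the filter-then-adjust order matters for the multiple-testing
  correction);
* the two-sided exact p-value is `min(1, 2 * min(P(X <= n1), P(X >= n1)))`.
  For a symmetric null this equals the minimum-likelihood two-sided test,
  and it is reproduced in the test suite by direct pmf summation for every
  total up to 200;
* Benjamini–Hochberg adjustment runs over the analysable peaks only, and
  `q < 0.05` defines an *allele-biased* origin.

Counting is a plain sum of per-SNP allele depths: a read covering two SNPs
is counted twice.  This mirrors how allele depths are exported by variant
callers and keeps the statistic reproducible from a VCF alone; it slightly
underestimates the variance when SNPs sit closer than a read length, which
is one reason the binomial model should be read as an operational test
statistic rather than a generative read model.  Indels are excluded from
counting throughout.

`log2_ratio = log2(n1/n2)` is reported with infinite sentinels when one
side is zero; averages over origins exclude those sentinels.

## Non-B-DNA annotation

**G4.** The scanner finds the classical pattern — four tracts of at least
three Gs separated by 1–7 nt loops — on the plus strand, and the C-analogue
on the minus strand.  Two details are easy to get wrong.  First, the loop
class `[ACGT]` contains G itself, so a single run of 15 or more Gs is a
valid match; any scanner built on "maximal G-runs chained by G-free gaps"
misses those.  `find_g4()` therefore runs a dynamic programme over
*tract-start anchors* (every position where >= 3 consecutive Gs begin) and
returns the union of all raw matches, merged into maximal regions.  The
test suite proves the equivalence against an oracle that enumerates every
`(start, end)` substring and full-matches it against the pattern.  Second,
ambiguous bases: N never counts toward a tract or a loop.

**iG4.** The intermolecular pattern is four triplets, each `CCC` or `GGG`,
separated by 1–7 arbitrary letters.  We keep the literal `[A-Z]` spacer
class (so N is admitted in spacers — unlike G4 loops), match by an exact DP
over triplet anchors, merge, and then *subtract* G4s: any merged region
overlapping a G4 hit on either strand by >= 1 bp is removed.  Subtraction
by any-overlap is a package convention; it makes the invariant "no iG4 hit
ever overlaps a G4 hit" exactly testable.

**Triplex.** A deliberately simplified candidate detector, not a
reimplementation of dynamic-programming triplex scores: candidates are
mirror repeats with arms of at least `ceiling(min_core/2)` bases (default
core 15), loops up to 8 bp, and arms at least 90% purine or 90% pyrimidine.
The 0–7 type code is a package convention built from three bits:
pyrimidine-rich arms give the parallel class (types 0–3, the acid-dependent
configurations), purine-rich arms the antiparallel class (4–7); the
donor-arm bit marks the more purine-rich arm; the strand bit marks which
strand carries the purine tract.  Counts from this detector are comparable
within an analysis but not with published triplex-package scores.

**30-mers.** `enumerate_kmers()` reports every k-mer position above a GC
threshold, flagged by whether it fully contains a G4 or iG4 *pattern*
match (the iG4 flag deliberately ignores G4 subtraction, since the
question is quadruplex-forming potential).  The GC threshold separating
"high-GC" controls is recomputed from the data as the mean GC of
quadruplex-containing k-mers rather than hard-coded.

## Composition skew

Skew is `(G - C)/(G + C)` (or the A/T analogue) in 50-bp sliding windows at
1-bp step; a window with no G or C is missing, not zero, and missing
windows are excluded from position-wise averages rather than shrinking
them.  Window values are assigned to the window *start* (a documented
choice; nothing downstream depends on it beyond a fixed 25-bp half-window
phase).  For summit-anchored profiles, a peak whose central kilobase has
fewer Gs than Cs is reverse complemented ("adjusted" skew); exact ties keep
the reference orientation.  This makes the adjusted central skew
non-negative by construction, which is asserted as an invariant.

Profile clustering uses Euclidean k-means (k = 4 by default) with
k-means++ seeding, best of 10 restarts by total within-cluster sum of
squares, missing values imputed by the profile mean.  Cluster labels are
ordered by decreasing central G-density so runs are comparable; the label
order of a k-means fit is otherwise arbitrary.

## Island calling

Skewed regions and asynchronously replicated domains (ARDs) share one
SICER-style caller over binned signal.  A bin is *eligible* when its value
reaches `window_value`; eligible bins separated by at most `gap`
ineligible bins merge; islands are trimmed to their eligible ends, must
span at least `island_length` bins, and must reach `island_score`.  The
score is defined as the sum of `value / window_value` over eligible bins —
the island-score semantics of the original tool are not published, and
this definition has the property that the skewed-region parameter set
(threshold 0.375, gap 4, score 16, length 15 on 25-bp bins) reproduces the
intended ~400 bp minimum region: 16 threshold-level bins of 25 bp.
The equivalence of the caller with a brute-force span enumerator is tested
on a thousand randomized tracks and parameter draws.

ARDs are islands of the absolute maternal-paternal S/G1 (TimEX) ratio
difference on 5-kb windows: threshold 0.02, gap 250 kb, minimum 50 kb
(core ARDs: 0.1 / 50 kb / 50 kb), with no score filter — the domain
definition is by threshold, gap and size only.  Each island is then tested
on the 2x2 table of summed S- and G1-phase read counts for the two
homologues (Pearson chi-squared, 1 df, no continuity correction) and
retained below a BH FDR of 5%.  The island sign records which homologue
has the higher mean ratio.

## Enrichment statistics

Permutation tests shuffle the *feature* set while the query set stays
fixed (the reported quantities are of the form "% of ARDs containing an
allele-biased origin", so the biased origins are what gets randomized).
Shuffling preserves interval lengths exactly, places intervals uniformly
over valid starts, allows shuffled intervals to overlap each other, and
stays within chromosome by default.  The empirical p-value is the fraction
of iterations whose statistic is *strictly above* the observed value; the
conventional `(k+1)/(n+1)` correction is available behind a flag but off
by default, so a reported p of 0 means "never exceeded in n shuffles" and
has resolution 1/n.  The complementary strictly-below fraction is reported
for depletion.

GC-matched controls resample candidate regions (template length
distribution, uniform placement, rejection against an exclusion set) per
GC bin to match the template's GC histogram; a bin that cannot be
populated after a bounded number of candidate batches is a hard error
naming the bin.  Peak-height matched resampling bins the reference heights
into quantile bins and draws the pool per bin without replacement where
possible, at the largest size achievable.

## The synthetic study conditions

`simulation_spec()` defaults define the package's reference simulation,
chosen once to emulate the study conditions at desk scale:

| parameter | default | rationale |
|---|---|---|
| genome | 2 x 500 kb | large enough for ~200 slot-separated origins and 200-kb timing domains |
| origins | 200, width 750 bp | peak width at the published median (~772 bp) |
| biased fraction | 10% | matches the observed ~9% of analysable origins |
| allelic ratio | log-uniform 1.5–100 | the published range of homologue usage ratios |
| SNP density | 1/kb | human heterozygosity scale |
| depth | Poisson(100) per origin | comfortably above the 50-read filter |
| skew cores | 500 bp, G 0.55 / C 0.15 | upper end of the published 200–500 bp skewed-core range; the island caller cannot see < ~400 bp by design |
| ARDs | 200 kb, amplitude 0.12 | the published core-ARD size; amplitude safely above the 0.02/0.1 thresholds |
| timing noise | sd 0.005 per 5-kb window | keeps background bins below the 0.02 ARD threshold |

Planted G4/iG4 motifs are fixed canonical sequences padded by A/T flanks
(so a planted copy scans positive iff it is undisrupted), half of them
carrying a haplotype-specific SNP that destroys the third G-triplet (or a
C-triplet for iG4) on one homologue.  Skewed cores are drawn from
per-position nucleotide probabilities, not fixed strings, so island
calling is exercised on realistic noisy composition.  Read depths follow a
Poisson total split binomially by the true efficiency `e1` — the simplest
generative model matching the binomial test's assumptions, which is what
makes FDR calibration a meaningful test.  `simulate_allele_counts()`
exposes the same depth model at the count level for calibration studies at
scale (the null calibration uses 20 replicates of 10,000 origins).

What the generator does *not* emulate: read-level errors and mapping bias,
indel variants (the analysis is restricted to SNPs; applying indels would
break the shared coordinate system of the haplotype pair), linked SNPs
sharing reads, chromatin-driven origin clustering, and timing asynchrony
in minutes (only the ratio-difference amplitude the ARD caller consumes).
Passing tests therefore demonstrate the correctness and calibration of the
machinery under its stated model, not robustness to alignment artefacts in
real sequencing data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; VCF positions are
  converted on load.  Unphased or homozygous VCF records are skipped (with
  a warning for unphased heterozygotes), not errors.
* `binom_allele_p` is vectorised over `pbinom` tails; totals of zero give
  NA and class `non_analysable`.
* Orientation ties (central G = C) keep the reference strand.
* k-means is seeded; duplicated profiles always co-cluster; `k` larger
  than the profile count is an error.
* Empty feature sets give zero overlaps, not errors; an empty *query* in
  `overlap_summary()` is an error because the percentage is undefined.
* Island bins with missing values are ineligible; a bin-size mismatch
  between track and parameters is an error rather than a silent rebin.

## Scale of the shipped analyses

The test suite and the bundled pipeline run on the reference simulation
(1 Mb diploid genome, 200 origins) and smaller fixtures; permutation
panels default to a few hundred iterations and the GC-control stage to a
few small sets at a 0.05 GC bin.  These sizes are the package's chosen
desk-scale working points; all of them are plain parameters
(`pipeline_config()`, `simulation_spec()`) and scale up unchanged — at
genome scale one would raise `n_iter` to the 1,000–10,000 range and
tighten the control GC bin to 0.01.

## Known limitations

* The triplex detector is a structural heuristic; its type codes follow a
  package convention and its hit set is not comparable to
  dynamic-programming triplex scores.
* The island score definition is a declared convention (the original
  tool's semantics are unpublished); alternative readings (eligible-bin
  count, probabilistic scores) would change borderline islands.
* Per-SNP depth summation double-counts reads spanning two SNPs.
* The count-level and sequence-level simulators share the depth model but
  not a read model; neither emulates reference bias.
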