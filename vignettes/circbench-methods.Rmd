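---
title: "Benchmarking circRNA junction predictions against imperfect data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking circRNA junction predictions against imperfect data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Back-splice junctions (BSJs) — the non-colinear junctions unique to circular
RNAs — are detected from reads that span them. Deep, paired-end, high-quality
sequencing of RNase-R-treated RNA is the gold standard for this, but most
available libraries are ordinary total RNA-Seq: no RNase R enrichment, often
single-end, shallow, or error-laden. `circbench` provides the machinery to ask,
quantitatively: *how fragile are BSJ predictions under those imperfections, and
which properties of a circRNA make it robustly predictable anyway?*

The package implements an evaluation framework, not a circRNA caller. Its
stages are: (1) truth-label predictions from a total-RNA library against a
matched RNase-R library; (2) degrade the input reads in three controlled ways
and re-evaluate; (3) contrast the properties of the circRNAs that survive
degradation with those that are lost.

## Truth labelling by RNase R enrichment

RNase R is a 3'→5' exoribonuclease that digests linear RNAs; covalently closed
circles survive. For a candidate junction with `m` supporting reads in the
treated library and `n` in the untreated one, the enrichment score is

    E = (m - n) / (m + n),   E in [-1, 1]

and a candidate is labelled **true** iff `E > 0`, strictly: a tie (`m == n`) is
conservatively false, and a candidate absent from the treated library gets
`m = 0`, hence `E = -1`. The evaluation universe is the total-RNA prediction
set — candidates seen only after treatment do not enter the true positive rate,
whose denominator is everything the total-RNA run predicted. Junction identity
across samples and callers is the exact coordinate triple `(chrom, start,
end)`; strand is recorded but ignored for matching because caller conventions
differ. Candidates with fewer than two junction-spanning reads are discarded
before any evaluation.

True positive rates are reported both as fractions and as percentages rounded
half-up to two decimals, the convention used when such rates are quoted in
print (e.g. 1362 of 3488 candidates → 39.05%).

## The three degradation models

* **Single-end projection** keeps exactly one mate of each pair, unmodified.
* **Subsampling** keeps each *pair* independently with probability `rate`
  (Bernoulli per pair rather than exact-count sampling: streaming-friendly,
  order-independent, and it never breaks mate pairing). Whether real depth
  titrations sample mates jointly is rarely documented; pair-level sampling is
  the only choice that leaves the data usable by paired-end callers.
* **Error injection** replaces, in every read, exactly `min(k, L)` distinct
  uniformly chosen positions with a base drawn uniformly from `{A,C,G,T,N}`
  minus the original (an original `N` becomes one of `{A,C,G,T}`). Quality
  strings are left untouched — no pipeline stage consumes them, and editing
  them would conflate base errors with quality-score effects.

All three are deterministic given a seed. Error injection consumes a fixed
amount of randomness per read (a full position permutation plus one
replacement draw per position), so with a fixed seed the mutated position sets
are *nested* across increasing `k`. This is deliberate: it turns "more errors
never help" from a statement in expectation into a per-run guarantee, which is
what makes detected-circRNA counts provably monotone along an error titration
driven by one seed. Uniform error positions are the default; real libraries
often decay toward the 3' end, but a positional bias model would only matter
to a stage that reads qualities, and none does.

## The two-sample Kolmogorov–Smirnov test

The property comparison needs a two-sample K-S test; it is implemented from
scratch so that the statistic is exactly the tie-aware supremum

    D = sup_t | F1(t) - F2(t) |

over the pooled sample points, and the two-sided p-value is the asymptotic
Kolmogorov tail `Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)`
evaluated at Stephens' small-sample-corrected argument
`lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D`, `ne = n1*n2/(n1+n2)`. The
alternating series is truncated once terms fall below 1e-10 (the truncation
index grows like `3.4 / lambda`, capped, with `D = 0` short-circuited to
`p = 1`) and the result is clamped to `[0, 1]`. Tests verify `D` against a
brute-force oracle on exhaustive small samples and calibrate the p-value's
type-I error on null replicates; `stats::ks.test` serves as an independent
cross-check of `D` (exact agreement) and of `p` (approximate — R omits the
0.12 correction). The test is two-sided and no significance level is imposed;
callers decide. The reported `shift_direction` uses medians, not means,
because read-count distributions have heavy right tails.

## Per-circRNA properties and the S1/S2 contrast

True circRNAs from the perfect-data evaluation are split by a degraded rerun:
**S1** = still detected (≥ 2 junction reads), **S2** = lost. Four properties
are compared between the groups:

* **distance** — the 1-based inclusive span `end - start + 1` between the
  back-splice sites (inclusivity is a convention; nothing downstream depends
  on the off-by-one).
* **E** — the enrichment score above.
* **R** — the junction reads ratio `R = n / N`, where `N` counts all reads,
  circular and linear, around the circularised region. `N` presumes alignment
  data this package does not ingest, so it is operationalised as: junction
  reads plus linear-derived reads overlapping either back-splice site. In
  synthetic mode that is computed exactly from read provenance; for external
  data it must arrive as a precomputed column in the prediction table.
* **reads** — the junction read count `n` from the *untreated* library, the
  quantity actually available at prediction time (the treated-library count
  `m` would not be).

## The synthetic benchmark

Real inputs for this framework are a matched pair of total-RNA and RNase-R
libraries plus external caller outputs. The generator replaces all of that
with a ground-truthed toy system so every stage runs from a single seed in a
couple of minutes.

**Transcriptome.** One random chromosome (default 500 kb) carries, without
overlap between loci: 100 linear transcripts (log-normal expression, log-sd 1);
50 circRNA spans, each embedded with probability 0.8 in a linear *host*
transcript extending 200–800 bp beyond it on each side; and 25 *decoy* loci
(below). Hosts matter twice: they supply the linear reads that make the
junction-ratio denominator non-trivial, and they deplete under RNase R like
any linear RNA. CircRNA spans are log-normal (median 800 bp, clamped to
[300, 3000]) and drawn independently of expression, so the splice-distance
property has no built-in association with detectability — the negative control
in the property comparison.

**CircRNA abundance.** The defining difficulty of circRNA detection is that
junction coverage sits near the detection threshold: circRNAs are typically
one to two orders of magnitude rarer than their host mRNAs. The generator
therefore parameterises circRNA expression directly in junction-coverage
units: the expected number of BSJ-spanning pairs per circRNA at the configured
depth follows a truncated Pareto law (shape 1 — Zipf-like, the standard
heavy-tailed model for transcript abundance) with median 2 and cap 25. Median
2 places half the planted circles within reach of the ≥ 2-read filter at full
depth but not at half depth, reproducing the regime in which depth titration
bites; the heavy tail supplies the wide read-count spread that the S1/S2
contrast measures. Internally each coverage target is converted to an
expression weight against the realised linear background (the < 1% circular
mass itself is neglected in that normalisation).

**Reads.** Fragments are drawn from transcripts proportional to expression ×
length; fragment length is Normal(250, 50) truncated to [read length,
transcript length]; circular transcripts are fragmented *on the circle*, so a
fragment may wrap the junction and yield BSJ-spanning mates; sequenced strand
is uniform; qualities are constant `I` because no stage reads them. For a
circle of length `C` and read length `L`, a given mate spans the junction with
at least `min_overlap` bases on each side for exactly `L - 2*min_overlap + 1`
of the `C` equally likely fragment anchors — the closed form the read
simulator is tested against.

**RNase R.** Each treated-library fragment survives with probability 0.05 if
linear-derived and 1.0 if circ-derived. No measured depletion efficiency
exists; 0.05 is a free parameter and is documented as such. The treated run
draws `depth * rnaser_depth_factor` fragments (default factor 5) before
depletion: a digested pool is sequenced at instrument depth, not at a fraction
of it, and without this renormalisation the treated and untreated junction
counts of a genuine circle would be equal in expectation — enrichment
labelling would be a coin flip even for perfect circles, which contradicts
what the treatment is for. The factor is deliberately conservative; relative
enrichment in real treated libraries is far larger.

**Decoys — the false-positive channel.** Each decoy is a reported junction key
whose "probe" is ordinary contiguous sequence from a dedicated low-expression
linear locus (coverage law = half the circRNA law). Decoys therefore attract
supporting reads through sheer coverage, not circularity; under RNase R they
deplete like the linear RNA they really are and label false. They keep the
true positive rate meaningfully below 1 and give the read-count re-ranking
something to discard.

**The pseudo-predictor.** Prediction is anchor-based against the *planted*
junction probes (the flanks concatenated across each BSJ, and the decoy
probes): a read supports a junction if it contains the probe's central core —
`min_overlap` (default 10) bases on each side of the junction point — on
either strand with at most `max_mismatch` (default 2) mismatches; `N` counts
as a mismatch; a pair counts once. Searching only planted probes is a design
choice, not a shortcut: the package evaluates the evaluation framework, and a
knowledge-based detector gives controllable sensitivity with a realistic
degradation response at desk scale. Matching a window with ≥ `min_overlap`
flanks and ≤ `max_mismatch` mismatches is equivalent to matching the fixed
2×`min_overlap` core (any wider alignment contains the core with no more
mismatches; the core alignment itself qualifies), which is what the
implementation exploits: cores are split into `max_mismatch + 1` exact
segments (pigeonhole), indexed in direct-address tables, and candidate hits
are verified in full — in C++, because ~130 probes × 400k reads × 12
degradation conditions is far beyond what per-pattern string matching in R
sustains.

Consequences worth knowing before interpreting results: with 2 of 100
positions mutated, a 20 bp core still tolerates the damage almost always, so
the `k = 2` condition is nearly indistinguishable from clean data — the
response curve steepens from `k = 5` on (hypergeometric: the expected core
damage at `k` errors is `k/5`). And because an injected error occasionally
*completes* a near-miss alignment elsewhere, the count of all candidates is
monotone only for planted circles, not for the decoy channel.

## What the generator does and does not emulate

It emulates: the linear/circular abundance contrast, RNase R depletion with a
realistic library-size renormalisation, junction coverage near the detection
threshold, coverage-driven false positives, host-gene linear background at the
splice sites, and deterministic degradation titrations. It does not emulate:
alignment to a real genome (and hence mapping ambiguity, the main
false-positive source for real callers), splice isoforms and intron lariats,
positional quality decay, GC bias, rRNA carry-over, or multiple chromosomes.
Passing tests on this benchmark therefore validate the *evaluation machinery*
and the qualitative degradation response — they say nothing about the accuracy
of any particular circRNA caller on real data, and the absolute true positive
rates here (dominated by the decoy channel's size) are not comparable to rates
on real libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in memory; BED-like files are
  0-based half-open and converted only at the I/O boundary.
* Duplicate prediction rows merge by summing counts, keeping the first-seen
  strand; output is key-sorted, so parsing is order-independent and
  re-serialisation is idempotent.
* `top_k_by_reads` breaks read-count ties by lexicographic key order —
  deterministic under permutation of the input.
* All randomness flows from one global seed through
  `derive_seed(seed, stage_label)` (a 31-bit polynomial hash); no stage reads
  OS entropy. The error-titration conditions deliberately share one derived
  seed (see the nesting argument above).
* Degenerate inputs fail loudly: enrichment with `m + n = 0`, junction ratio
  with `N = 0`, K-S with an empty sample, and an S1/S2 comparison with an
  empty group are errors, not silent NAs; an empty labelled set reports
  `tpr = NaN`, not 0.
* gzip FASTQ is detected from magic bytes, not file extension.

## Problem sizes used by the test suite

The reference benchmark in the tests runs the full default configuration (50
circles, 200k pairs, all ten degradation conditions — about two minutes);
module tests use a 12-circle / 15k-pair configuration. The K-S oracle check
enumerates all sample pairs of size ≤ 8 over a three-letter alphabet
(164² pairs) and calibrates the p-value on 2,000 null replicates at
n1 = n2 = 100. These sizes are the package's choices for a fast, deterministic
suite; the generator scales to larger configurations without code changes.

## Known limitations

* The junction-ratio denominator for external data depends entirely on the
  supplied `region_reads` column; the package cannot validate it.
* The asymptotic K-S p-value is approximate for the small S1/S2 groups a
  50-circle benchmark produces (it is accurate to within a few percent of the
  exact tail in that range, and the brute-force `D` is exact); an exact or
  permutation p-value is out of scope.
* The pseudo-predictor cannot discover junctions that were not planted, so
  recall against unknown truth is not a measurable quantity here — by design.
* KNIFE-style junction ids that reference annotated exon boundaries are taken
  at face value; reconciling them with CIRI coordinates on real data may
  require external annotation, and the exact-triple matching rule is this
  package's convention.
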