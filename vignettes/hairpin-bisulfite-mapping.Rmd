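---
title: "Diagnosing bisulfite read mapping failure with hairpin sequence recovery"
author: "hairpinBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing bisulfite read mapping failure with hairpin sequence recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Whole-genome bisulfite sequencing converts unmethylated cytosines to
thymines before sequencing. The treatment is what makes methylation readable,
but it also destroys information: most cytosines in a mammalian genome are
unmethylated outside CpG context, so a converted read is drawn from an
effectively three-letter alphabet. Aligners compensate by collapsing C to T
in both read and reference ("three-letter" mapping), which removes
conversion mismatches but makes distinct genomic locations collide. The net
effect is that bisulfite libraries map far worse than ordinary DNA
libraries, and a large fraction of reads is lost as ambiguous or unmapped.

Hairpin bisulfite sequencing offers a unique window into this problem. A
hairpin adapter covalently links the Watson and Crick strands of each DNA
duplex before denaturation, so a read pair observes *both* converted
strands of the same molecule. Because methylation state is what decides
whether a position reads C or T on one strand (and G or A on the other),
the two mates together determine the original, unconverted sequence — and
any position where the mates are inconsistent with the conversion chemistry
must be a PCR or sequencing error.

`hairpinBS` implements this whole loop on synthetic data: a simulator with
the statistical structure of real hairpin libraries, the original-sequence
recovery, a minimal bisulfite-aware read mapper with an exhaustive oracle,
and the downstream analyses that connect mapping failure to sequence
entropy, read length, and mismatch location.

## The recovery rule table

After orienting the A-enriched mate into Watson coordinates
(reverse-complementing it), each overlap position shows a pair of bases
(t, a):

| t (T-enriched) | a (A-enriched) | meaning                        | recovered |
|---|---|---|---|
| x | x (equal)   | no conversion at this position; C/C and G/G also carry a methylation call | x |
| T | C           | unmethylated Watson C, converted on the T strand only | C |
| G | A           | unmethylated Crick C (seen through the Watson G)      | G |
| anything else  | | chemically impossible: PCR or sequencing error | N |

Equal pairs (C,C) and (G,G) call a *methylated* Watson or Crick cytosine;
(T,C) and (G,A) call the unmethylated states. The mirror cell (C,T) is an
error, not a bisulfite signal: the hairpin construct fixes which mate is
T-enriched, so the table is deliberately asymmetric (a `swapMates` switch
exists for mislabeled input).

Errors are recovered as `N` rather than a guessed base. This is a design
choice: `N` mismatches everything in the mapper, so an undetected
miscorrection can never masquerade as a clean alignment. The alternative
(`errorBase = "t"`) takes the T-enriched base.

```{r recovery-example}
library(hairpinBS)
# the A-enriched mate arrives reverse-complemented (delivered orientation)
aDelivered <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet("ATAC")))
p <- HairpinPairSet("p1", tRead = "ATGT", aRead = aDelivered)
rec <- recoverPairs(p)
recoveredSeqs(rec)   # "ATGC": both conversions undone
methCalls(rec)       # the two converted positions call unmethylated
```

## The simulator

The generator's defaults are the study conditions, chosen to mirror a
mammalian hairpin library:

* **Genome**: random sequence at 42% GC (a typical mammalian value), one
  record, with optional planted repeat families. Repeat families can be
  `collapse = "ct"` or `"ga"`: copies that differ only at C-vs-T (or
  G-vs-A) positions, i.e. distinguishable as plain DNA but identical after
  three-letter collapse. These reproduce, in miniature, the mechanism by
  which conversion creates ambiguity.
* **Methylome**: CpG cytosines methylated with probability 0.8, all other
  cytosines 0.02 — the rates typical of somatic mammalian methylomes. CpG
  methylation is strand-symmetric by default (`hemimethylationRate = 0`).
* **Read lengths**: `{100: 0.634, 75: 0.2, 50: 0.166}`. Real hairpin lanes
  are dominated by full-length 100–101 bp reads (about 63% in the data this
  package emulates); the remainder split between 75 and 50 is our choice
  and fully configurable.
* **Conversion**: complete (`conversionRate = 1`) by default; incomplete
  conversion is supported but not part of the stock conditions.
* **Error model**: independent per-base substitutions on each mate,
  uniform over the three alternative bases, no indels (all downstream
  analyses count mismatches, and the mapper is Hamming-only). The default
  hairpin rate of 0.002/base leaves roughly 68% of 100 bp pairs free of
  detectable errors, matching the exactly-aligning fraction reported for
  real hairpin replicates. The single-end simulation study uses 1% and 10%
  instead, the two error regimes used to bracket the best possible mapping
  performance.
* **Qualities**: constant; no analysis here uses them.

What the simulator does *not* emulate: restriction-digest site enrichment,
PCR duplicates, indel errors, quality decay along the read, natural genetic
variation between sample and reference, and chimeric fragments. Passing
tests on this generator therefore demonstrate the mechanics and directions
of the analyses, not real-data magnitudes — real-genome percentages depend
on genome repeat structure and aligner internals that are out of scope
here.

## The mapper

`buildMapperIndex()` hashes every k-mer (default k = 16, the classic
sliding-window width of hash-based bisulfite aligners) of each reference
*view*. Bisulfite mode indexes four views — the C→T and G→A conversions of
the Watson text and of its reverse complement — so a non-directional read
matches exactly one view with zero conversion-induced mismatches.
Plain mode indexes the two unconverted strands.

`mapReads()` collects candidate locations from exact seed hits
(non-overlapping k-mers across the read), scores each candidate by Hamming
mismatches between converted read and converted window, and reports:

* **unique** — one location attains the best score within the threshold;
* **ambiguous** — several locations tie at the best score;
* **unmapped** — no location scores within the threshold.

Numerical and tie-breaking choices:

* Threshold `floor(0.1 × length)` mismatches. The 10% default is a
  stand-in: real aligners' effective thresholds are not published, so
  real-data category percentages are not expected to transfer.
* A location reachable under both conversions counts once, keeping the
  minimum score; ties between views resolve in the fixed canonical order
  (C→T before G→A, Watson before Crick). Locations sort by (sequence,
  position, strand).
* At most 100 tied best locations are retained per read; reads with more
  are ambiguous and `nBest` records the exact tie count (the count is
  known at no extra cost, so we store it rather than a ">cap" marker).
* `N` mismatches everything, so recovered-error positions can never help
  an alignment.
* Sensitivity: with seeds across the whole read, any location with fewer
  mismatches than the number of *disjoint* seeds (`floor(n/k)`) is
  guaranteed to be found; the terminal anchored seed improves this in
  practice but adds no guarantee. Above that score the seed mapper may
  miss locations the exhaustive scan finds — the oracle-equivalence tests
  are therefore run in regimes where best scores sit well below the bound.
* `bruteForceMap()` scans every position of every view with the same
  scoring and category rules and no heuristic; it is the correctness
  oracle and the arbiter of "genuinely repeated" origins.

## The analyses

**Sequence entropy.** `sequenceEntropy()` is base-2 Shannon entropy of a
read's A/C/G/T composition, 0 for a homopolymer and 2 for uniform
composition (these two closed forms force the base-2 logarithm). `N` is
excluded from the frequencies; an all-`N` sequence is an error. Bisulfite
conversion depletes C, so converted reads concentrate toward T-rich,
low-entropy compositions; `entropyByCategory()` buckets per-category
entropies in 0.1-wide bins (exact zeros get their own bucket, bucket x
covers ((x−1)/10, x/10]).

**KS comparisons.** `ksTwoSample()` computes the exact sup-CDF difference D
(ties handled exactly) with the standard asymptotic p-value; exact
small-sample p-values are out of scope and only D is asserted in tests.
The "maximum difference" between category distributions is interpreted as
this two-sample KS statistic, consistent with the adjacent KS tests; the
bucket-level maximum difference can be read off `entropyByCategory()`
output if wanted.

**Bootstrap recovery benefit.** Each of B = 50 replicates draws pairs with
replacement, keeps the exactly-aligning subset, maps both converted mates
in bisulfite mode and the recovered originals in plain mode at identical
thresholds, and records
`unique%(recovered) − mean(unique%(T), unique%(A))`. The p-value is
one-sided (the fraction of replicates with non-positive improvement) and
the variance is the sample variance over replicates. Because mapping is
deterministic per read, each distinct pair is mapped once and replicates
resample the cached per-pair categories — numerically identical to
remapping inside every replicate, at a fraction of the cost. The replicate
size defaults to the input size; the reference analysis used
millions of reads per replicate, which desk-scale studies replace by their
input size.

**Mismatch location.** `mismatchWindowSplit()` strata pairs whose k flagged
errors are confined to the first 25 bases versus the remainder (pairs with
errors on both sides belong to neither; k = 0 has no side and is reported
once as the exact stratum). `mismatchLocationEffect()` maps each stratum's
T-enriched reads with seeds confined to the first `seedRegion = boundary`
bases. This confinement is a deliberate modelling choice: the production
aligners whose behaviour this analysis characterises anchor their seeds at
the 5' end, which is precisely why 5' mismatches are costlier there. With
the package's default full-read pigeonhole seeding the left/right asymmetry
would vanish by construction, so the analysis emulates the end-anchored
regime instead; the mapper's default remains full-read seeding everywhere
else.

**Cross-strand rescue and mapper union.** `crossStrandRescue()` reports, in
each direction, the share of uniquely mapped reads whose partner mate is
not uniquely mapped (transferring a unique partner's position rescues those
reads); `mapperUnion()` reports the OR of two mappers' unique sets.

**Methylation estimation.** `estimateMethylation()` pools the recovery
calls, derives each call's CpG/CpH context from the recovered sequence
(Watson call at offset i is CpG iff i+1 reads G; Crick call iff i−1 reads
C; calls whose context base is off-read or an error are excluded), and
reports rates with Wilson score intervals. Note that overlapping reads and
the two strands of one CpG yield correlated calls; the call-count interval
is honest only at low coverage, which is how the parameter-recovery study
is designed.

## Study sizes

The stock studies in the test-suite and the acceptance script run at desk
scale, chosen so each analysis has clear statistical power on one CPU:
100 kb genomes and 10,000 pairs for the recovery round trip; twenty
randomized 50 kb genomes × 500 reads for oracle equivalence; a 50 kb
repeat-rich study genome (30 low-GC repeat families of 150 bp, one third
each C→T-collapsing, G→A-collapsing and verbatim — about 18% of the
genome) with 2,500–3,000 pairs for the directional analyses; a 500 kb
genome at ~0.3× coverage for methylation-rate recovery. The directional
findings (positive recovery benefit, entropy ordering
unmapped ≤ ambiguous ≤ unique, unique% rising with read length, 5'
mismatches costlier and increasingly so with k, conversion never raising
mean entropy) are asserted as directions; their magnitudes are properties
of the synthetic genome, not of any real genome.

## Limitations

* Hamming-only scoring; no indels anywhere in the loop.
* Mates are assumed to overlap fully after orientation (ragged pairs are
  truncated to the shorter mate); partially overlapping mates would need
  gapped inter-mate alignment, which is out of scope.
* PCR and sequencing errors are indistinguishable by construction, as in
  the underlying chemistry.
* The mapper is a minimal stand-in: no FM-index, no mapping quality, no
  paired-end co-mapping constraints. Its percentages are not comparable to
  production aligners on real data; its role is to make the mechanisms
  measurable and exactly checkable against an exhaustive oracle.
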