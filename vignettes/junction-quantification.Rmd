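---
title: "Quantifying exon-junction usage with bait sequences: models and methods"
author: "baitquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exon-junction usage with bait sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitquant)
```

## The problem

Alternative splicing of a multi-exon gene — here an *Fmr1*-like gene with an
optional exon 12, an optional exon 14, three acceptor sites on exon 15
(A/B/C) and two on exon 17 (A/B) — can be read directly out of bulk RNA-Seq:
a read that crosses an exon–exon junction is unambiguous evidence for that
particular splice. `baitquant` implements a bait-based junction quantifier:
fixed-length reference sequences ("baits") are built across each junction of
interest, reads are retrieved by *full-identity* (no-mismatch) local matching,
filtered through a Karlin–Altschul E-value window, counted when they span the
junction with a minimum anchor on each side, and normalized to RPKM (reads
per kilobase of bait per million sequenced reads). Stage effects are then
tested non-parametrically (Kruskal–Wallis across age groups, Dunn's post-hoc
on pairs, gated on the omnibus test).

The biological signal this pipeline targets is developmental regulation of
exon-14 skipping in the rodent forebrain: skipping shifts the reading frame
(exon 14's length is not a multiple of 3), creating premature termination
codons (PTCs) on exon 15 when acceptor site 15A or 15B is used, or a stop on
exon 17 with site 15C. The skipped transcripts are therefore candidate
substrates for nonsense-mediated decay, and their junction reads (13–15A/B/C)
are expected to be scarce relative to the inclusion junction (13–14).

## Bait design

A junction bait takes the last `bait_len/2` nucleotides of the donor exon and
the first `bait_len/2` of the acceptor exon, measured from the chosen
acceptor-site offset, so the junction sits exactly at the bait midpoint
(default 100 nt, 50:50). A constitutive bait is the plain concatenation of a
run of never-skipped exons; the default panel includes the 1,122-nt exon 1–11
coding bait, which serves as a length-robustness control for the 100-nt
junction baits. A read can only support a junction if its match covers the
midpoint with at least `a_min` nucleotides on each side (default 10) — the
50:50 design implies junction coverage but says nothing about a minimum
overhang, so `a_min` is this package's explicit knob.

## Matching and the E-value window

"Full identity" is interpreted per reported local alignment: the matcher
reports, per read and strand, the *maximal exact common substring* with the
bait (k-mer seeding plus ungapped extension along each seeded diagonal;
common substrings shorter than the seed are invisible, which is irrelevant
above the E-window's length floor). The Karlin–Altschul E-value of a match of
length $L$ against a bait of length $m$ and a read database of $n$ total
nucleotides is

$$E = K\, m\, n\, e^{-\lambda r L}$$

with defaults $\lambda = 1.28$, $K = 0.46$, $r = 1$ approximating ungapped
nucleotide BLAST with +1/−2 scoring. The retrieval filter keeps hits with
$E \in [4\times10^{-60},\ 4\times10^{-23}]$ and at most 20,000 hits per bait
(smallest E first). Because $E$ is monotone in $L$, the window inverts to an
integer match-length window $[L_{\min}, L_{\max}]$; with $m = 100$ and
$n = 10^9$ this is $[60, 100]$. The window is re-derived per sample from its
actual database size ($n = \sum$ read lengths), so the same E-value bounds
adapt to library depth. With the default window, $L_{\min} \geq 43$ for any
$n \geq 1$, which keeps it above both the seed length and the 2·`a_min`
junction core — two facts the fast scan below relies on.

For speed, each sample is scanned once: every countable read must contain,
verbatim (or reverse-complemented), either the 2·`a_min`-nt junction core of a
junction bait or one of a set of k-mers tiled across a constitutive bait at a
step no larger than $L_{\min} - k + 1$. Those seeds are located exactly with
`Biostrings::matchPDict` over the concatenated read set, and only candidate
reads are passed to the full maximal-match routine — a pure optimization, not
an approximation, and the test suite asserts equality with the exhaustive
per-read path.

## The synthetic study

The simulator emulates the design of a developmental brain RNA-Seq project:
13 forebrain stages (E14–P112), about 4 replicates per stage, unpaired 101-nt
reads. Its ground truth is a per-stage profile: the focal gene's share of the
library, the exon-14 skip probability, acceptor-site usage vectors for exons
15 and 17, and an exon-12 inclusion probability. The package defaults encode
the study conditions this pipeline is meant to recover:

* total focal-gene abundance declines monotonically from E14 to P112 with an
  elevation at P3;
* exon-14 skipping of 0.45 during E17–E20 against a 0.10 baseline;
* exon-15 site usage (A, B, C) = (0.40, 0.35, 0.25), so site A accounts for
  about 40% of 14–15 junctions;
* exon-17 site usage (0, 1): site 17B is treated as the constitutive acceptor
  and the 16–17A bait is expected to retrieve nothing;
* exon-12 inclusion 0.25 — a free default; exon 12 is not baited and only
  perturbs transcript lengths.

Reads are drawn per sample: a read comes from the focal gene with the
profile's target fraction (its transcript class sampled from the event
probabilities) or from one of 50 random 2,000-nt decoy transcripts; start
positions are uniform over valid positions, strands uniform, substitution
errors optional (default 0 — under a full-identity filter errors act purely
as count deflation). Everything is a deterministic function of the seed;
per-sample seeds are derived by hashing the sample id so adding a sample
never perturbs another's reads.

Two free scale choices deserve justification. The library size default
(2×10^5 reads/sample) is a desk-scale working size — the original datasets'
depths are not on record here, and all statistics are depth-normalized. The
base focal-gene fraction (0.04 at E14) is a *depth* choice made by power
analysis, not a biological abundance claim: at 2×10^5 reads and 4 replicates
it yields roughly 1,000–1,400 exon-13 junction reads per stage, putting the
binomial standard error of recovered skip and site-usage fractions near
0.013, small against the 0.35 skip contrast and the ±0.05 recovery tolerance
the tests use. The decoy background exists to be the RPKM denominator and to
not collide with baits; it is not a realistic transcriptome, so the focal
fraction plays the role a gene's coverage would play in real data.

What passing these tests shows — and does not show. The simulator has uniform
coverage, no positional or GC bias, no indels, constant quality, and a random
background. Recovery under these conditions validates the pipeline's
arithmetic (counting, windowing, normalization, testing), not its robustness
to alignment artifacts, paralogs, or coverage bias in real libraries.

## The fixture gene

Real *Fmr1* sequences are not packaged; a seeded fixture gene reproduces the
structural facts the analysis depends on: 17 exons; exons 1–11 of 102 nt each
(so the constitutive bait is 1,122 nt); optional exon 12 of 105 nt (a
multiple of 3 — its skipping is in-frame); exon 14 of 52 nt (not a multiple
of 3 — skipping shifts the frame); exon-15 acceptor offsets A/B/C = 0/21/33
and exon-17 offsets A/B = 0/12 (multiples of 3, so site choice preserves
codon phase and frame assignments depend only on exon-14 inclusion). Stop
codons are implanted so that the full-length frame terminates on exon 17
while the shifted frame hits stops inside exon 15 between the A/B and B/C
offsets (PTCs for sites A and B) and, failing those, early on exon 17 (site
C). Junction straddle codons are guarded by forcing a C at donor-exon ends.
Sequences are rejection-sampled until every bait occurs exactly once in each
transcript that carries its junction and nowhere else — including reverse
complements and the decoy background.

## Statistics

Kruskal–Wallis uses midranks and the standard tie correction (delegated to
`stats::kruskal.test`, with the correction factor reported); the chi-square
approximation is used at all group sizes, as is conventional, with a seeded
Monte-Carlo permutation p-value available for very small groups (full
enumeration over all assignments of 52 observations into 13 groups is not
tractable, so "exact" is approximated by permutation). At this design's group
sizes — 13 groups of 4 — the chi-square approximation is measurably
conservative: the package's own type-I calibration check puts its null
rejection rate near 3% at nominal 5%, while the permutation p-value is
calibrated by construction. That conservatism is why the permutation option
exists and when it should be preferred. Dunn's z statistics
are computed from the pooled midranks with the tie term
$\sum (t^3-t) / (12(N-1))$; the default reports classical per-pair
significance at $\alpha = 0.05$ with no multiplicity adjustment —
matching a procedure that declared pairs significant at P < 0.05 without
stating an adjustment — and Bonferroni/Holm are available. Dunn is gated:
it runs only when the omnibus Kruskal–Wallis rejects at $\alpha$.

Outlier exclusion operationalizes "removed because anomalously many reads
were retrieved across different target sequences": a sample is excluded when
its RPKM exceeds its (structure, stage) group median by more than 5 MADs on
at least 3 distinct baits. The narrative rule this stands in for has no
published algorithm, so both parameters are exposed and the exclusion report
is part of the run output.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; exon numbering keeps 1-based
  display labels.
* The E-window inversion nudges the ceiling/floor by 1e-9 to absorb
  floating-point edge effects, and is cross-checked against a forward scan.
* All-identical stage values give H = 0, p = 1 (the tie correction would be
  0/0); all-zero sibling counts give flagged `NA` usage fractions; zero
  denominators give flagged `NA` ratios.
* Matcher tie-breaks: longest match, then smallest bait start, then smallest
  read start; a read hitting on both strands is counted once.
* The PTC rule is the exon-junction-complex convention — a stop more than
  50 nt (configurable) upstream of the last exon–exon junction — applied to
  the stop codon's 3' end; a stop in the last exon is never a PTC.

## Problem sizes used by the test suite

Unit tests run on toy genes and 1–4k-read samples. The study-level checks use
the design sizes: 13 stages × 4 replicates × 2×10^5 reads for recovery,
usage, and determinism; 40 replicates of 5×10^4 reads for simulator
calibration; 1,000 replicates of 13 × 4 null draws for the type-I error of
the stage test. These sizes were chosen so a complete run is a few minutes on
one core while keeping recovery standard errors well inside the stated
tolerances.

## Known limitations

* Gapped alignment, mismatch tolerance and quality-aware matching are out of
  scope; an external BLAST adapter could be added behind the same interface.
* The E-value window's correspondence to any particular BLAST service
  configuration is approximate by construction (the original flavor and
  effective database-length convention are unknown); the window is exposed
  as two bounds plus scoring parameters.
* Junction probabilities for the closed-form expectations encode the
  Fmr1-like event semantics (exons 12/14/15/17); other gene architectures
  can be spliced and baited, but the profile machinery would need their event
  map.
* The mapping from the 24 transcript combinations to a non-redundant protein
  isoform catalogue is deliberately not modeled — it depends on protein-level
  definitions outside this package's data.
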