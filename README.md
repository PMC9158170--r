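# baitquant

Quantification of alternative splicing from bulk RNA-Seq by **exact matching
of junction-spanning reads against bait sequences**, with Karlin–Altschul
E-value filtering, RPKM normalization and non-parametric stage statistics.

## What it is for

For a multi-exon gene with an optional exon and alternative 3' splice-acceptor
sites — the motivating case is *Fmr1*, whose exon 14 can be skipped and whose
exon 15 has three acceptor sites (A/B/C) — a sequencing read that crosses an
exon–exon junction is direct evidence for one specific splice. `baitquant`
builds fixed-length baits across each junction (100 nt, 50:50 between the two
exons), retrieves reads at full identity (no mismatches within the reported
match), keeps matches whose E-value

&nbsp;&nbsp;&nbsp;&nbsp;*E* = *K·m·n·*exp(−*λ·r·L*)

falls in a configurable window (defaults 4×10⁻⁶⁰ to 4×10⁻²³, with a 20,000-hit
retrieval cap), counts a read when its match covers the junction with ≥ 10 nt
on each side, and converts counts to RPKM
(count / ((bait_len/1000)·(total_reads/10⁶))). Per-bait stage effects are
tested with the tie-corrected Kruskal–Wallis H (χ², df = k−1) and, when the
null is rejected at α = 0.05, Dunn's post-hoc pairwise z tests. A robust
outlier rule (group median + 5·MAD on ≥ 3 baits) excludes samples that
retrieve anomalously many reads across targets.

The package is audience-complete for desk work: it ships a seeded
**synthetic-data generator** — a fixture gene reproducing the structural facts
that matter (1,122-nt constitutive exon 1–11 bait, frame-shifting exon-14
skip, premature termination codons on exon 15 for sites 15A/15B and on exon
17 for 15C) and a 13-stage forebrain study design (E14…P112, 4 replicates,
unpaired 101-nt reads, elevated exon-14 skipping at E17–E20, site-15A usage
near 40%) — so every downstream stage is testable without downloads. It also
annotates ORFs and PTCs under the 50-nt exon-junction rule, flagging
NMD-candidate transcripts.

## Worked example

Simulate one library from the E19 profile (skip fraction 0.45) and quantify
the default bait panel:

```r
library(baitquant)
bg    <- make_background(2, n = 50, len = 2000)
gene  <- make_gene(1, background = bg)
baits <- default_bait_set(gene)
prof  <- default_study_profiles()[["E19"]]
cfg   <- simulation_config(library_size = 50000)
reads <- simulate_sample(gene, bg, prof, cfg, sample_seed = derive_seed(1, "demo"))
quantify_sample(baits, reads)
```

```
   bait_id read_count bait_len total_reads  rpkm
1    E1-11        911     1122       50000 16239
2   J10-11         60      100       50000 12000
3   J13-14         30      100       50000  6000
4  J14-15A          9      100       50000  1800
5  J14-15B          9      100       50000  1800
6  J14-15C          7      100       50000  1400
7  J13-15A         10      100       50000  2000
8  J13-15B          9      100       50000  1800
9  J13-15C          8      100       50000  1600
10 J16-17A          0      100       50000     0
11 J16-17B         75      100       50000 15000
```

Reading it: `E1-11` is the 1,122-nt constitutive coding bait and `J10-11` a
constitutive junction — both track total gene output. `J13-14` counts
exon-14-containing messages; the `J13-15*` rows are the skipping junctions
(here 27 of 57 exon-13 junction reads, an estimated skip fraction of 0.474
against a simulated truth of 0.45); `J14-15A/B/C` split the 14–15 junction by
acceptor site; `J16-17A` retrieves nothing because site 17B is the
constitutive acceptor in the design. RPKM divides each count by bait length
(kb) and library size (millions): 30 reads on a 100-nt bait in a 50,000-read
library → 30 / (0.1 × 0.05) = 6000.

The full study — 13 stages × 4 replicates, simulation through statistics —
is one call:

```r
run <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
print(run)                         # significant baits, excluded outliers
summary(run)                       # per-bait H/df/p, skip estimates, usage
run$stats[["J13-14"]]$dunn         # Dunn pairs, e.g. E14 vs E17..E20
plot(run)                          # per-bait RPKM box plots by stage
render_summary(run, "run1/report") # figures + text digest
```

`run1/` receives `rpkm.tsv`, `stats_kw.tsv`, `stats_dunn.tsv`,
`outliers.tsv`, `samples.tsv` and a JSON metadata sidecar; identical config
and seed reproduce the tables byte for byte.

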