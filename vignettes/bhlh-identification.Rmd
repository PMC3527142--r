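---
title: "Identifying and classifying bHLH transcription factors in genomic contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying bHLH transcription factors in genomic contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhscan)
```

## The problem

Basic helix-loop-helix (bHLH) transcription factors regulate neurogenesis,
myogenesis, circadian rhythms and many other developmental programs. The
motif itself — a basic DNA-binding region followed by two α-helices
separated by a variable loop, about 60 residues with 19 highly conserved
amino-acid sites — is diagnostic enough that a genome's full bHLH
complement can be recovered by translated sequence search, conserved-site
checking and phylogenetic placement against reference motifs of known
family. Animal bHLHs fall into 45 orthologous families grouped into six
higher-order groups: A (E-box binders driving neurogenesis/myogenesis), B
(proliferation, sterol metabolism), C (PAS-domain proteins), D (Emc-type
antagonists lacking the basic region), E (Hairy/Enhancer-of-split,
ending in the WRPW tetrapeptide), and F (COE).

This package implements that identification-and-classification procedure
as a tested pipeline, validated two ways: against a packaged transcription
of the ponerine ant repertoire (57 gene models whose printed tallies the
code must reproduce), and against synthetic genomes with known truth.

## Pipeline and model assumptions

### Translated scan

Each reference motif is locally aligned (Smith–Waterman, affine gaps,
PAM250) against all six reading frames of every contig. This replaces the
heuristic translated-BLAST step of genome annotation practice with an
exact algorithm: at motif scale (≤ 75 residues) exhaustive alignment is
affordable and removes seeding artifacts from the test surface. The
permissive E = 10 expectation cutoff of a BLAST search maps poorly onto
raw scores, so acceptance works in two stages: per contig, queries whose
best frame score reaches `anchor_min_frac` (default 0.25) of their
self-score are pursued (capped at the `scan_top_queries` = 10 best), and a
final *assembled candidate* must reach `scan_min_frac` (default 0.40) of
its query's self-score. Matched regions are masked and re-scanned so that
intron-separated coding regions of one query surface as secondary hits
(floor `secondary_min_score` = 20). Hits identical in contig, frame and
coding region are collapsed; overlapping spans are union-merged when the
overlap covers at least half the shorter span (a convention: it cannot
fuse tandem paralogs, which do not overlap).

### Splice-aware gene-model reconstruction

The best hit of a locus anchors reconstruction on the "working strand"
(the reverse complement for minus-strand loci). The anchor is first
trimmed to its positively scoring core — weakly matching edge codons
picked up from flanking sequence would otherwise hide a splice site — and
then extended outward. At each step two hypotheses compete:

* **contiguous extension** along in-frame codons, which, once chosen, is
  coordinate-driven (it runs to the motif boundary unless a stop codon or
  the contig edge intervenes — stop-interrupted candidates are flagged as
  possible pseudogenes rather than dropped);
* **an intron**: a boundary within 30 codons of the current coverage edge
  whose adjacent dinucleotides read `AG` (acceptor) or `GT` (donor), paired
  with every compatible splice partner within `max_intron_len` (default
  9000 bp, spanning the repertoire's observed 82–7943 bp), scoring the
  implied upstream/downstream exon against the unexplained query residues.

The intron hypothesis must beat contiguous extension by `intron_margin`
(default 5 score units); the margin prevents spurious splices when no
intron exists, because the maximization runs over hundreds of candidate
donor/acceptor sites. At most `max_introns` = 2 introns are placed per
gene (the repertoire's maximum). For coding regions split across two
assembly contigs, per-contig parts are reconstructed intron-free (matching
the repertoire's split genes, which contribute one coding region per
contig) and joined at the query split point maximizing the summed PAM250
score; the cross-contig gap is recorded without a length.

A hard invariant, asserted on every reconstruction: translating the
spliced coding segments reproduces the candidate's motif exactly.

### Conserved-site QC

Candidates are placed into the fixed 75-position reference coordinate
system by profile alignment (below) and scored at the 19 conserved sites.
The site positions and accepted residue sets are *derived from the
packaged reference alignment* — the 19 columns with the highest
modal-residue frequency, accepting residues observed in ≥ 5% of
references — rather than hard-coded, so the statistic stays self-consistent
with whatever reference set is supplied and can be overridden via YAML.
Acceptance requires ≥ 10 matches; the Emc and COE classes, whose motifs
are much shorter (roughly 30 and 50 residues), use minima of 5 and 8. A
gap at a site counts as a mismatch. Rejected candidates are reported with
reasons, never silently discarded.

### Profile alignment

Candidates are aligned to a position-specific profile of the reference
alignment (per-column frequencies, pseudocount 0.5, log-odds against the
reference residue background) by global dynamic programming with affine
gaps and free end gaps on the candidate, so short motifs are *placed*
rather than stretched. Candidate insertions (as in motifs carrying extra
helix-1 residues) become explicit insert columns; merging candidates into
the reference alignment pads all rows consistently, and ungapping any row
returns its original sequence. Profile alignment of each candidate to a
fixed curated alignment replaces de-novo progressive MSA: it is
deterministic and serves exactly the two uses the pipeline has for an
alignment (site checking and tree input), at the cost of never revising
the reference alignment itself.

### Phylogenetics

* **Distances.** The pairwise distance between aligned motifs is the mean,
  over shared ungapped columns, of δ(a,b) = (max(s(a,a), s(b,b)) − s(a,b))
  / (max(s(a,a), s(b,b)) − min(PAM250)), a normalized PAM250 dissimilarity
  that is 0 for identical residues and at most 1. The exact step-matrix
  transformation used by legacy phylogeny software is unpublished, so this
  is a documented stand-in; consequently published bootstrap values for
  specific genes are not expected to reproduce numerically, and the
  package's phylogenetic claims are validated by properties (consistency
  on additive matrices, oracle agreement) instead.
* **Trees.** Neighbor-joining (Saitou–Nei, negative branch lengths clamped
  to 0) and Fitch parsimony with NNI hill-climbing from the NJ start
  (ties keep the current tree; gaps are missing data). On
  phylogenetically structured alignments the NNI search almost always
  reaches the brute-force optimum (98/100 tree-generated instances in the
  development study); on structureless uniformly random alignments it
  plateaus near 75% — a documented heuristic gap, irrelevant to the
  pipeline's use case but worth knowing if the function is reused.
* **Support.** Bootstrap resampling of alignment columns; support of an
  edge is the percentage of replicate trees containing the same
  bipartition (or the same rooted clade when an outgroup is given).
  Defaults mirror standard practice for this analysis: 1000 NJ
  replicates, 100 parsimony replicates, threshold 50. Rooting on the
  outgroup re-attaches supports by bipartition matching, so it is
  idempotent and support-preserving.

### Tiered orthology assignment

Each accepted candidate is analysed inside its higher-order group (seeded
by its best-scoring scan query's group): candidate + the group's reference
members of one species + outgroup. For each configured method the
reference maximizing the support of the candidate+reference clade is the
proposed ortholog. Tiers: (1) every method agrees with all supports ≥ 50;
(2) every method agrees, at least one support ≥ 50; (3) tentative —
monophyly in at least one method while the others find none; (4) resolved
only against the fallback species' references (the sub-tier records which
of 1–3 applied there); (5) unclassified. Method disagreement on the
partner forces the fallback. The threshold is inclusive (≥ 50): the
source repertoire counts members whose weakest support is exactly 50 among
its confidently assigned set. With a method subset configured (e.g. NJ
only, for speed), "all methods" means all configured methods, and the call
records which ran. Candidates sharing one ortholog are reported as
putative duplications and numbered in candidate order (`PaUSF1`,
`PaUSF2`); group-E calls can additionally be checked for the terminal
`WRPW` peptide when full-length proteins are available.

## The synthetic data generator

`synthetic_reference_set()` builds the reference compendium: per-family
representative motifs, the 59-member fly set, the 51-member bee fallback
set, and the rice outgroup OsRa. Family names, groups and member counts
are real; the *sequences* are synthetic, generated by hierarchical
mutation from a single bHLH-like consensus (group ancestors at
substitution rate 0.25 on non-conserved positions, family ancestors at
0.18 from their group ancestor, species members at 0.08 from their family
ancestor, outgroup at 0.45), with the 19 designated conserved sites never
mutated. The rates were chosen once so that within-family divergence is
clearly smaller than between-family divergence within a group — the regime
in which family assignment by monophyly is meaningful at all. Emc and COE
rows are truncated to their characteristic short windows (positions 46–75
and 26–75), which exercises the lowered QC minima.

`make_benchmark()` plants mutated copies of fly reference motifs on
individual contigs: families drawn first without replacement, then with
replacement (creating in-paralog pairs), uniform codon choice for reverse
translation, 0–2 canonical `GT..AG` introns per gene at codon boundaries
with lengths resampled from the packaged repertoire's 26 observed lengths,
random strand, random flanks, plus one decoy engineered to mismatch 12 of
the 19 conserved sites (it aligns well, so it must be rejected by QC, not
missed by the scan). Intron insertion keeps at least 4 codons of coding
sequence on each side of every intron: with a substitution-only divergence
model and `GT..AG` as the only splice signal, exons shorter than a few
codons are not identifiable from sequence alone, so the generator stays
inside the identifiable regime (real repertoires do contain 2-codon
terminal exons — recovering those requires a splice-site model, which is
out of scope).

What the benchmark does *not* emulate: repeats and transposable elements,
indel divergence (except the documented insertion fixtures in the test
suite), codon bias, non-canonical splice sites, and genes overlapping on
one contig. Passing the benchmark therefore demonstrates the pipeline's
logic is correct under its stated model, not that it is robust to every
feature of real assemblies.

## Numerical and design choices

* Coordinates are 1-based inclusive; intron length is the gap between
  consecutive coding-segment coordinates (validated against every printed
  length in the packaged table, e.g. the two-intron gene with gaps 5715
  and 7943 bp). Minus-strand segments are stored in genome coordinates
  with descending transcript order.
* An intron's region label (basic / helix 1 / loop / helix 2; default
  bounds 1–13 / 14–28 / 29–59 / 60–75, a stated convention) is the region
  of the motif position whose codon follows the intron, taken through the
  candidate's profile-alignment positions so insertions and truncations
  shift correctly.
* Split-contig genes are excluded from intron length statistics and the
  intron-bearing gene count; they are listed separately, matching how the
  source repertoire tabulates its two split genes.
* Every stochastic operation draws from its own RNG stream derived from
  (seed, operation tag), so modules are independently reproducible and the
  whole pipeline is byte-deterministic for a fixed seed.
* Test and example problem sizes (benchmarks of 3–20 genes, NJ-only
  classification at 200 replicates, parsimony checks at ≤ 6 taxa where
  brute-force enumeration of all 105 topologies is exact) were chosen as
  the smallest instances that still exercise every code path; the default
  configuration keeps the published-scale replicate counts.

## Known limitations

* Maximum-likelihood tree building (quartet puzzling) is not implemented;
  the tier rules operate on the configured NJ/MP methods. Published
  three-method support triples therefore have no in-package counterpart.
* The scan assumes one gene per locus window; two genes of the same family
  closer than `max_intron_len` on the same strand would be merged into one
  locus (tandem-duplicate paralogs on different contigs, the common case,
  are unaffected).
* Domain-architecture checks beyond the terminal WRPW string (PAS, Orange
  domains) and EST/expression evidence are out of scope.
* The 19 derived site positions match the generator's invariant columns on
  the packaged synthetic reference set; for a user-supplied real reference
  alignment they are re-derived and may differ from any hand-curated list.
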