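---
title: "Methods: phase-resolved transcriptome dissection with bdellotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved transcriptome dissection with bdellotx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

*Bdellovibrio bacteriovorus* alternates between a free-swimming, non-replicative
attack phase (AP) and an intraperiplasmic, replicative growth phase (GP).
`bdellotx` implements the computational side of dissecting this dimorphic
transcriptome from bulk RNA-seq: per-ORF expression calling and AP/GP
classification, transcription start site (TSS) mapping from paired
TAP(+)/TAP(−) 5′-end libraries, discovery of the two-box sigma-28 (FliA-like)
promoter element, and detection of AP-specific intergenic small RNAs. Because
raw reads for the original experiment are not publicly available, the package
ships a synthetic-genome generator with planted ground truth; every analysis
stage is validated end to end against what was planted.

## Expression model

Reads are counted per ORF with a permissive overlap rule: a read increments
every gene it overlaps by at least one base. Counting is strand-blind by
default, matching the unstranded Illumina mRNA-seq chemistry of the era this
analysis targets; a `stranded` flag is available. Reads spanning two adjacent
ORFs are deliberately counted for both — the per-gene counts are not intended
to sum to the library size.

Expression is normalized as RPKM,
$\mathrm{RPKM} = c \cdot 10^9 / (L \cdot N)$,
with $c$ the gene's count, $L$ its length in bases and $N$ the total mapped
reads of the library (all mapped reads, not only those in ORFs; the
denominator is configurable). A gene is *expressed* in a condition when its
RPKM is strictly above 50.

Differential expression between the two conditions is a one-degree-of-freedom
goodness-of-fit chi-square computed **on the RPKM pair** $(a, b)$ against
equal expected values, $X^2 = (a-b)^2/(a+b)$, with Bonferroni correction over
the genes that received any reads. Running a count test on continuous
normalized values is statistically unusual, but it is the procedure this
analysis lineage uses; we keep it as the single-replicate testing rule and
expose the family size in the output metadata. With $a=b=0$ the p-value is
defined as 1.

Classification into phase programs uses expression flags and fold only — the
chi-square is reported alongside but does not gate categories:

* `silent`: expressed in neither phase;
* `AP_only` / `GP_only`: expressed in exactly one phase;
* `AP_dominant` / `GP_dominant`: expressed in both, with at least a 5-fold
  RPKM ratio (`>=` on the boundary);
* `shared`: expressed in both within 5-fold.

GC comparisons between AP and GP gene sets use a two-sided Welch t-test on
per-gene GC fractions; third-codon GC is available separately. Ambiguous
bases are excluded from numerator and denominator.

## TSS calling and promoters

The two 5′-end libraries differ by tobacco acid pyrophosphatase treatment:
primary (triphosphorylated) 5′ ends are captured preferentially in TAP(+), so
TAP(+)/TAP(−) enrichment marks genuine TSSs over processed ends. A position is
called when

1. it has at least 5 TAP(+) reads,
2. its depth-normalized enrichment
   $(r_+ / N_+) \,/\, ((r_- + 1) / N_-)$ is at least 3 — the pseudocount of
   one read on the TAP(−) count avoids zero denominators and is conservative,
3. it lies within 300 nt 5′ of a same-strand gene start, or within the first
   three codons (annotation slack).

The two libraries are depth-normalized by their totals because they were
sequenced to different depths; the enrichment scale is therefore invariant to
per-library resequencing. Criterion 3 is skipped (`annotation = NULL`) when
calling TSSs for sRNA discovery, which by definition have no annotated
downstream gene.

Manual redundancy curation is replaced by two deterministic surrogates:
within any same-strand chain of calls spaced ≤ 5 nt, only the call with
maximal TAP(+) support survives (ties resolve to the most 5′ position in
transcript orientation), and the pipeline driver drops calls whose first
assigned gene is unexpressed in both phases.

Operon membership is the open design point of this stage: the source analysis
maps 140 promoters onto 232 genes without describing the joining procedure.
We extend each TSS gene-by-gene along the strand while the next gene is
co-oriented, lacks its own TSS call, and either the intergenic gap is ≤ 50 nt
or the gap's minimum coverage holds at least 25% of the upstream gene's mean
coverage; a zero-coverage upstream gene never licenses read-through. Both
parameters are exposed.

Promoters are the 50 bases immediately 5′ of each TSS, reverse-complemented
on the minus strand so all promoters read 5′→3′ relative to transcription.
Extraction is exact and round-trips: re-extracting at the same coordinates
reproduces the identical string.

## Two-box motif discovery

The AP promoter element is modeled as a pair of position-weight matrices — a
5-column −35 box and a 6-column −10 box — joined by a spacer of 14–18 nt with
its own weight distribution. The spacer window is centered on the consensus
spacer of 16 with ±2 flexibility; promoters are short (50 nt), so a
zero-or-one occurrence model is used.

*Seeding* is exhaustive over the data: every (5-mer, spacer, 6-mer) triple
occurring exactly in at least two promoters is scored for mismatch-tolerant
support (fraction of promoters containing the gapped word with at most one
total mismatch, counted with `Biostrings`), and triples reaching a 10%
support floor are ranked by enrichment over the expectation under the
promoter set's own base composition (Laplace-smoothed). The exact-support
prefilter only narrows the seed set; on random promoter sets it helps
guarantee the required explicit "no motif" outcome. If no triple reaches the
floor, discovery returns a `no_motif()` object rather than an error.

*Refinement* iterates best-placement realignment: each promoter contributes
its maximal-scoring placement (log-odds over both boxes plus the log spacer
weight) if that score is positive, PWMs are rebuilt with a pseudocount of 0.5
per base, and the spacer distribution is re-estimated, until assignments
stabilize (at most 20 iterations). Because a gapped word shifted by one
column has near-identical mismatch-tolerant support, the converged alignment
can sit one column out of phase; a deterministic polishing step evaluates ±1
column shifts of each box and keeps the alignment maximizing total
information content, followed by one final realignment. The reported score
threshold is the 5th percentile of retained promoter scores under the final
model — the absence of any published threshold makes this a package
definition, chosen to reproduce present/absent labels stably on synthetic
data.

Scanning maximizes the same score over all admissible placements, with ties
broken toward the smallest −35 offset, then the smallest spacer. Prevalence
is the fraction of promoters with a hit at or above the threshold, reported
also as a nearest-integer percent. Everything is deterministic: seeding is
exhaustive and tie-breaks are lexicographic.

## Intergenic sRNA discovery

Candidate territory is the complement of the gene union (intervals ≥ 50 nt).
Each region is counted in both conditions, normalized as region RPKM, tested
with the same chi-square/Bonferroni machinery (family = number of screened
regions), and retained when the AP/GP fold exceeds 4 and the adjusted p-value
is at most 0.05. When the GP RPKM is zero the fold denominator is floored at
the RPKM of a single read on that interval — folds stay finite and ranked
without inventing precision.

Long 5′UTRs masquerade as intergenic signal, so a candidate is discarded when
coverage from its own edge to the adjacent gene pointing away from it (right
neighbour on `+`, left neighbour on `-`) never falls below 25% of the
candidate's mean coverage *and* that gene is expressed in AP. Including the
candidate's edge base in the scan means a candidate whose expression dies out
before the gene boundary is never mistaken for a UTR, even when region and
gene abut.

Boundaries are then fixed from the TSS data: calls inside the region or
within 50 nt upstream of it anchor a transcript, whose strand is the TSS
strand. The 3′ end is found by a two-pass coverage scan in transcript
direction, bounded to the region (refined sRNAs never cross into genes):
first the contiguous covered block (gaps of up to 20 consecutive uncovered
bases are bridged), then a floor at 10% of the block's own peak, then an
extension of at most one read length through the trailing covered taper.
Fixed-length reads whose 5′ ends lie within the transcript produce a
read-length coverage ramp at the 3′ end; the bounded extension recovers the
true end, while an abrupt coverage cliff maps to the cliff exactly. Using the
block-local peak (not the region-wide one) matters when two sRNAs of very
different abundance share one intergenic region — a configuration that
actually occurs in the published sRNA table. Each qualifying TSS is refined
independently, and overlapping same-strand refinements keep the
better-supported TSS.

RPKM, fold and the chi-square are recomputed on the refined interval with
the screening family size; the fold/p filters are re-applied, making the
pipeline idempotent on its own output. Homology-based filtering (blastX,
RFAM) is replaced by a purely local rule with no network dependency: a
candidate is flagged when its sense-strand sequence contains a closed ORF
(ATG through an in-frame stop) of ≥ 50 codons. A start codon without an
in-frame stop does not flag. Finally, each sRNA's 50-base promoter is scanned
with the discovered two-box motif.

All serialized coordinates are 1-based inclusive, so `size = end − start + 1`
(the convention under which the published sRNA coordinates reproduce their
printed sizes); BED and bedGraph outputs use their native 0-based convention.
Reported folds are rounded to the nearest integer, consistent with most of
the published table's rows.

## What the generator emulates — and what it does not

`simulation_spec()` fixes the study conditions once:

* 36 bp reads; a 100 kb genome with 80 genes of mean length 800 bp
  (≈ 1/38 of the real genome, keeping per-gene coverage realistic);
* program fractions 10% AP-only, 43% GP-only, 3% AP-dominant, 2% GP-dominant,
  7% shared, 35% silent — scaled from the published category counts with 65%
  of genes expressed;
* genes laid out in program-homogeneous clusters of 3–10 (the published
  mosaic of phase-specific islands), grouped into operons of 1–3 genes;
* every expressed operon gets a TSS 20–150 nt upstream of its first codon;
  66% of AP-program promoters carry TTAAG-N16-CCGATA with the −10 box ending
  7 nt before the TSS (the published logo shows the boxes but not the offset;
  7 nt is the canonical sigma-factor discriminator length);
* AP genes drawn at GC 0.52, GP genes at 0.47 — a small but, at these gene
  counts, highly significant difference in the published direction;
* 8 intergenic sRNAs with the published size spectrum (98–655 nt), their own
  TSSs, transcript-level AP/GP folds log-uniform on [16, 5300], and 3 of 8
  carrying the promoter motif;
* 5 × 10⁵ whole-transcriptome reads per condition and 5′-end tracks of
  68,000/75,000 reads, scaled ≈ 1:100 from the published 6.8 M/7.5 M;
* a processed-site density of 10 per kb. This value comes from the
  normalization algebra, fixed before any caller was run: with per-library
  depth normalization, the enrichment observed at a planted TSS is
  $E\,(n_\mathrm{tss}+n_\mathrm{proc})/(E\,n_\mathrm{tss}+n_\mathrm{proc})$
  rather than the raw factor $E$, because TSS signal inflates the TAP(+)
  total itself. Processed ends must dominate the site census (biologically
  they do) for TAP enrichment to survive normalization; at the default
  enrichment factor 10 this yields ≈ 6–8 observed enrichment at true TSSs and
  ≈ 0.6 at processed sites, leaving the 3-fold rule a wide margin in both
  directions.

Read 5′ ends are uniform within each transcript — the real within-transcript
coverage shape is unknown, and uniformity is the simplest model that
exercises the counting and boundary logic. Reads are multinomial over
transcripts with weight = level × length; phase-exclusive programs have level
zero in the other condition, dominant programs a 20-fold transcript-level
bias (well beyond the 5-fold rule after library-composition effects), and
sRNAs an AP level that gives them roughly the read mass of the entire coding
complement — mirroring the extreme abundance of the published riboswitch
sRNA. Note that a planted sRNA "fold" is a transcript-level ratio; the
measured RPKM fold also carries the AP/GP library-composition factor (≈ 1.5
under defaults), which only increases AP folds.

The generator does **not** emulate sequencing error, quality scores, mapping
ambiguity, 5′-biased coverage, antisense transcription, or rRNA carry-over.
Passing tests on synthetic data therefore demonstrate the correctness of the
counting, calling, discovery and boundary logic under the stated statistical
model — not robustness to artefacts of real libraries.

## Numerical and degenerate-input choices

* Chi-square p-values come from `pchisq` upper tails; an independent
  quadrature of the χ²(1) density agrees to < 10⁻¹⁰ over the tested range.
* Bonferroni is exact: `p_adj = min(1, n·p_raw)`.
* `percent_of()` rounds half away from nothing special — plain `round()`;
  all printed percentages in the package are nearest-integer.
* Empty inputs: empty alignment sets give zero counts; an annotation without
  genes aborts the pipeline before later stages; a 5′-end track with zero
  total is an error for the TSS caller (the enrichment is undefined).
* Gene placement failure (genes do not fit the genome) raises an explicit
  error naming required versus available bases.
* Determinism: the generator consumes `set.seed(seed + k)` per stage, so the
  same spec yields byte-identical serialized bundles; the analysis itself
  contains no randomness.

## Problem sizes

The test suite exercises a 60 kb/50-gene bundle with 1.5 × 10⁵ reads per
condition for the module tests and the full default conditions (100 kb,
80 genes, 10⁶ whole-transcriptome read records) for the end-to-end property
suite; motif discovery properties use 100 synthetic promoters with 66 planted
elements, matching the published prevalence. These sizes keep per-gene
coverage far above the 20× the recovery properties assume.

## Known limitations

* Single-replicate statistics throughout: the chi-square on RPKM values has
  no dispersion model, and significance should be read as a screening
  heuristic, exactly as in the source analysis.
* GP-phase TSS calling is out of scope (prey RNA fragmentation degrades GP
  5′-end libraries in the real experiment), so GP sRNAs and GP promoters are
  invisible to this pipeline.
* The ORF filter is a local surrogate for homology screening; a conserved
  non-ATG ORF or a short conserved peptide would not be flagged.
* Operon joining is a surrogate for an undescribed manual procedure; its
  parameters (gap 50 nt, 25% coverage continuity) are exposed rather than
  claimed.
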