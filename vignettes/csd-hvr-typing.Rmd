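---
title: "Typing csd HVR alleles from short reads: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing csd HVR alleles from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdTyper)
```

## The biological setting

The honeybee *complementary sex-determiner* (*csd*) locus controls sex:
heterozygotes develop as females, hemizygous haploids as drones, and
homozygous diploids are non-viable in practice. The alleles differ mainly
in the hypervariable region (HVR) of exon 7, a short asparagine/tyrosine
repeat-rich peptide bracketed by the conserved motifs `SSLS` (N-terminal)
and `IEQI` (C-terminal). Pairs of alleles differing by at least five amino
acids reliably trigger female development, which is why allele inventories
matter for breeding programmes. `csdTyper` reconstructs the two HVR
alleles of a diploid worker from whole-genome short reads and aggregates
them into a population catalogue.

## The assembly model

Reads overlapping the HVR interval (`NC_037640.1:11771976-11772119`,
1-based inclusive, 144 bp, the samtools region convention) are clustered
by a greedy overlap-layout-consensus procedure that reproduces the
user-visible contract of a classic clustering assembler run with a
minimum overlap of 40 bases and minimum overlap identity of 90 %:

* Overlaps are gap-free dovetail or containment alignments, scored
  `matches − 2 × mismatches` by default. Both orientations of the second
  sequence are always evaluated. `N` never counts as a match.
* The highest-scoring qualifying pair of units (reads or partial contigs)
  is merged; the layout is re-consensused column-by-column by majority
  vote, ties resolved by higher summed base quality, then alphabetically;
  `N` never wins a tie against a concrete base.
* Iteration stops when no qualifying overlap remains. Units with at least
  two reads are contigs; the rest are singletons. All tie-breaks (score,
  then overlap length, then forward orientation, then unit id) are
  deterministic, so identical inputs give identical assemblies.

The gap-free default reflects the variation actually seen at this locus at
read scale — substitutions and large length differences between alleles,
not small indels within a read — and keeps the overlap semantics exactly
auditable against an exhaustive enumeration oracle (which the test suite
does on small instances). The full sophistication of quality-weighted
assemblers (repeat masking, quality-weighted alignment) is intentionally
not replicated: the contract being relied on is only
"contigs + singletons under (40, 90 %)".

No depth cut-off is applied before assembly. As an automatable stand-in
for manual inspection of poorly supported assemblies, `assemble()` offers
an optional post-hoc median-depth filter (`minContigDepth`), off by
default.

A sample is accepted only when it assembles into **exactly two contigs
with at most one singleton** — the diploid expectation — and a genotype is
called only when **both** contigs translate into valid HVR peptides.

## Peptide validation

Each contig consensus is translated in all six frames (standard code,
stops as `*`, `N`-containing codons as `X`, trailing bases ignored). The
HVR peptide is the span from the first `SSLS` to the end of the last
`IEQI` within one frame. The span is rejected when it contains `*`
(truncation) or `X` (consensus ambiguity must not fabricate alleles), or
when its length falls outside 20–80 aa (published alleles run 27–50 aa;
the bounds leave margin without admitting junk). The anchor pair is the
operational reading of "translations matching the csd amino-acid
sequence": it is exactly the shared termini of all 88 packaged reference
alleles, and both anchors are configurable.

If two frames yield valid spans with *different* peptides the call is
rejected as ambiguous rather than guessed. Identical peptides from
several frames are accepted — required for strand invariance, since a
reverse-complemented contig must give the same answer through frames 4–6.

## Catalogue statistics

An allele is a distinct HVR peptide (exact amino-acid identity, the
convention used when comparing against database entries at "100 %
coverage and 100 % identity" — here implemented as strict full-length
string equality against the packaged GenBank-accession table). Copies are
counted two per genotype. Allele ids rank by descending copy count, ties
by first occurrence; the stable key in all outputs is the peptide string
itself, because the published numbering is not fully reconstructible.

Percentages are rounded half-up to 2 decimals. The diversity ratio
(distinct alleles / sequences analysed) is reported truncated to 2
decimals by default — the packaged catalogue gives 88/138 = 0.6377,
reported 0.63, matching the published figure, which is consistent with
truncation rather than rounding — with half-up and raw values available.

The packaged reference (88 alleles, 138 sequences over seven subspecies)
reconstructs copy counts from the per-subspecies frequency columns and
the subspecies totals (68, 42, 8, 10, 4, 4, 2), because the published
per-population column is internally inconsistent for at least one allele
(its population frequency contradicts its own subspecies frequency and
the accompanying prose); the printed value is retained as
`pop_freq_printed_pct` for reference.

## The synthetic cohort generator

`generateCohort()` emulates the study's data regime so every stage can be
tested without restricted raw data:

* **150 bp reads**, the platform read length the pipeline targets.
* **Depth 20× per haplotype** by default — of the same order as the
  per-sample HVR coverage implied by the study scale (a few thousand
  region reads across ~125 samples), and high enough for majority
  consensus to cancel sequencing errors.
* **Substitution-only errors at 0.1 %**, an Illumina-like figure; no
  indel model, matching the gap-free assembler default.
* **Allele pairs at least 5 aa apart** (alignment difference), the
  heterozygosity margin known to secure female development; pairs are
  drawn without replacement from the 88 packaged alleles.
* **Flanks**: each haplotype embeds its back-translated allele in 200 nt
  of random DNA, drawn independently per haplotype. Independent flanks
  emulate the sequence divergence that accompanies distinct alleles
  around the HVR; sharing identical flanks between the two haplotypes
  would make two-contig assembly ill-posed at any depth, which the real
  locus does not exhibit at typing-relevant scale. Back-translations use
  independently drawn synonymous codons per haplotype for the same
  reason.
* **Subspecies weights** default to the sampled cohort's proportions
  (61/43/8/6/4/2/1 over ligustica, Buckfast, carnica, sicula, mellifera,
  hybrid carnica, cecropia, normalised).

What the simulator does *not* model: base-quality profiles, PCR
duplicates, mapping artefacts, indels, contamination, or more than two
alleles per sample. Passing the synthetic recovery tests therefore shows
the pipeline's logic and numerics are sound under the stated read model;
it does not certify performance on degraded real libraries.

The published sample funnel (125 samples in, 87 passing assembly, 174
translated sequences, 154 after truncation filtering, 69 fully resolved
samples, 138 final sequences) depends on restricted raw data and is not
reproducible here; the funnel is instead validated structurally (monotone
counts, final sequences = 2 × resolved samples) and by a 50-sample
synthetic recovery experiment (depth 20×, error 0.1 %, fixed seed)
requiring at least 95 % exact genotype recovery.

## The tree

The allele tree is a deliberate simplification: pairwise global-alignment
distances (match 0, mismatch 1, gap 1, normalised by alignment length —
among minimum-cost alignments the longest is used as normaliser, making
the value deterministic), canonical Saitou–Nei neighbor joining, negative
branch lengths clamped to zero and flagged, and rooting at the midpoint
of the outgroup's pendant edge. Maximum-likelihood inference under an
amino-acid substitution model is out of scope. Because the published
outgroup sequence is not redistributable, the package ships a clearly
labelled *synthetic* divergent outgroup peptide used only to exercise
rooting.

## Numerical and design choices at a glance

| Parameter | Default | Why |
|---|---|---|
| `minOverlap` | 40 bp | clustering contract of the original pipeline |
| `minIdentity` | 0.90 | idem |
| `mismatchPenalty` | 2 | favours clean junctions; any positive value preserves the acceptance thresholds |
| contigs / singletons | 2 / ≤1 | diploid expectation; "less than two singletons" read as ≤1 |
| anchors | `SSLS`, `IEQI` | shared termini of all 88 reference alleles |
| peptide length | 20–80 aa | published range 27–50 with margin |
| rounding | half-up 2 dp (frequencies), truncation 2 dp (diversity ratio) | reproduces the published figures |
| homozygous calls | retained, flagged | the published pipeline never states this case; flagging preserves information |

Problem sizes used by the test suite (oracle instances of ≤8 reads,
cohorts of 5–50 samples at depth 15–20×) were chosen so each property is
exercised at the smallest scale at which it is meaningful.

## Known limitations

* Amino-acid identity defines an allele; synonymous nucleotide variation
  is invisible by design.
* More than two true alleles (contamination) is not detected — the sample
  simply fails the two-contig filter.
* The greedy assembler is not guaranteed optimal for pathological overlap
  graphs; its guarantees are the tested invariants (read conservation,
  determinism, junction validity, separation of alleles ≥5 aa apart).
* The NJ tree is a visual aid; no support values are computed.
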