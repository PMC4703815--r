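---
title: "Mining candidate polymorphic microsatellites from multiple assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining candidate polymorphic microsatellites from multiple assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyssr)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem duplications of
short DNA motifs whose copy number mutates fast enough to make them prime
molecular markers for genotyping, linkage mapping and breeding. The expensive
part of SSR marker development has never been finding repeats — it is finding
repeats that are actually *polymorphic* in the material at hand, which
traditionally requires amplifying every locus in a panel of individuals and
sizing the products on gels.

When several assembled genomes or transcriptomes of a species or genus are
available, that screen can be done in silico: detect SSRs on one assembly,
locate the homologous locus in every other assembly, and keep the loci whose
repeat counts differ. `polyssr` implements that screen end to end, together
with the two confidence metrics that make the candidate list usable — the
spread of repeat counts across assemblies and the fraction of assemblies in
which the locus could not be found at all — plus deterministic PCR primer
design and a transferability score for each primer pair.

## The procedure

For a reference assembly $R$ and non-reference assemblies $S_1 \dots S_m$:

1. **Header sanitation.** Every sequence id is rewritten `<sample>|<id>` so
   identically named contigs from different assemblies cannot collide.
2. **SSR detection** on $R$: all maximal perfect tandem arrays with primitive
   motif length 2–6 whose full-copy count meets the per-length thresholds
   (defaults 6/5/5/5/5 for di- through hexanucleotides). Mononucleotide runs
   are excluded; partial trailing copies are not counted and not part of the
   locus interval. Loci are serialised `CPSSR_<n>` in reference coordinate
   order.
3. **Flank extraction**: $l$ bases (default 100) on each side of the tract;
   `upstream + tract + downstream` becomes the homology query.
4. **Homology search** of every query in every $S_j$ with a self-contained
   k-mer seed-and-extend aligner (below), keeping hits with flank identity
   $\ge$ MI and flank coverage $\ge$ MC (defaults 0.95/0.95).
5. **Best-hit selection** per (locus, sample) by alignment score; if the
   runner-up scores $\ge$ 0.9 times the best, the sample is called
   `AMBIGUOUS` — two near-equal placements are the signature of a paralogous
   duplication whose repeat count should not be trusted.
6. **Genotyping**: the hit region is elongated by $e$ bases (default 50) on
   both sides, oriented, and scanned for the longest run of full copies of
   any rotation of the reference motif. One full copy suffices for `FOUND`:
   a genuinely polymorphic array can have decayed to a single copy in one
   assembly, and such alleles must be reported, not discarded. Zero copies
   gives `MISSING`.
7. **Scoring**: per locus, the *dispersion degree*
   $\mathrm{SD} = \sqrt{\tfrac1n \sum_i (x_i - \bar x)^2}$ over the reference
   count plus all `FOUND` counts, and the *missing rate*
   $\mathrm{MR} = (\#\mathrm{MISSING} + \#\mathrm{AMBIGUOUS}) / m$. A locus
   passes iff $\mathrm{SD} > 0$ and $\mathrm{MR} \le 0.5$.
8. **Transferability**: each `FOUND` sample's flanks (its hit region minus
   the genotyped run) are globally aligned to the reference flanks; the
   per-locus mean identity is reported, and each primer pair's binding
   intervals are projected through the alignment column map into every
   sample and re-scored — 100 means the binding sites are completely
   conserved, the condition favouring cross-assembly amplification.
9. **Primer design** (below) and optional **genomic-region classification**
   against a GFF3 annotation.

## The aligner and the MI/MC semantics

The search is deliberately self-contained (no external aligner binary):
exact k-mer seeds (default $k = 12$, found with `Biostrings::matchPDict`) on
both strands are clustered by diagonal, and each cluster is extended with a
banded global (fitting) alignment of the whole query over the chained span
(match +1, mismatch −1, gap open −2 charged on the first gap base, −1 per
additional base; band of twice the expected indel slack, at least 16). `N`
mismatches everything, including `N`, and no low-complexity masking of any
kind is applied. Because SSR-tract k-mers match every same-motif run in a
genome, extension is only triggered for clusters containing at least one
seed with at most 32 occurrences in the target; this is an
occurrence-triggering rule, not masking — any hit that could reach the
coverage threshold necessarily has unique flank seeds.

Identity is matches over alignment columns and coverage is the fraction of
query bases aligned to target bases, both computed **excluding the columns
of the query's SSR tract**. This is a deliberate definition, not an
approximation: the tract's length is exactly the quantity that varies
between samples, and with $l = 100$ a two-copy difference in a
hexanucleotide array (12 bases of a ~230-base query) would otherwise push a
perfect homolog below MI = 0.95 on its own. Whether the tract is actually
present in the hit is decided by the genotyping step, mirroring the
screen-then-re-detect order of the procedure. The alignment *score* still
covers the whole query, so best-hit selection sees the tract.

Tie-breaks everywhere are total and documented: best hits by (score,
identity, leftmost target interval, + strand); tandem-run location by (run
length, leftmost start, earlier rotation phase); primer pairs by (penalty,
smaller product, leftmost forward start). This, plus the absence of any
random draw in the pipeline proper, makes outputs byte-identical across
repeated runs and across worker counts.

## Primer design

A deterministic constraint-based designer replaces an external primer
program: every substring of the upstream flank (and reverse complement of
the downstream flank) with length 18–24, melting temperature 57–63 °C,
GC 40–60 % and no mononucleotide run over 4 is a candidate; pairs must
bracket the whole tract, give a product of 100–300 bases, and differ by at
most 3 °C. Pairs are ranked by
`|Tm_f − 60| + |Tm_r − 60| + 0.5(|len_f − 20| + |len_r − 20|) + |ΔTm|`, and
up to three are reported per locus. Melting temperatures use the
deterministic GC-count formulas (Wallace rule below 14 bases,
`64.9 + 41 (GC − 16.4)/len` from 14 on) rather than nearest-neighbour
thermodynamics: they are trivially recomputable in tests and monotone in GC
content; a nearest-neighbour model is a documented extension point, not a
default. An adapter for externally produced 12-column tabular alignment
hits exists (`read_tabular_hits()`) for users who prefer their own search,
and is off by default.

## What the simulator emulates — and what it does not

`simulate_assemblies()` generates the study the tests and the acceptance
script run on: one shared i.i.d.-uniform background chromosome per sample
(default 6 samples × 1 Mb, matching a six-assembly screen at desk scale),
with 100 planted SSR loci (random primitive motifs of length 2–6, reference
counts 1–5 copies above threshold), half of them polymorphic with
per-sample copy-number offsets drawn from −2..+2. Non-reference flanks
(100 bases per side) receive substitutions at 0.005/base and 1–3-base
indels at 0.001/base; each (locus, sample) drops out (tract and flanks
deleted) with probability 0.05. Paralogous duplication — an identical-flank
copy inserted elsewhere, which must drive the `AMBIGUOUS` path — is off by
default and exercised by dedicated scenarios. Two bookkeeping choices keep
the ground truth exact: the two background bases adjacent to each tract are
pinned (identically in all samples) so the background can never extend a
planted array by even one base, and the truth table records the tandem run
*realized* in the emitted sequence, because a flanking substitution can
legitimately lengthen an array — the data, not the sampling intention, is
the truth.

A fixed companion scenario, `scenario_cpssr4933()`, reproduces a
qualitatively harder allele series observed in real screens of rice
genomes: a hexanucleotide (CCACGG) locus with five reference copies, three
samples at four copies, one at three, and one whose array carries two
internal substitutions that leave a single intact copy. A correct pipeline
reports it as one passing candidate with counts {5, 4, 4, 4, 3, 1},
positive dispersion and zero missing rate.

What the simulator does **not** emulate: realistic base composition and
repeat landscapes (GC skew, transposons, compound and interrupted SSRs),
coalescent structure among samples, assembly errors other than locus
dropout, and transcriptome-vs-genome comparisons (out of scope throughout).
Passing tests therefore demonstrate algorithmic correctness under
controlled variation, not performance on any particular real genome.

## Numerical and degenerate-input choices

* Population SD (divisor $n$, reference included) is used for the
  dispersion degree; with samples in the single digits the $n$ vs $n-1$
  choice materially changes the number, so it is fixed, documented, and the
  reference-inclusion choice lives in one function (`score_locus()`).
* MR's denominator is the number of non-reference samples only.
* Flank and binding-region similarity use pairwise reference-vs-sample
  global alignment (gap −2 per column, gaps count in the denominator)
  rather than a multiple alignment: pairwise identity against a fixed
  reference needs no external program, and is deterministic and
  independently checkable. The per-locus value is the mean over `FOUND`
  samples; a binding site whose projection retains fewer than half its
  bases in a sample is treated as deleted (contributes 0, flagged).
* Empty results are legal everywhere: header-only tables are written, a
  locus with no admissible primer pair is reported with zero pairs, and a
  reference without SSRs yields a warning plus empty outputs.
* Flanks shorter than $l$ (locus at a contig end) are clipped and flagged;
  queries shorter than $k$ are skipped with a warning.

## Validation scale

The shipped suite validates the detector against a brute-force enumerator
on 1,000 random kilobases (half with planted arrays), the aligner against
`Biostrings::pairwiseAlignment` on 200 pairs up to 2 kb, motif-class
canonicalisation exhaustively over all 5,456 motifs, and the full pipeline
on the default 6 × 1 Mb study (recovery of planted polymorphic loci with
exact counts ≥ 95 % and zero monomorphic leakage) plus the fixed scenario
above. `scripts/acceptance.R` re-runs the full study and the scenario from
scratch for any seed and writes the headline numbers as JSON.

## Known limitations

* Only perfect, single-motif SSRs are modelled; compound or interrupted
  repeats appear, if at all, as separate loci.
* The ambiguity rule flags paralogs only when both copies align well over
  their flanks; a paralog that has diverged in its flanks but not its tract
  is indistinguishable from the true locus by construction.
* Banded extension assumes the homolog's indel budget fits the band
  (twice the expected slack, minimum 16 bases); structural rearrangements
  inside a flank defeat it and the sample is reported `MISSING` rather
  than wrong.
* The Tm formulas ignore salt and oligo concentration; reported
  temperatures are comparable between primers of this package, not
  calibrated predictions.
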