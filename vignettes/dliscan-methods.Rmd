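---
title: "Detecting differentially located insertion sequences with dliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially located insertion sequences with dliscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dliscan)
```

## The problem

Insertion sequences (ISs) are the smallest bacterial transposable
elements: a transposase gene bounded by short terminal inverted repeats.
Because ISs move, two closely related strains usually share most IS
copies at homologous loci but differ at a handful of sites — the
*differentially located ISs* (DLISs) that drive gene knock-outs,
promoter capture and other phenotypic changes.  `dliscan` finds DLISs by
comparing two assembled genomes (complete or draft) against a library of
IS nucleotide sequences.  It needs no sequencing reads and no knowledge
of transposition mechanism, inverted repeats or direct repeats: the
decision is made entirely from the *genomic context* of each IS copy.

## The method

For a query/reference genome pair the pipeline is:

1. **Identical-scaffold removal.**  Every query scaffold is searched
   against the reference.  A scaffold is dropped as identical when some
   HSP covers more than 99 % of it (`identical_qcov`) *and* fewer than
   20 nucleotides (`identical_max_unaligned`) lie outside the union of
   all HSPs against one reference scaffold.  The per-HSP reading of the
   coverage clause is deliberate: a large replicon carrying many
   insertions is covered almost completely by the *union* of its HSPs,
   but no single HSP passes 99 %, so it is retained for analysis while a
   scaffold differing only by scattered SNPs is removed.
2. **IS scanning.**  Scaffolds are searched against the IS library
   (E-value cutoff 1e-10; one retained hit per genomic region, best
   bitscore wins).  Hits shorter than one third of the library IS are
   discarded unless they touch a scaffold end (within `scaffoldDiff` =
   20 nt), where draft assemblies legitimately carry partial ISs.
   Scaffolds with fewer than `ISdiff` = 50 non-IS nucleotides are
   dropped entirely.  Occurrences closer than `consecutive_gap`
   (2 × `surroundingLen` by default) are tagged as consecutive — their
   flanks overlap another IS, a known false-positive mode.
3. **Flank extraction (QIFs).**  The `surroundingLen` = 500 nt windows
   adjacent to each occurrence are extracted.  With shift `S`, the left
   flank is `[start - S - L, start - S)` and the right flank
   `[end + S, end + S + L)`; flanks truncate at record ends and flanks
   shorter than `minLength` = 50 nt are treated as absent.  Flanks are
   searched against the IS library: a hit from the same IS, group or
   family tags the occurrence for manual verification.
4. **Anchor mapping.**  The concatenated two-flank QIF is searched
   against the other genome: a single hit with query coverage above 90 %
   means the reference locus is contiguous — no IS there — and the
   occurrence is a direct DLIS candidate (a target-site duplication of up
   to 14 nt cannot defeat this coverage test).  Otherwise each flank is
   mapped independently (coverage > 90 %, alignment ≥ `minAlnLength`,
   E ≤ 1e-10) and a unique consistent anchor pair is sought on one
   reference record.
5. **RAF interrogation.**  The reference region between paired anchors
   (or, for single-flank contig-end QIFs, a window of
   `shift + longest IS + surroundingLen` on the side where the IS would
   sit) is searched against the IS library.  A related IS at the
   anchored position means the insertion exists in both genomes
   (**SLIS**); no IS, or an unrelated one, means a **DLIS**.
6. **Both directions, consolidation, outputs.**  The whole procedure is
   repeated with the genomes exchanged, so ISs present only in the
   reference are reported with `found_in = reference`.  Rows pointing at
   the same reference-side locus (same classification, family and
   record, loci within 50 nt) are merged: this removes same-location
   calls discovered twice and joins the two halves of an IS split across
   draft contig ends.  Tables (`FinalResults.csv`, `QueryISs.csv`,
   `RefISs.csv`, `ConsecutiveIS.csv`, `stats.txt`/`stats.json`) and an
   optional PDF context report are written.

### Classification vocabulary

Every occurrence that survives scanning receives exactly one of eight
labels: `DLIS`, `SLIS`, `VERIFY_RELATED_IS_IN_FLANK`,
`VERIFY_CONSECUTIVE_IS`, `VERIFY_UNSPECIFIC_MULTIHIT`,
`DISCARD_NO_ANCHOR`, `DISCARD_LOW_COVERAGE`,
`DISCARD_CONTEXT_MISMATCH`.  The three `VERIFY` classes form, together
with `DLIS`, the high-sensitivity call set (`DLIS+VERIFY` in
`score_against_truth()`); the precedence when several verify conditions
hold is related-IS > consecutive > unspecific, reporting the most
actionable cause once.  `SLIS` versus `DLIS` is decided by RAF content,
not by the anchor-gap length; the gap is used only to choose the correct
anchor pair among multiple hits (scored by closeness to either
`2·shift` or `2·shift + IS length`, unique minimum wins, ties are
unspecific).

### Shift mode

Some elements sit inside nested repeat structures (e.g. group II introns
whose target sites lie within ISs); their immediate flanks are then
repetitive or absent from the other genome and the occurrence cannot be
anchored.  Shift mode enlarges the masked region by `S` nucleotides on
each side so flanks are sampled farther away.  Internally every
gap/offset expectation moves with the shift: a DLIS locus may present
any anchor gap from ~0 (extra novel sequence in the query shrinks the
reference gap) up to `2S`, an SLIS locus `2S + IS length`, and the
single-flank RAF offset becomes `S`.  This is what makes results
invariant over `S` in the 0–2000 nt range for isolated insertions while
letting a shift larger than the decoy rescue repeat-flanked elements.

## The search engine

Homology search is a contract (`search_sequences()`): hits with
normalized 0-based half-open intervals, subject strand, identity,
E-value, bitscore and a recomputed per-HSP query coverage.  The default
backend shells out to NCBI BLAST+ `blastn`; culling is re-applied
engine-agnostically on the parsed hits (per query, a hit is dropped when
a better hit overlaps it by more than half of the shorter span; ties
prefer the smaller query start) so both backends obey one rule.  The
built-in backend — used where BLAST+ is not installed — seeds with
stride-sampled 16-mers, groups seeds by alignment diagonal, chains
nearby seeds and extends ungapped with a vectorised X-drop, mapping
scores to E-values through a monotone Karlin–Altschul-style formula.  It
reproduces BLAST hit presence and endpoints (±2 nt) for exact and
near-exact matches of ≥ 100 nt, which is all the pipeline asks of it;
it does not attempt gapped alignment, so concatenated-QIF hits across an
indel fall back to the per-side anchor path (which is insensitive to the
difference).  Strand is never used as a filter: insertions occur in both
orientations.

## The simulator and what the synthetic tests show

`simulate_insertions()` plants a chosen number of copies of one IS at
random positions, optionally with a target-site duplication: at point
`p` the genome receives `IS + duplicate of the tsd nucleotides left of
p`, producing the biological TSD–IS–TSD pattern.  Feature coordinates
are shifted; truth tables carry both original and modified coordinates.
`make_synthetic_genome()` supplies an i.i.d. background at a chosen GC
with dummy CDS features and optional pre-existing IS copies, and
`fragment_assembly()` cuts a genome into draft-like contigs —
`is_midpoint_breakpoints()` reproduces the classic draft structure with
half an IS on each contig end.

The packaged validation conditions are a 500 kb synthetic chromosome
with 50 insertions of a 1200 nt IS, 4 nt TSD and 5 kb minimum spacing,
plus a replicated protocol of 3 × 100 insertions of a 1221 nt element at
2 kb spacing.  Under these conditions detection is complete
(sensitivity and precision 1.0 in the strict DLIS mode, in both complete
and draft form).  An i.i.d. background is deliberately easy: it has no
segmental duplications, rRNA operons, prophages or diverged IS relics,
and identical genetic background means no SNP/indel noise in the
flanks.  Passing these tests therefore demonstrates the correctness of
the machinery — coordinates, strand handling, draft logic, consolidation
— not the precision to expect on real strains, where repeats and
rearrangements populate the verify/discard categories and precision
drops.  The relative ordering the suite *does* check (high-sensitivity
mode ≥ strict mode; shift neutrality; symmetry of the two directions)
transfers to real data.

## Numerical and design choices

* Coordinates are 0-based half-open internally; conversion to 1-based
  closed happens once, at the table/GenBank write boundary.
* "Unaligned nucleotides" in the identity filter uses the union of HSP
  query spans, so a single inversion does not hide identity.
* Occurrence intervals are the hit footprint on the genome, not the
  library IS extent — the only safe definition for partial draft copies.
* Pair selection among multiple anchor hits scores `|gap|` against the
  two expected values; a tie means the locus is genuinely ambiguous and
  is reported as unspecific rather than guessed.
* The RAF window uses the longest library IS plus one flank, so any
  same-site IS of any library family is detectable; an IS found in a RAF
  must start within `raf_edge_tol` = 50 nt of the anchored position
  (direct repeats ≤ 14 nt plus endpoint jitter) to call SLIS.
* Consolidation clusters reference-side loci with single-linkage at
  50 nt rather than rounding midpoints to a fixed grid, which would
  split twin partial calls straddling a bucket edge.
* Truth matching in `score_against_truth()` uses a 50 nt tolerance
  (endpoint jitter and TSDs) with greedy one-to-one nearest matching;
  for well-spaced truth this equals optimal matching.
* `filter_identical = FALSE` exposes the classification machinery on
  identical replicons (every occurrence then classifies as SLIS), which
  is how the self-comparison property is verified.
* Circular topology is read and written but flanks never wrap the
  origin; they truncate at record ends.
* Library headers default to the underscore convention
  (`name_family_group`); unknown labels never satisfy the relatedness
  test, so unannotated entries cannot inflate the verify classes.

## Known limitations

* IR/DR information is not used to refine IS ends; library quality
  bounds call quality.
* ISs carried on repeated cassettes (transposons with passenger genes,
  phage-borne copies) anchor ambiguously and surface as verify
  categories, by design.
* The built-in engine is a fallback for environments without BLAST+,
  not a general aligner; genomes with high SNP density between strains
  should be compared with the external backend.
* Origin-spanning insertions in circular replicons are reported as two
  contig-end cases rather than one joined call.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: 40–60 kb fixtures for unit tests and the 500 kb conditions above
for the end-to-end checks, a few seconds per comparison with BLAST+ on
one CPU.
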