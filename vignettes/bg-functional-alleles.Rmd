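---
title: "Annotating BG cDNA clone libraries: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating BG cDNA clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgalleles)
```

## The problem

Chicken BG genes (butyrophilin family, in and around the MHC) form a
rapidly evolving multigene family with extensive copy-number variation:
head-to-tail arrangement drives unequal crossing-over, so the gene content
differs between haplotypes and strict orthology cannot be established. A
pragmatic alternative is to compare, across haplotypes, the BG transcripts
expressed in one cell type — "functional alleles". This package implements
the sequence-analysis machinery for that comparison, starting from Sanger
cDNA clone libraries amplified with conserved primers.

Every BG gene shares one architecture, which the `GeneModel` class
encodes: exon 1 carries the 5'UTR and a 33-aa signal sequence; exon 2 the
114-aa extracellular Ig-V domain; exon 3 the transmembrane (TM) region;
then 20–40 repeat exons of canonically 21 nt (a few of 18 or 24 nt) that
encode the heptad repeats of a long cytoplasmic tail; and a final exon
holding the last coding nucleotides and the 3'UTR. The repeat exons are
all phase 1: the first codon of each repeat unit is split, one nucleotide
coming from the previous exon and two from the exon under consideration.
That split codon is the organising fact of most of the analysis below.

## Coordinates

Internally all coordinates are 1-based and closed, the IRanges convention,
which is what every function reports. The JSON gene-model dialect written
by `writeGeneModel()` uses 0-based half-open coordinates, and GFF3 input
uses 1-based inclusive coordinates; both are converted exactly once at the
I/O boundary. This confines off-by-one risk at split codons to two small,
tested conversion sites.

## Clone annotation

`segmentClone()` locates each model exon in a clone in model order. Exact
substring search is tried first (Sanger-finished clones from a matching
haplotype are usually exact), then banded semi-global alignment
(match 1, mismatch −1, gap open −4, extend −1). A clone stretch between
two located exons that matches the model's intervening intron at the
identity threshold is labelled a retained intron; anything else is
unaligned. The default `minExonIdentity = 0.85` tolerates inter-haplotype
divergence (the alleles under study differ by well under 7% in any
region) while rejecting random sequence. Exon order is enforced;
rearranged clones drop out as unassignable, consistent with treating them
as artefacts. Clones may carry *more* repeat exons than the model: after
each repeat exon the annotator greedily accepts extra tandem copies of
that exon (preferring the model's own next exon whenever it explains the
same stretch at least as well), which is how a four-exon tandem insertion
in one haplotype is recognised against a shorter reference.

`translateWithSplitCodons()` reads the located segments in the
signal-sequence frame, optionally including retained introns (the
"actual" transcript) or skipping them (the "conceptual" transcript, i.e.
exons without introns), and halts at the first in-frame stop (standard
vertebrate nuclear code, stops TAA/TAG/TGA). Each codon is attributed to
the segment contributing two of its three nucleotides. This rule decides
three things at once: the last signal-sequence codon (1 nt in exon 1, 2
nt in exon 2) is counted with the Ig-V domain; every repeat exon owns
exactly seven codons (its split codon plus six complete ones); and
retained-intron codons are recognisably intronic. Almost all retained
introns introduce an in-frame stop, producing the truncated cytoplasmic
tails the actual-transcript translation reports.

`countApparentHeptads()` counts one unit per fully translated repeat exon
(18- and 24-nt exons count one unit each — exons are counted, not
fractional heptads) plus one per complete heptad the final exon encodes
before its stop. The count therefore depends on where the stop falls: 28
repeat exons with one further complete repeat in the final exon give 29
apparent repeats, 37 + 1 give 38, and 27 with the stop at the start of
the final exon give 27.

## Grouping and artefact screening

Clones sharing an exon-2 sequence *exactly* are one putative gene; no
clustering threshold is used because genuinely distinct BG genes can
differ by a single exon-2 nucleotide. Within a line, groups are lettered
by descending clone count ("a" = most clones) and splice variants within
a group (distinct full clone sequences) are numbered by descending count,
giving names like `NTBGa-1`. Ties, which the naming convention itself
never had to face, are broken lexicographically by sequence so the output
is a total order, stable under permutation of the input.

Two artefact screens follow. `flagSingletons()` marks a group as possible
PCR mis-incorporation when it has exactly one clone, from one PCR batch,
with exon-2 one nucleotide away from a larger group in the same line;
flagged groups are kept, not deleted, since one-nucleotide sister genes
exist. `detectChimeras()` formalises a screen the original analysis
performed by inspection: a clone is chimeric when a prefix from one
group's representative and a suffix from another's, switching once,
explain it strictly better (by `margin = 3` mismatches) than any single
parent, with each side at least 150 nt and at most 2 mismatches. These
defaults are documented and configurable precisely because no published
criterion exists; the reported breakpoint window spans the informative
sites bracketing the switch, which is the best resolution the data can
give.

## Coiled-coil register

Because the repeat unit's first codon is split, the helical register is
assigned from codon position within the 21-nt repeat, not from absolute
residue index: positions 1–7 map to registers e, f, g, a, b, c, d. The
hydrophobic interface of the presumed two-chain coiled coil falls on
codons 4 and 7 (registers a and d); `interfaceHydrophobicity()` makes the
qualitative claim testable as fractions per register. Residue chemistry
follows the fixed partition acidic {D,E}, basic {K,R,H}, cysteine {C},
polar {S,T,N,Q,Y}, glycine/proline as a helix-breaking sub-class, and the
remainder hydrophobic. Treating histidine as basic and tyrosine as polar
are choices this package fixes explicitly; glycine and proline are kept
out of the hydrophobic fraction so the interface statistic is not
inflated by helix breakers.

`decorateVariation()` aligns tails at whole-heptad granularity (a small
Needleman–Wunsch over heptad blocks, gap = one unit), because the
insertions actually observed in BG tails are whole repeat exons; inserted
heptads are reported separately and excluded from shared-position counts.
`findPatches()` slides a window (default 4 heptads, threshold 0.6) over
the five non-interface registers only — a and d are excluded as the
hydrophobic stripe, e and g are retained because charge there is part of
the biology — and merges overlapping qualifying windows into maximal
patch calls. Both parameters are reported with every call since the
original patches were identified by eye.

## Silent and replacement variation

`compareRegions()` compares two conceptual transcripts region by region:
codon-wise in coding regions (whole-codon amino-acid comparison decides
silent vs replacement, even for multi-hit codons), nucleotide-wise in the
5'UTR and the untranslated remainder of the final exon. Repeat units in
the tail are aligned as whole units, so different repeat-exon counts
appear as excluded indel blocks. Two accounting conventions are
available: `per_position` (each changed nucleotide contributes one count
— the convention behind published per-position tallies) and `per_codon`
(one count per changed codon); both are emitted because published
difference counts are ambiguous between them. `selectionSummary()`
applies the stated neutral heuristic — random changes yield roughly two
replacements per silent change — and flags ratios above 2; no p-value is
computed because the heuristic is the whole published test.

## The synthetic generator

`simulateGeneFamily()` derives a gene family from one ancestor:
repeat-exon cassettes are deleted from the tail end, or tandemly
duplicated (emulating the observed exon insertions), the final exon is
rebuilt to encode the requested number of heptads before its stop, and
per-region substitutions are applied at transition:transversion odds 2:1
(a neutral default; no substitution model is published for these genes).
Every phase-1 junction in generated genes uses invariant nucleotides
(donor exon ends in G, acceptor begins AG, so the split codon is always
GAG), which guarantees that cassette insertion and deletion never create
frameshifts or junction stops. Substitutions avoid primer sites,
start/stop codons, splice dinucleotides and these junction bases, and are
re-drawn if they would create an in-frame stop, so simulated conceptual
transcripts always translate to their designed length and the heptad
ground truth is exact.

Default conditions mirror the study system: four genes with 33, 28, 31
and 27 repeat exons (the BG8-, BG9-, BG12- and BG13-like inventories),
one gene with a stop after one final-exon repeat, per-region substitution
rates of 1–2% per nucleotide, primer sites embedded exactly (conserved
primer design), intron retention at 0.2 per intron per transcript, and
introns of 80–300 nt. Retention frequency and intron lengths are not
published quantities; these values are fixed, documented placeholders,
and the retention probability applies uniformly to all introns.
`simulateCloneLibrary()` adds the two artefact classes with full ground
truth: single-crossover chimeras (breakpoint uniform within exon 2 or the
tail, the regions where a chimera would mislead grouping) and singleton
mis-incorporation errors (one extra Ig-V substitution, present once in
one PCR batch). What the generator does *not* emulate: sequencing-trace
noise, indel errors, coverage bias, template switching with multiple
crossovers, and gene conversion. Passing the recovery tests therefore
shows the pipeline's logic is correct on clean Sanger-like data, not that
it is robust to every real-data pathology.

## Numerical and degenerate-input choices

Translation ignores a trailing 1–2 nt remainder (with a warning) only
when no stop was reached; ties in model choice go to the first model in
input order after screening by exact exon-2 occurrence; register
positions beyond 7 (24-nt exons) wrap into the next heptad; a census over
aligned sequences excludes gap-containing columns from the total and
counts them separately; a selection ratio with zero silent changes is
reported as undefined rather than infinite. Problem sizes in the test
suite (families of 2–5 genes, 4–8 repeat exons, clone depths 1–10, 20
recovery seeds) were chosen as the smallest sizes at which every code
path — retention, duplication, chimerism, singleton error — is exercised.

## Known limitations

Real deposited sequences are fetched (and cached) from GenBank rather
than bundled; runs against them need either network access once or a
pre-populated cache. The annotator assumes the model's exon order and
does not discover novel non-repeat exons. Chimera detection tests single
crossovers only. The tail alignment anchors on whole heptads and will
misplace insertions that are not multiples of one repeat unit; the
conserved tail cysteine is reported but deliberately not used as an
alignment anchor, since its invariance is an observation, not a rule.
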