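---
title: "Guide design and off-target classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design and off-target classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protospacer)
```

## The problem

SpCas9 cuts double-stranded DNA wherever its guide RNA base-pairs with a
protospacer lying 5′ of an NGG PAM — but it tolerates mismatches, more so
away from the PAM, and it also cleaves at NAG PAMs at reduced efficiency.
Designing a guide therefore means two searches, not one: find candidate
sites in the gene of interest, and find everything else in the genome the
same guide might cut. This package implements both, plus the positional
classification of predicted off-target sites that makes the risk list
actionable, the filter cascade that turns it into a short list of
high-specificity guides, and the bench-facing outputs (cloning oligos,
validation amplicons).

## Target search

A candidate site is a window of L+3 nt whose last two bases read GG on the
searched strand; the PAM's first base is unconstrained. Three 5′ patterns
are supported — GGX₁₈, GX₁₉ and X₂₀ — because U6- and T7-driven transcripts
must start with G; if the vector supplies that G, the unconstrained X₂₀
pattern maximizes candidates. **X₂₀ is the default**: with a 20-nt spacer it
is the only pattern whose sole constraint is the spacer length itself, and
the G-start requirement is better handled as a logged warning than a hard
filter (the pipeline warns for every kept non-G-start guide). Spacer GC is
filtered to an inclusive 20–80% window over the spacer only (PAM excluded),
since very high or low GC spacers are poorly active; the bounds are
tunable. Truncated guides (L = 17–18) improve specificity and are supported
by setting `guide_len`; region III below shrinks accordingly, and L < 13 is
rejected so the region partition stays well-defined.

Antisense sites are found by scanning the reverse complement and mapping
coordinates back to the input record's sense strand, so all reports share
one 1-based, fully-closed coordinate convention; the conversion lives in
one place in the scanner. Guides containing N are dropped (they cannot be
synthesized); overlapping and duplicate-sequence sites are all kept at this
stage — duplicates are what the multi-locus filter downstream is for.

### Nickase pairs

For D10A double nicking the two guides must sit PAM-out with a bounded gap.
With both members projected onto sense coordinates, the offset is defined
as `(sense member's site start) − (antisense member's site end) − 1`: the
signed gap between the two PAM-distal guide ends, 0 when the guides abut,
negative when they overlap. The default window −2..32 bp covers the
offsets with demonstrated 5′-overhang nicking activity. One protospacer may
join several pairs; restricting members to a single pair would discard
valid designs and is left to the user.

## Off-target enumeration

For each guide the genome is scanned exhaustively on both strands for
windows whose spacer region is within k mismatches (default 5, the largest
separation at which bona fide off-target mutation has been observed) and
whose PAM is NGG or NAG. Three PAM rules are applied literally: the N
position is never compared; a GG→AG change is not counted as a mismatch;
any other PAM (NCG/NTG/NGA/NGT/NGC…) disqualifies the window. Genomic N
bases never match any guide base, soft-masked (lowercase) genome sequence
is uppercased on input so repeat regions are scanned like any other DNA,
and windows that would run past a chromosome end are skipped rather than
padded.

The scanning core is `Biostrings::matchPattern(max.mismatch = k)` — an
exact (lossless) C-level Hamming-neighborhood search — wrapped so that PAM
admissibility, coordinate/strand bookkeeping and mismatch-position
numbering are applied uniformly. Correctness is established by a dual
route: `brute_force_scan()` re-implements the identical contract as a pure
position-by-position comparison with no matching library, and the test
suite and acceptance script demand bit-identical hit sets between the two
on randomized genomes. Mismatch positions are numbered from the
PAM-proximal base (position 1 adjacent to the PAM) so that region
definitions are stable under guide truncation. A palindromic site can
legitimately appear once per strand.

## POT classification and risk

Counting from the PAM, region I is positions 1–7, region II 8–12 (I+II =
the seed, whose mismatches strongly reduce cleavage), region III 13–L.
Types: **I** — 1–5 mismatches all in region III; **II** — 1–5 mismatches in
II∪III with at least one in region II and none in region I; **III** — 1–3
mismatches with at least one in region I. Two boundary readings were
genuinely open:

* *Type II.* Read as "at least one mismatch in region II, none in I":
  the only reading under which the three types partition the mismatch
  patterns with no overlap (a permits-only reading would make every Type I
  pattern also Type II). The suite verifies the partition exhaustively over
  all `r format(sum(choose(20, 0:5)))` mismatch-position subsets of size
  0–5.
* *Region-I mismatches with 4–5 total.* No type admits them; they are
  excluded from POT but still counted as off-target hits. Biologically
  these are the least likely sites to cleave.

Zero-mismatch windows split by PAM: an NGG perfect match is the on-target
(or a multi-mapping locus) and is never a POT; an NAG perfect match is a
real cleavage risk with no mismatch class of its own, so it is reported as
Type I with n = 0, flagged `nag_perfect`, and given the top risk rank.
Risk ranking is ordinal only — Type I > II > III, then fewer mismatches
first, dense ranks, ties equal; no numeric cleavage probability is
assigned, because the classification is positional, not thermodynamic.

## Selection cascade

Discards apply in precedence order: no perfect genomic locus
(`not_on_genome` — typical for guides spanning exon junctions when the
input is mRNA/CDS); more than one perfect locus (`multi_locus`); any POT
with 1 or 2 mismatches (`has_1or2_mm_pot`). The NAG n = 0 POT deliberately
does not trigger the third rule — the rule is about 1–2 mismatch sites —
but it dominates the risk ranking, so such guides sort last among
survivors in practice. Survivors are ordered by total POT, then total
off-target count, both ascending. When the input is mRNA/CDS the single
perfect genomic hit is deemed the on-target; with genomic input the
perfect hit at the input's own locus is.

## Flank extraction and oligo QC

The predicted cut sits 3 nt upstream of the PAM (between spacer positions
3 and 4, PAM-proximal numbering). `extract_flank()` returns a window
(default 1000 bp) around that center for PCR/T7E1 validation. For even
window lengths the center sits just left of the window midpoint —
`floor((window − 1)/2)` bases to its left — chosen so extraction is
bit-reproducible; the window truncates at chromosome bounds rather than
sliding, so near an end fewer bases are returned (and the pipeline logs a
warning). Spacer QC reads the repeat rules literally: "more than 4
continuous T" means ≥5 T (a pol-III terminator), "more than 5 continuous
A/C/G" means ≥6, and "more than 6 di-/tri-nucleotide repeats" means >6
tandem copies of the unit — copies, not bases; at L = 20 the trinucleotide
rule cannot fire, but it is retained for amplicon-scale checks.

## Annotation

Off-target/POT loci are intersected with GTF features (default CDS, exon,
gene) by ≥1-bp overlap, strand-agnostically — a double-strand break
disrupts both strands regardless of the feature's orientation; feature
strand is reported, not filtered on. Ensembl/UCSC chromosome dialects are
harmonized by stripping a leading `chr` on both sides (switchable).
Parsing uses `rtracklayer`, overlap uses `GenomicRanges::findOverlaps`,
and the tests cross-check against a naive all-pairs scan.

## The synthetic genome generator

`make_toy_genome()` draws a uniform-random A/C/G/T background (GC fraction
settable, 0.5 by default) and overwrites it with planted sites: a guide,
chosen mismatch positions (mutated by a fixed cyclic base substitution so
a planted mismatch is always a real mismatch), a chosen PAM and strand.
The truth table it returns — coordinates, mismatch count and positions,
PAM class — is what the engine's output is compared against. It emulates
what matters to this method: exact and near-match windows, tolerated and
rejected PAMs, multi-copy guides, strand placement. It does not emulate
repeat families, segmental duplications, chromatin or base-composition
structure of real genomes, so passing tests demonstrate algorithmic
correctness of search/classification/selection, not off-target burdens of
real guides — on a real 3-GB genome a typical guide accrues thousands of
4–5-mismatch hits, which this generator's scale does not reproduce. The
generator seeds its own RNG stream and restores the caller's state, so
truth tables are reproducible and composable with other seeded code.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by choice:
toy genomes of 1–60 kb (oracle-equivalence checks on 100 randomized
instances up to ~20 kb), a three-exon CDS-like input of 898/185/1105 bp
for the search-mode counts, 50 random sequences for the strand-count
decomposition, and the complete enumeration of all 21,700
mismatch-position subsets of size ≤5 for the classification partition.
Everything is deterministic for a fixed seed; re-running a pipeline config
byte-reproduces every report (timestamps exist only outside the reports).
Coordinates are 1-based closed throughout; ambiguity codes other than N
are rejected rather than expanded, keeping the alphabet the method
actually models.

## Known limitations

* Hamming distance only: DNA/RNA-bulge (indel) off-targets are out of
  scope, as are non-SpCas9 PAMs.
* No on-target efficiency scoring and no probabilistic cleavage scores
  (CFD/MIT-style); the classification is positional.
* The whole genome is held in memory as character vectors; this is
  comfortable to ~100 Mb genomes but a 3-GB mammalian genome wants ~6 GB
  of RAM and patience — the engine is exact, not indexed across guides.
* GTF annotation reports overlap only; it does not reason about promoters
  or regulatory regions.
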