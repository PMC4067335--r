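# protospacer

CRISPR/Cas9 guide design with genome-wide off-target risk classification,
for anyone who needs to pick sgRNAs for a gene of interest in any organism
with a reference genome: find candidate target sites, enumerate every locus
the nuclease might also cut, rank those risks by where the mismatches fall,
and keep only the guides a careful experimentalist would clone.

## What it computes

**Target search.** A protospacer is an L-nt spacer (default L = 20)
immediately 5′ of an NGG PAM. Sites are searched on the sense strand, the
antisense strand, or both, under three 5′ patterns — 5′-GGX₁₈-NGG-3′,
5′-GX₁₉-NGG-3′ or 5′-X₂₀-NGG-3′ (the G/GG prefixes guarantee proper U6/T7
transcript initiation) — and filtered to a spacer GC window (default
20–80%). A paired mode enumerates PAM-out guide pairs for D10A-nickase
double nicking, keeping pairs whose *offset* — the signed gap between the
two PAM-distal (5′) guide ends — lies in a window (default −2 to 32 bp).

**Off-target enumeration.** Each guide is compared against every genomic
window on both strands. A window is a potential site when its spacer region
is within k mismatches of the guide (default k = 5) and its PAM reads NGG
or NAG; the PAM's N is never compared, the GG→AG change is not a mismatch,
and NCG/NTG/NGA/NGT/NGC windows are discarded.

**POT classification.** Counting positions from the PAM (position 1
adjacent to it), the spacer splits into region I (1–7), region II (8–12) —
together the seed — and region III (13–L). A potential off-target cleavage
site (POT) is:

| Type | mismatches | placement |
|------|-----------|-----------|
| I    | 1–5       | all in region III (seed intact — most dangerous) |
| II   | 1–5       | in II∪III, at least one in II, none in I |
| III  | 1–3       | at least one in region I |

Region-I mismatches with 4–5 total fit no type and are excluded from POT
(they still count as off-target hits). Risk rank orders Type I > II > III,
then fewer mismatches first.

**Selection.** Guides are discarded, in order, when they (1) have no
perfect genomic match (e.g. they span an exon junction), (2) match more
than one locus perfectly, or (3) carry any POT with only 1–2 mismatches.
Survivors are sorted by POT count, then total off-target count.

**Bench prep.** Kept guides get annealing oligos (default adapters
`accg`/`aaac` for BsaI cloning into a U6 sgRNA vector) after sequence QC
(no ≥5-T pol-III terminator, no ≥6-base homopolymer, no >6-copy di-/tri-
nucleotide tandem), plus an amplicon of genomic sequence (default 1000 bp)
centered on the predicted cut 3 nt upstream of the PAM, for T7E1/sequencing
validation. Off-target loci can be intersected with a GTF to flag hits in
CDS/exon/gene features.

## Worked example

Plant one guide at four engineered loci in a seeded toy genome, then scan
and classify:

```r
library(protospacer)
guide <- "GACGTTAAACCGGATTACCA"
tg <- make_toy_genome(42, c(chr1 = 5000, chr2 = 3000), list(
  plant_spec(guide, "chr1", 200, "+", integer(0), "AGG"),
  plant_spec(guide, "chr1", 1200, "-", c(15, 18), "TGG"),
  plant_spec(guide, "chr2", 700,  "+", c(3), "CGG"),
  plant_spec(guide, "chr2", 1500, "+", integer(0), "TAG")))
hits <- search_offtargets(c(my_guide = guide), tg$genome, k = 5)
pots <- rank_risk(classify_hits(hits))
pots[, c("chrom","start","strand","n_mismatch","pam_class","pot_type","risk_rank")]
#>   chrom start strand n_mismatch pam_class pot_type risk_rank
#> 1  chr1   200      +          0       NGG  perfect        NA
#> 2  chr1  1200      -          2       NGG        I         2
#> 3  chr2   700      +          1       NGG      III         3
#> 4  chr2  1500      +          0       NAG        I         1
```

Reading the table: the chr1:200 locus is the on-target (perfect NGG match,
not a POT). The minus-strand site with mismatches at PAM-proximal positions
15 and 18 is Type I — both mismatches sit in the non-seed region, so
cleavage there is likely; with only 2 mismatches this guide would be
discarded by the selection cascade. The single region-I mismatch at chr2:700
is Type III (seed disrupted, lower risk). The zero-mismatch NAG site is the
most dangerous POT of all (rank 1). Oligos for cloning:

```r
make_oligos(guide, "my_guide")
#>   guide_id              sense_oligo          antisense_oligo
#> 1 my_guide accgGACGTTAAACCGGATTACCA aaacTGGTAATCCGGTTTAACGTC
```

The full pipeline — `run_pipeline(run_config("targets.fa", "genome.fa"))`
or the CLI `Rscript inst/cli/protospacer-cli.R -i targets.fa -g genome.fa
-o b -t p -n 5 -s 5 -e 35 -d out/` — writes
`report_protospacer_single.txt`, `report_protospacer_pairs.txt`,
`search_OT.txt`, per-type folders `Type_I_POT`/`Type_II_POT`/`Type_III_POT`,
per-guide files under `Sort_POT_byID`, kept guides under `Final_report`,
oligos, flank amplicons and a `run.log` of stage counts.

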