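# Shared fixtures and independent oracles for the test suite.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# Independent sliding-window protospacer oracle: regex-free, position by
# position, one strand of one string, start positions of guide+PAM windows.
naive_site_starts <- function(seq, L = 20L, pattern = "X20",
                              gc_min = 20, gc_max = 80) {
  n <- nchar(seq)
  W <- L + 3L
  starts <- integer(0)
  if (n < W) return(starts)
  for (p in seq_len(n - W + 1L)) {
    win <- substr(seq, p, p + W - 1L)
    if (substr(win, L + 2L, L + 3L) != "GG") next
    if (pattern == "GX19" && substr(win, 1L, 1L) != "G") next
    if (pattern == "GGX18" && substr(win, 1L, 2L) != "GG") next
    guide <- substr(win, 1L, L)
    if (grepl("N", guide, fixed = TRUE)) next
    gc <- 100 * lengths(regmatches(guide, gregexpr("[GC]", guide))) / L
    if (gc < gc_min || gc > gc_max) next
    starts <- c(starts, p)
  }
  starts
}

# Literal POT type predicates, written directly from the three definitions,
# independent of the package's classifier.
pot_type_predicates <- function(pos, n) {
  c(I = n >= 1 && n <= 5 && length(pos) > 0 && all(pos >= 13),
    II = n >= 1 && n <= 5 && all(pos >= 8) && any(pos >= 8 & pos <= 12),
    III = n >= 1 && n <= 3 && any(pos <= 7))
}

# A guide with benign composition used across planted-genome tests.
fixture_guide <- function() "GACGTTAAACCGGATTACCA"

# Engineered end-to-end scenario shared by the pipeline and acceptance
# tests. The input record is built from four guides with no stray GG/CC
# dinucleotides, so the only protospacers the search can find are the four
# intended ones; the toy genome then plants the loci that drive each
# selection verdict.
guide_A <- "TAGTGCTTGAAATATGCGAC"   # on-target only           -> kept
guide_B <- "TAATCAACGAGCTTAATGAG"   # two perfect loci         -> multi_locus
guide_C <- "GCGTATCGATTACGAGCTTA"   # 1-mm POT planted         -> has_1or2_mm_pot
guide_D <- "CATGCTAGAAAGACTAGTTT"   # absent from the genome   -> not_on_genome

pipeline_record <- function() {
  filler <- strrep("ATTA", 6)
  paste0(filler, guide_A, "TGG", filler, guide_B, "TGG",
         filler, guide_C, "TGG", filler, guide_D, "TGG", filler)
}

pipeline_fixture <- function(seed = 501) {
  tg <- make_toy_genome(seed, c(chr1 = 5000, chr2 = 3000), list(
    plant_spec(guide_A, "chr1", 200, "+", integer(0), "AGG"),
    plant_spec(guide_A, "chr1", 1000, "+", integer(0), "TAG"),  # NAG perfect
    plant_spec(guide_A, "chr1", 1800, "+", integer(0), "TCG"),  # rejected PAM
    plant_spec(guide_B, "chr1", 2600, "+", integer(0), "TGG"),
    plant_spec(guide_B, "chr2", 500, "-", integer(0), "AGG"),
    plant_spec(guide_C, "chr2", 1200, "+", integer(0), "CGG"),
    plant_spec(guide_C, "chr2", 2000, "+", c(9), "AGG")))       # 1-mm POT
  input <- write_tmp_fasta(c(target_gene = pipeline_record()))
  genome <- write_tmp_fasta(tg$genome)
  list(input = input, genome = genome, truth = tg$truth)
}

# Sorts a hit table into a canonical row order for set comparison.
canonical_hits <- function(hits) {
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
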