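test_that("planted sites obey the PAM tolerance rules", {
  g <- fixture_guide()
  tg <- make_toy_genome(101, c(chr1 = 2000), list(
    plant_spec(g, "chr1", 200, "+", integer(0), "AGG"),
    plant_spec(g, "chr1", 600, "+", integer(0), "TAG"),
    plant_spec(g, "chr1", 1000, "+", integer(0), "TCG")))
  hits <- search_offtargets(c(g1 = g), tg$genome, k = 0)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(200, 600))
  expect_identical(hits$pam_class, c("NGG", "NAG"))
  expect_equal(hits$n_mismatch, c(0L, 0L))
})

test_that("mismatch positions are numbered from the PAM and lowercased", {
  g <- fixture_guide()
  tg <- make_toy_genome(102, c(chr1 = 1500), list(
    plant_spec(g, "chr1", 300, "-", c(15, 18), "TGG"),
    plant_spec(g, "chr1", 800, "+", c(1, 7), "CGG")))
  hits <- search_offtargets(c(g1 = g), tg$genome, k = 5)
  minus <- hits[hits$strand == "-", ]
  plus <- hits[hits$strand == "+" & hits$start == 800, ]
  expect_identical(minus$mismatch_positions, "15,18")
  expect_identical(plus$mismatch_positions, "1,7")
  # lowercase letters mark exactly the mismatched positions (5' indexing)
  lc <- gregexpr("[acgt]", plus$site_seq)[[1]]
  expect_equal(as.integer(lc), c(20 + 1 - 7, 20 + 1 - 1))
})

test_that("engine matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:25) {
    glen <- 20L
    tg <- make_toy_genome(1000 + i,
                          c(cA = sample(2000:8000, 1),
                            cB = sample(1000:4000, 1)))
    guide <- random_dna(glen, gc = runif(1, 0.3, 0.7))
    k <- sample(0:5, 1)
    eng <- canonical_hits(search_offtargets(c(g = guide), tg$genome, k))
    ora <- canonical_hits(brute_force_scan(guide, tg$genome, k, "g"))
    expect_identical(eng, ora, info = paste("instance", i, "k =", k))
  }
})

test_that("hit sets grow monotonically with the mismatch budget", {
  set.seed(32)
  tg <- make_toy_genome(33, c(chr1 = 6000))
  guide <- random_dna(20)
  prev <- 0L
  key <- character(0)
  for (k in 0:5) {
    h <- search_offtargets(c(g = guide), tg$genome, k)
    kk <- paste(h$chrom, h$start, h$strand)
    expect_true(all(key %in% kk))
    expect_gte(nrow(h), prev)
    prev <- nrow(h); key <- kk
  }
})

test_that("searching the reverse-complement genome mirrors the hit set", {
  set.seed(34)
  g <- fixture_guide()
  tg <- make_toy_genome(35, c(chr1 = 3000), list(
    plant_spec(g, "chr1", 500, "+", c(4), "AGG"),
    plant_spec(g, "chr1", 900, "-", c(15), "GGG")))
  fwd <- search_offtargets(c(g1 = g), tg$genome, k = 5)
  rc <- c(chr1 = revcomp(tg$genome[["chr1"]]))
  rev <- search_offtargets(c(g1 = g), rc, k = 5)
  n <- nchar(tg$genome[["chr1"]])
  mirrored <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         n_mismatch = rev$n_mismatch,
                         pam_class = rev$pam_class)
  o1 <- order(fwd$start, fwd$strand); o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(fwd$start[o1], mirrored$start[o2])
  expect_equal(fwd$n_mismatch[o1], mirrored$n_mismatch[o2])
  expect_identical(fwd$pam_class[o1], mirrored$pam_class[o2])
})

test_that("every guide from an embedded record is recovered at k = 0", {
  set.seed(36)
  insert <- random_dna(300)
  tg <- make_toy_genome(37, c(chr1 = 4000))
  chrom <- tg$genome[["chr1"]]
  genome <- c(chr1 = paste0(substr(chrom, 1, 1500), insert,
                            substr(chrom, 1501, nchar(chrom))))
  ps <- find_protospacers("ins", insert, mode = "both",
                          gc_min = 0, gc_max = 100)
  expect_gt(nrow(ps), 0)
  hits <- search_offtargets(ps, genome, k = 0)
  for (i in seq_len(nrow(ps))) {
    h <- hits[hits$guide_id == ps$guide_id[i], ]
    expected_start <- 1500 + ps$start[i]
    expect_true(any(h$start == expected_start & h$n_mismatch == 0),
                info = ps$guide_id[i])
  }
})

test_that("off-target counting includes all planted copies", {
  g <- fixture_guide()
  tg <- make_toy_genome(38, c(chr1 = 3000), list(
    plant_spec(g, "chr1", 100, "+", integer(0), "AGG"),
    plant_spec(g, "chr1", 1100, "-", integer(0), "TGG"),
    plant_spec(g, "chr1", 2100, "+", integer(0), "GGG")))
  hits <- search_offtargets(c(g1 = g), tg$genome, k = 0)
  expect_equal(count_offtargets(hits, "g1"), 3)
  expect_equal(count_offtargets(hits, "nonexistent"), 0)
})

test_that("degenerate genomes are handled without error", {
  g <- fixture_guide()
  expect_equal(nrow(search_offtargets(c(g1 = g), c(chr1 = "ACGT"), k = 5)), 0)
  lone <- c(chr1 = paste0(g, "AGG"))
  h <- search_offtargets(c(g1 = g), lone, k = 0)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1, 23))
})

test_that("genome N bases never match a guide base", {
  g <- fixture_guide()
  site <- paste0(g, "AGG")
  substr(site, 10, 10) <- "N"
  genome <- c(chr1 = paste0(strrep("T", 30), site, strrep("T", 30)))
  h0 <- search_offtargets(c(g1 = g), genome, k = 0)
  expect_equal(nrow(h0[h0$start == 31, ]), 0)
  h1 <- search_offtargets(c(g1 = g), genome, k = 1)
  expect_equal(h1[h1$start == 31, "n_mismatch"], 1L)
})
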