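test_that("exemplar mismatch patterns classify to their POT types", {
  expect_identical(classify_hit(c(15, 18)), "I")
  expect_identical(classify_hit(c(9, 14, 20)), "II")
  expect_identical(classify_hit(3), "III")
  expect_identical(classify_hit(c(2, 8, 13, 19)), "excluded")
  expect_identical(classify_hit(integer(0), "NGG"), "perfect")
  expect_identical(classify_hit(integer(0), "NAG"), "I")
  expect_error(classify_hit(21), "outside")
})

test_that("classification agrees with the literal type predicates", {
  set.seed(41)
  for (i in 1:400) {
    n <- sample(0:5, 1)
    pos <- sort(sample(1:20, n))
    got <- classify_hit(pos, "NGG")
    pred <- pot_type_predicates(pos, n)
    if (n == 0) {
      expect_identical(got, "perfect")
    } else if (any(pred)) {
      expect_equal(sum(pred), 1)
      expect_identical(got, names(pred)[pred])
    } else {
      expect_identical(got, "excluded")
    }
  }
})

test_that("truncated-guide region scheme keeps the partition valid", {
  sch <- region_scheme(18)
  expect_identical(sch$region_III, 13:18)
  expect_identical(sort(c(sch$region_I, sch$region_II, sch$region_III)), 1:18)
  expect_error(region_scheme(12))
  expect_identical(classify_hit(c(14, 17), L = 18), "I")
  expect_identical(classify_hit(c(8, 18), L = 18), "II")
})

test_that("risk ranking orders by type then mismatch count", {
  pots <- data.frame(
    guide_id = "g", n_mismatch = c(1L, 3L, 5L, 1L, 0L, 2L, 2L),
    pot_type = c("I", "I", "I", "III", "I", "II", "II"),
    stringsAsFactors = FALSE)
  r <- rank_risk(pots)$risk_rank
  expect_lt(r[1], r[2])            # Type I n=1 outranks Type I n=3
  expect_lt(r[3], r[4])            # Type I n=5 outranks Type III n=1
  expect_equal(r[6], r[7])         # identical (type, n) tie
  expect_equal(r[5], 1)            # NAG perfect (Type I, n=0) is rank 1
  excl <- rank_risk(data.frame(guide_id = "g", n_mismatch = 4L,
                               pot_type = "excluded"))
  expect_true(is.na(excl$risk_rank))
})

test_that("per-guide reports satisfy their counting invariants", {
  g <- fixture_guide()
  tg <- make_toy_genome(42, c(chr1 = 4000), list(
    plant_spec(g, "chr1", 200, "+", integer(0), "AGG"),
    plant_spec(g, "chr1", 700, "+", c(15), "TGG"),
    plant_spec(g, "chr1", 1200, "-", c(3), "AGG"),
    plant_spec(g, "chr1", 1700, "+", c(1, 8, 13, 19), "CGG")))
  hits <- search_offtargets(c(g1 = g), tg$genome, k = 5)
  pots <- classify_hits(hits)
  reps <- guide_reports(data.frame(guide_id = "g1", guide = g,
                                   stringsAsFactors = FALSE), pots)
  expect_equal(reps$total_ot, nrow(hits))
  expect_lte(reps$total_pot, reps$total_ot)
  expect_lte(reps$n_perfect, reps$total_ot)
  expect_equal(reps$total_pot, reps$pot_I + reps$pot_II + reps$pot_III)
  expect_equal(reps$pot_I, 1)   # {15}
  expect_equal(reps$pot_III, 1) # {3}
  expect_equal(reps$n_perfect, 1)
})

test_that("selection cascade applies discards in precedence order", {
  reports <- data.frame(
    guide_id = c("off_genome", "multi", "near_miss", "good_a", "good_b",
                 "multi_and_near"),
    total_ot = c(0L, 12L, 6L, 9L, 4L, 8L),
    n_perfect = c(0L, 2L, 1L, 1L, 1L, 3L),
    pot_I = 0L, pot_II = 0L, pot_III = 0L,
    total_pot = c(0L, 2L, 3L, 2L, 2L, 1L),
    min_mm_pot = c(NA, 3L, 2L, 3L, 4L, 1L),
    n_pot_mm12 = c(0L, 0L, 1L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
  sel <- select_guides(reports)
  v <- setNames(sel$discard_reason, sel$guide_id)
  expect_identical(v[["off_genome"]], "not_on_genome")
  expect_identical(v[["multi"]], "multi_locus")
  expect_identical(v[["near_miss"]], "has_1or2_mm_pot")
  expect_identical(v[["multi_and_near"]], "multi_locus")  # precedence
  kept <- sel[sel$verdict == "kept", ]
  expect_identical(kept$guide_id, c("good_b", "good_a"))  # pot ties -> ot
  expect_true(all(kept$discard_reason == "none"))
})

test_that("POT report files land in the right folders", {
  pots <- data.frame(
    guide_id = c("g_S_1", "g_S_1", "g_S_2"),
    chrom = "chr1", start = c(10L, 50L, 90L), end = c(32L, 72L, 112L),
    strand = "+",
    site_seq = strrep("A", 23), mismatch_positions = c("15", "9", "3"),
    n_mismatch = c(1L, 1L, 1L), pam_class = "NGG",
    stringsAsFactors = FALSE)
  pots <- rank_risk(classify_hits(pots))
  sel <- select_guides(guide_reports(
    data.frame(guide_id = c("g_S_1", "g_S_2"), guide = strrep("A", 20)),
    pots))
  out <- file.path(tempfile(), "run")
  write_pot_reports(pots, sel, out)
  t1 <- read.delim(file.path(out, "Type_I_POT", "Type_I_POT.txt"))
  t2 <- read.delim(file.path(out, "Type_II_POT", "Type_II_POT.txt"))
  t3 <- read.delim(file.path(out, "Type_III_POT", "Type_III_POT.txt"))
  expect_equal(c(nrow(t1), nrow(t2), nrow(t3)), c(1, 1, 1))
  expect_true(file.exists(file.path(out, "Sort_POT_byID", "g_S_1.txt")))
  expect_true(file.exists(file.path(out, "Final_report", "final_report.txt")))
  # empty input still produces header-only files
  out2 <- file.path(tempfile(), "empty")
  empty_pots <- pots[0, ]
  write_pot_reports(empty_pots, select_guides(guide_reports(
    data.frame(guide_id = character(), guide = character()), empty_pots)),
    out2)
  expect_equal(nrow(read.delim(file.path(out2, "Type_I_POT",
                                         "Type_I_POT.txt"))), 0)
})
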