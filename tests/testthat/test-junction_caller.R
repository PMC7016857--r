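test_that("mismatch profiles from CIGAR + MD follow the span conventions", {
  ## plain match
  p <- mismatch_profile("30M", "30")
  expect_equal(p$span, 30L)
  expect_length(p$mm_offsets, 0)
  ## substitutions at MD-reported offsets
  p <- mismatch_profile("30M", "10A15C3")
  expect_equal(p$mm_offsets, c(10L, 26L))
  ## insertions excluded from the reference span
  p <- mismatch_profile("10M2I10M", "20")
  expect_equal(p$span, 20L)
  expect_length(p$mm_offsets, 0)
  ## deletions consume reference bases and count as mismatches
  p <- mismatch_profile("10M2D10M", "10^AC10")
  expect_equal(p$span, 22L)
  expect_equal(p$mm_offsets, c(10L, 11L))
  ## soft clips excluded entirely
  p <- mismatch_profile("5S20M", "20")
  expect_equal(p$span, 20L)
  ## MD/CIGAR disagreement is an error
  expect_error(mismatch_profile("30M", "10"), "inconsistent")
})

test_that("MD-less fallback recomputes mismatches from the reference", {
  ref <- "ACGTACGTACGTACGTACGT"
  qry <- "ACGTACTTACGTACGTACGT"  # one substitution at offset 6
  p <- mismatch_profile("20M", NA, seq = qry, ref_seq = ref)
  expect_equal(p$mm_offsets, 6L)
  ## with an insertion: ref walks 20, query walks 22
  qry2 <- paste0(substr(qry, 1, 10), "GG", substr(qry, 11, 20))
  p2 <- mismatch_profile("10M2I10M", NA, seq = qry2, ref_seq = ref)
  expect_equal(p2$span, 20L)
  expect_equal(p2$mm_offsets, 6L)
  expect_error(mismatch_profile("20M", NA), "no MD")
})

test_that("overhang statistics split the span at the junction seam", {
  s <- overhang_stats(44L, 57L, integer(), 50L)
  expect_equal(c(s$left_len, s$right_len), c(6L, 7L))
  s <- overhang_stats(45L, 57L, integer(), 50L)
  expect_equal(c(s$left_len, s$right_len), c(5L, 7L))
  ## entirely left of the junction: degenerate right side
  s <- overhang_stats(10L, 40L, integer(), 50L)
  expect_equal(s$right_len, 0L)
  ## mismatch rates are per side
  s <- overhang_stats(40L, 60L, c(2L, 5L, 12L), 50L)
  expect_equal(s$left_mm_rate, 2 / 10)
  expect_equal(s$right_mm_rate, 1 / 10)
})

test_that("junction-spanning rule is strict on both overhang and rate", {
  mk <- function(l, r, lr = 0, rr = 0)
    list(left_len = l, right_len = r, left_mm_rate = lr, right_mm_rate = rr)
  expect_true(is_junction_spanning(mk(6, 7)))
  expect_false(is_junction_spanning(mk(5, 20)))    # 5 is not more than 5
  expect_false(is_junction_spanning(mk(20, 20, lr = 3 / 20)))  # 0.15 not < 0.15
  expect_true(is_junction_spanning(mk(20, 20, lr = 2 / 20)))
})

test_that("competitive assignment implements the discard rules", {
  man <- make_manifest(c("circA", "circB"))
  valid_A <- make_hit("t1", "circ|circA", 40L, 70L)
  genome_hit <- make_hit("t1", "chr1", 100L, 130L)
  ## unique valid junction hit, no genome hit
  a <- assign_reads(valid_A, man, all_tags = "t1")
  expect_equal(a$status, "CIRC")
  expect_equal(a$circ_id, "circA")
  ## junction + genome: discarded as CIRC_AND_LINEAR
  a <- assign_reads(rbind(valid_A, genome_hit), man, all_tags = "t1")
  expect_equal(a$status, "CIRC_AND_LINEAR")
  ## two circRNAs: ambiguous
  b <- rbind(valid_A, make_hit("t1", "circ|circB", 44L, 70L))
  expect_equal(assign_reads(b, man, all_tags = "t1")$status,
               "AMBIGUOUS_MULTI_CIRC")
  ## genome only
  expect_equal(assign_reads(genome_hit, man, all_tags = "t1")$status, "LINEAR")
  ## junction hit that does not span
  ns <- make_hit("t1", "circ|circA", 10L, 40L)
  expect_equal(assign_reads(ns, man, all_tags = "t1")$status, "NONSPANNING")
  ## genome hit beats a non-spanning junction hit
  expect_equal(assign_reads(rbind(ns, genome_hit), man,
                            all_tags = "t1")$status, "LINEAR")
  ## no hits at all
  expect_equal(assign_reads(valid_A, man, all_tags = c("t1", "t9"))$status,
               c("CIRC", "UNALIGNED"))
})

test_that("duplicate hits to the same circRNA collapse to the best one", {
  man <- make_manifest("circA")
  h <- rbind(make_hit("t1", "circ|circA", 40L, 70L, mm_offsets = c(1L, 2L)),
             make_hit("t1", "circ|circA", 42L, 72L, mm_offsets = 5L),
             make_hit("t1", "circ|circA", 41L, 71L, mm_offsets = 8L))
  a <- assign_reads(h, man, all_tags = "t1")
  expect_equal(a$status, "CIRC")
  expect_equal(a$ref_start, 41L)  # fewest mismatches wins, tie -> leftmost
})

test_that("assignment is a partition and monotone in the thresholds", {
  man <- make_manifest(c("c1", "c2"))
  set.seed(99)
  tags <- sprintf("t%03d", 1:120)
  hits <- do.call(rbind, lapply(tags, function(tg) {
    n <- sample(0:3, 1)
    if (n == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(j) {
      ref <- sample(c("circ|c1", "circ|c2", "chr1"), 1)
      st <- sample(30:60, 1); len <- sample(12:40, 1)
      nmm <- sample(0:3, 1)
      make_hit(tg, ref, st, st + len,
               mm_offsets = if (nmm) sort(sample.int(len, nmm)) - 1L else integer(),
               orientation = sample(c("+", "-"), 1))
    }))
  }))
  base <- assign_reads(hits, man, all_tags = tags)
  expect_equal(nrow(base), length(tags))
  expect_equal(sum(table(base$status)), length(tags))
  n_circ <- function(a) sum(a$status == "CIRC")
  ## stricter overhang or rate never increases CIRC count
  expect_lte(n_circ(assign_reads(hits, man, min_overhang = 10, all_tags = tags)),
             n_circ(base))
  expect_lte(n_circ(assign_reads(hits, man, max_mm_rate = 0.05, all_tags = tags)),
             n_circ(base))
  ## sense_only restricts further
  expect_lte(n_circ(assign_reads(hits, man, sense_only = TRUE, all_tags = tags)),
             n_circ(base))
})

test_that("SAM parsing yields grouped hits with mismatch profiles", {
  d <- withr::local_tempdir()
  man <- make_manifest("circA", junction_offset = 8L)
  sam <- c("@HD\tVN:1.6\tSO:unknown",
           "@SQ\tSN:chr1\tLN:50",
           "@SQ\tSN:circ|circA\tLN:16",
           paste("t1", 0, "circ|circA", 3, 0, "10M", "*", 0, 0,
                 strrep("A", 10), "*", "NM:i:1", "MD:Z:4G5", sep = "\t"),
           paste("t2", 4, "*", 0, 0, "*", "*", 0, 0, strrep("C", 10), "*",
                 sep = "\t"),
           paste("t3", 16, "chr1", 11, 0, "10M", "*", 0, 0,
                 strrep("A", 10), "*", "NM:i:0", "MD:Z:10", sep = "\t"))
  sf <- file.path(d, "toy.sam")
  writeLines(sam, sf)
  hits <- parse_alignments(sf, man)
  expect_equal(nrow(hits), 2L)  # unmapped t2 yields no hit
  h1 <- hits[hits$tag_id == "t1", ]
  expect_true(h1$is_junction_ref)
  expect_equal(h1$ref_start, 2L)
  expect_equal(h1$ref_end, 12L)
  expect_equal(h1$mm_offsets[[1]], 4L)
  h3 <- hits[hits$tag_id == "t3", ]
  expect_equal(h3$orientation, "-")
  expect_false(h3$is_junction_ref)
  expect_setequal(attr(hits, "all_tags"), c("t1", "t2", "t3"))
})
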