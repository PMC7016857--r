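test_that("hypergeometric tail matches exact rational values", {
  ## frozen values computed with exact integer arithmetic (fractions of
  ## binomial coefficients)
  cases <- list(
    list(4, 4, 5, 10, 0.023809523809523808),
    list(0, 3, 4, 10, 1.0),
    list(2, 5, 5, 12, 0.7525252525252525),
    list(7, 9, 8, 20, 0.003215051202667302),
    list(3, 10, 4, 40, 0.04168946274209432),
    list(10, 10, 10, 10, 1.0),
    list(1, 30, 2, 60, 0.7542372881355932),
    list(12, 20, 25, 60, 0.03954664938077668),
    list(5, 6, 50, 60, 0.7406200800337809),
    list(2, 2, 2, 4, 0.16666666666666666))
  for (cs in cases)
    expect_equal(hypergeom_tail(cs[[1]], cs[[2]], cs[[3]], cs[[4]]), cs[[5]],
                 tolerance = 1e-12)
  expect_identical(hypergeom_tail(0, 5, 5, 20), 1)
  expect_error(hypergeom_tail(6, 5, 5, 20), "bounds")
  expect_error(hypergeom_tail(2, 25, 5, 20), "bounds")
})

test_that("hypergeometric tail matches a factorial summation oracle", {
  oracle <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
  }
  set.seed(77)
  for (i in 1:1000) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle(k, K, n, N),
                 tolerance = 1e-9,
                 info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
})

test_that("strand bias recovers planted sense fractions", {
  man <- make_manifest("cA")
  anno <- data.frame(chrom = "chr1", start = 0L, end = 500L, strand = "+",
                     gene_id = "g1", stringsAsFactors = FALSE)
  mk_asn <- function(n_sense, n_anti) data.frame(
    tag_id = sprintf("t%d", seq_len(n_sense + n_anti)), status = "CIRC",
    circ_id = "cA", ref = "circ|cA", ref_start = 40L, ref_end = 70L,
    orientation = c(rep("+", n_sense), rep("-", n_anti)),
    stringsAsFactors = FALSE)
  sb <- strand_bias(mk_asn(80, 20), man, anno)
  expect_equal(sb$circ_sense_fraction, 0.8)
  expect_equal(sb$n_circ_reads, 100L)
  ## zero circ reads: flagged undefined
  sb0 <- strand_bias(mk_asn(1, 0)[0, ], man, anno)
  expect_true(is.na(sb0$circ_sense_fraction))
  expect_equal(sb0$n_circ_reads, 0L)
  ## minus-strand parental gene flips the call
  anno_m <- transform(anno, strand = "-")
  man_m <- man; man_m$strand <- "-"
  sb_m <- strand_bias(mk_asn(80, 20), man_m, anno_m)
  expect_equal(sb_m$circ_sense_fraction, 0.8)
  ## circRNA outside any gene: reads excluded with a count
  anno_far <- transform(anno, chrom = "chr9")
  sb_x <- strand_bias(mk_asn(5, 0), man, anno_far)
  expect_equal(sb_x$n_excluded_no_parent, 5L)
  expect_equal(sb_x$n_circ_reads, 0L)
})

test_that("linear-side strand bias uses sampled transcripts", {
  anno <- data.frame(chrom = "chr1", start = c(0L, 600L),
                     end = c(500L, 1100L), strand = c("+", "-"),
                     gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  asn <- data.frame(
    tag_id = sprintf("t%d", 1:40), status = "LINEAR", circ_id = NA,
    ref = "chr1", ref_start = c(rep(100L, 30), rep(700L, 10)),
    ref_end = c(rep(130L, 30), rep(730L, 10)),
    orientation = rep("+", 40), stringsAsFactors = FALSE)
  sb <- strand_bias(asn, make_manifest("cA"), anno, seed = 4)
  ## 30 reads sense on g1 (+), 10 reads antisense on g2 (-)
  expect_equal(sb$linear_sense_fraction, 0.75)
  expect_equal(sb$n_linear_transcripts_sampled, 2L)
})

test_that("background junction sequences follow exon order and strand", {
  g <- random_genome(len = 400, seed = 55)
  ex <- data.frame(transcript_id = "tx1", chrom = "chr1",
                   start = c(100L, 200L), end = c(130L, 230L), strand = "+",
                   stringsAsFactors = FALSE)
  bg <- build_background_junctions(ex, g)
  expect_equal(unname(bg), paste0(substr(g[[1]], 116, 130),
                                  substr(g[[1]], 201, 215)))
  ## minus strand: reverse complement with exon order reversed
  ex_m <- transform(ex, strand = "-")
  bg_m <- build_background_junctions(ex_m, g)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(bg_m), paste0(rc(substr(g[[1]], 201, 215)),
                                    rc(substr(g[[1]], 116, 130))))
  ## 3 exons -> 2 junctions; single exon -> none; short exons give full length
  ex3 <- data.frame(transcript_id = "tx2", chrom = "chr1",
                    start = c(10L, 50L, 90L), end = c(20L, 70L, 120L),
                    strand = "+", stringsAsFactors = FALSE)
  expect_length(build_background_junctions(ex3, g), 2L)
  expect_equal(nchar(build_background_junctions(ex3, g)[[1]]), 10 + 15)
  expect_length(build_background_junctions(ex3[1, ], g), 0L)
})

test_that("motif foreground extracts covered contig blocks", {
  man <- make_manifest("cA")
  contigs <- stats::setNames(paste(rep("ACGT", 25), collapse = ""),
                             man$contig)
  pooled <- data.frame(rbp_condition = "R", circ_id = "cA",
                       tag_id = c("t1", "t2"),
                       ref_start = c(40L, 70L), ref_end = c(60L, 80L),
                       orientation = "+", multiplicity = 1L,
                       stringsAsFactors = FALSE)
  cand <- data.frame(rbp_condition = "R", circ_id = "cA",
                     stringsAsFactors = FALSE)
  fg <- export_motif_foreground(cand, pooled, contigs, man)
  expect_length(fg, 2L)  # two disjoint covered blocks
  expect_equal(nchar(fg[[1]]), 20L)
  expect_equal(fg[[1]], substr(contigs[[1]], 41, 60))
  expect_length(export_motif_foreground(cand[0, ], pooled, contigs, man), 0L)
})

test_that("binding profiles prune the most frequent species", {
  sets <- list(R1 = c("c1", "c2", "c3"), R2 = c("c1", "c4"),
               R3 = c("c1", "c2", "c5"))
  bp0 <- binding_profile(sets, drop_top_n = 0)
  expect_equal(dim(bp0$matrix), c(3L, 5L))
  ## c1 bound by all three is pruned first
  bp1 <- binding_profile(sets, drop_top_n = 1)
  expect_equal(bp1$dropped_circ, "c1")
  expect_false("c1" %in% colnames(bp1$matrix))
  ## frequency-sort oracle: no remaining column exceeds the dropped minimum
  freq <- colSums(bp0$matrix)
  expect_true(all(colSums(bp1$matrix) <= min(freq[bp1$dropped_circ])))
  ## an RBP left empty is dropped with a warning
  sets2 <- list(R1 = c("c1", "c2", "c3"), R2 = "c1", R3 = c("c2", "c3"))
  expect_warning(bp2 <- binding_profile(sets2, drop_top_n = 2), "dropped")
  expect_false("R2" %in% rownames(bp2$matrix))
  ## pruning everything is an error
  expect_error(binding_profile(sets2, drop_top_n = 3), "smaller drop_top_n")
})

test_that("RBP distances are pairwise hypergeometric tail p-values", {
  m <- rbind(A = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             B = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             C = c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0))
  d <- rbp_distance_matrix(m)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  ## disjoint profiles: k = 0 so p = 1
  expect_equal(d["A", "C"], 1)
  ## identical profiles: minimal p among all pairs with those margins
  enum <- vapply(0:4, function(k) hypergeom_tail(k, 4, 4, 10), numeric(1))
  expect_equal(d["A", "B"], min(enum[enum >= d["A", "B"]]))
  expect_equal(d["A", "B"], hypergeom_tail(4, 4, 4, 10))
})

test_that("hierarchical clustering merges closest RBPs first", {
  d <- matrix(c(0, .1, .9,
                .1, 0, .9,
                .9, .9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # A and B merge first
  expect_equal(hc$hclust$height[1], 0.1)
  expect_match(hc$newick, "\\(")
  ## two leaves: one merge at their distance
  d2 <- matrix(c(0, .3, .3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(d2)$hclust$height, 0.3)
  ## permutation invariance of merge heights
  p <- c(3, 1, 2)
  hp <- hierarchical_cluster(d[p, p])
  expect_equal(sort(hp$hclust$height), sort(hc$hclust$height))
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("gene-set enrichment applies size filters and Bonferroni", {
  set.seed(10)
  universe <- sprintf("g%04d", 1:500)
  gmt <- list(small = universe[1:9],              # < 10 genes: dropped
              termA = universe[1:40],
              termB = universe[101:160])
  sets <- list(tiny = universe[1:100],            # exactly 100: excluded
               rich = c(universe[1:35], universe[300:380]))
  res <- go_enrichment(sets, gmt, universe, n_rand = 5, seed = 3)
  expect_false("small" %in% res$term_id)
  expect_false("tiny" %in% res$rbp)
  expect_equal(sort(unique(res$term_id)), c("termA", "termB"))
  ## overlap and p-value check against direct computation
  rA <- res[res$term_id == "termA", ]
  expect_equal(rA$k_overlap, 35L)
  expect_equal(rA$p_true, hypergeom_tail(35, 40, rA$gene_set_size, 500))
  expect_equal(rA$corrected_score,
               rA$log_p_true - rA$mean_log_p_background)
  ## strong enrichment is Bonferroni-significant, unrelated term is not
  expect_true(rA$significant)
  expect_false(res[res$term_id == "termB", "significant"])
  expect_error(go_enrichment(sets, gmt, character(0)), "empty")
})

test_that("enrichment randomization is reproducible and order-independent", {
  universe <- sprintf("g%04d", 1:400)
  gmt <- list(t1 = universe[1:30], t2 = universe[31:80])
  sets <- list(A = universe[c(1:70, 200:250)], B = universe[100:220])
  r1 <- go_enrichment(sets, gmt, universe, seed = 9)
  r2 <- go_enrichment(sets, gmt, universe, seed = 9)
  expect_equal(r1, r2)
  ## reversing RBP order does not change each RBP's background
  r3 <- go_enrichment(rev(sets), gmt, universe, seed = 9)
  for (rbp in names(sets))
    expect_equal(r3$mean_log_p_background[r3$rbp == rbp],
                 r1$mean_log_p_background[r1$rbp == rbp])
})
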