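# shared in-code fixtures: a tiny deterministic genome and circRNA set, and
# small constructors used across test files

toy_genome <- function() {
  c(chr1 = "ACGTACGTACGTACGTACGTTTGCAGGTCAATCGGATCCTTAGGCATGCA",
    chr2 = "TTTTACGCGCGCATATATATGGGCCCAAATTTCCCGGGATCGATCGATCG")
}

toy_circs <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2"),
             start = c(4L, 10L, 2L),
             end = c(12L, 40L, 30L),
             strand = c("+", "-", "+"),
             circ_id = c("cA", "cB", "cC"),
             source = "toy", stringsAsFactors = FALSE)
}

# random uppercase genome as a named character vector
random_genome <- function(n_chroms = 1, len = 1000, seed = 1) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n_chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)),
    paste0("chr", seq_len(n_chroms)))
}

# build a hits data.frame row set for assign_reads tests
make_hit <- function(tag, ref, start, end, mm_offsets = integer(),
                     orientation = "+", is_junction = grepl("^circ\\|", ref)) {
  h <- data.frame(tag_id = tag, ref = ref, ref_start = start, ref_end = end,
                  orientation = orientation, n_mm = length(mm_offsets),
                  is_junction_ref = is_junction, stringsAsFactors = FALSE)
  h$mm_offsets <- list(as.integer(mm_offsets))
  h
}

make_manifest <- function(circ_ids, junction_offset = 50L) {
  if (length(circ_ids) == 0)
    return(data.frame(contig = character(), circ_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), junction_offset = integer(),
                      stringsAsFactors = FALSE))
  data.frame(contig = paste0("circ|", circ_ids),
             circ_id = circ_ids, chrom = "chr1", start = 0L, end = 100L,
             strand = "+", junction_offset = junction_offset,
             stringsAsFactors = FALSE)
}

# independent slicing oracle for junction contigs (string ops only)
oracle_contig <- function(circ, genome, flank = 50) {
  full <- toupper(substr(genome[[circ$chrom]], circ$start + 1, circ$end))
  if (circ$strand == "-") {
    comp <- chartr("ACGTN", "TGCAN", full)
    full <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  L <- nchar(full)
  k <- min(flank, L)
  paste0(substr(full, L - k + 1, L), substr(full, 1, k))
}
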