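## Synthetic data with known ground truth: random genomes with multi-exon
## gene models, planted circRNAs, CLIP-like reads (short, duplicated,
## partially antisense), and an exhaustive ungapped aligner so the whole
## pipeline is testable without external data or an external aligner.

#' Simulation configuration
#'
#' Defaults emulate a desk-scale CLIP-Seq experiment: a 200 kb two-chromosome
#' genome, 40 multi-exon genes, 20 circRNAs of which 10 receive
#' junction-spanning reads, short (25-40 nt) single-end reads, a low
#' per-base error rate, substantial PCR duplication, a modest antisense
#' fraction, plus linear-transcript reads and intergenic genomic reads as the
#' negative-control class.
#'
#' @param seed Master seed; each simulation stage derives its own substream.
#' @param n_chroms,chrom_len Genome shape.
#' @param n_genes,exons_per_gene,gene_len,intergenic_min Gene models
#'   (\code{gene_len} is a min/max range).
#' @param n_circ,circ_len Planted circRNAs (each in a distinct gene, sense
#'   strand).
#' @param n_bound_circ Number of circRNAs receiving junction reads.
#' @param reads_per_circ Min/max junction reads per bound circRNA.
#' @param read_len Min/max read length.
#' @param min_overhang Minimum planted bases on each side of the junction.
#' @param mismatch_rate Per-base substitution rate injected into reads.
#' @param pcr_dup_rate Probability a read is PCR-duplicated (geometric copy
#'   count).
#' @param antisense_fraction Fraction of junction/linear reads emitted
#'   reverse-complemented.
#' @param n_linear_reads,n_genomic_reads Linear-transcript and intergenic
#'   read counts.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 100000L,
                       n_genes = 40L, exons_per_gene = 3L,
                       gene_len = c(1500L, 3000L), intergenic_min = 500L,
                       n_circ = 20L, circ_len = c(100L, 400L),
                       n_bound_circ = 10L, reads_per_circ = c(4L, 8L),
                       read_len = c(32L, 40L), min_overhang = 16L,
                       mismatch_rate = 0.01, pcr_dup_rate = 0.4,
                       antisense_fraction = 0.1,
                       n_linear_reads = 5000L, n_genomic_reads = 2000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mismatch_rate >= 0, cfg$mismatch_rate <= 1,
            cfg$pcr_dup_rate >= 0, cfg$pcr_dup_rate <= 1,
            cfg$antisense_fraction >= 0, cfg$antisense_fraction <= 1,
            cfg$chrom_len > 0, cfg$n_bound_circ <= cfg$n_circ,
            cfg$read_len[1] >= 2 * cfg$min_overhang)
  class(cfg) <- "sim_config"
  cfg
}

## independent per-stage substream seeds derived from the master seed
.sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 17389L + stage * 101L
}

#' Simulate a genome with gene models and planted circRNAs
#'
#' Uniform-random chromosomes; non-overlapping multi-exon genes placed with
#' intergenic gaps; circRNAs placed inside distinct genes on the gene's
#' strand.  Deterministic given \code{config$seed}.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: writes \code{genome.fa},
#'   \code{genes.gff3} and \code{circ.bed} (BED6).
#' @return List with \code{genome} (named character), \code{genes},
#'   \code{exons}, \code{circs} (data.frames, 0-based half-open) and
#'   \code{paths} when written.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  set.seed(.sub_seed(config$seed, 1L))
  genome <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i)
      paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
            collapse = ""), character(1)),
    paste0("chr", seq_len(config$n_chroms)))
  ## place genes sequentially with gaps
  set.seed(.sub_seed(config$seed, 2L))
  genes <- list(); exons <- list()
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    pos <- config$intergenic_min
    for (g in seq_len(per_chrom[ci])) {
      len <- sample(config$gene_len[1]:config$gene_len[2], 1L)
      if (pos + len + config$intergenic_min > config$chrom_len)
        stop("requested genes exceed chromosome capacity")
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("gene_%03d", gid)
      genes[[gid]] <- data.frame(gene_id = gene_id,
                                 chrom = names(genome)[ci],
                                 start = pos, end = pos + len,
                                 strand = strand, stringsAsFactors = FALSE)
      ## alternate exon/intron blocks across the gene span
      nb <- 2L * config$exons_per_gene - 1L
      w <- stats::runif(nb, 0.5, 1.5)
      parts <- floor(len * w / sum(w))
      parts[nb] <- parts[nb] + (len - sum(parts))
      b0 <- pos + c(0L, cumsum(parts))
      for (e in seq_len(config$exons_per_gene)) {
        k <- 2L * e - 1L
        exons[[length(exons) + 1L]] <- data.frame(
          transcript_id = gene_id, gene_id = gene_id,
          chrom = names(genome)[ci],
          start = b0[k], end = b0[k + 1L], strand = strand,
          stringsAsFactors = FALSE)
      }
      pos <- pos + len + config$intergenic_min +
        sample(0:config$intergenic_min, 1L)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  ## circRNAs inside distinct genes, sense strand
  set.seed(.sub_seed(config$seed, 3L))
  circs <- if (config$n_circ > 0) {
    stopifnot(config$n_circ <= nrow(genes))
    host <- sample(nrow(genes), config$n_circ)
    do.call(rbind, lapply(seq_len(config$n_circ), function(i) {
      g <- genes[host[i], ]
      len <- sample(config$circ_len[1]:config$circ_len[2], 1L)
      s <- g$start + sample.int(g$end - g$start - len, 1L)
      data.frame(chrom = g$chrom, start = s, end = s + len,
                 strand = g$strand, circ_id = sprintf("circ_%03d", i),
                 source = "sim", gene_id = g$gene_id,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), circ_id = character(),
               source = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    write_fasta(genome, fa)
    gff <- file.path(out_dir, "genes.gff3")
    gr <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end),
      strand = exons$strand, type = "exon", ID = exons$transcript_id)
    rtracklayer::export(gr, gff, format = "gff3")
    bed <- file.path(out_dir, "circ.bed")
    utils::write.table(
      data.frame(circs$chrom, circs$start, circs$end, circs$circ_id, 0L,
                 circs$strand),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- list(fasta = fa, gff = gff, bed = bed)
  }
  list(genome = genome, genes = genes, exons = exons, circs = circs,
       paths = paths)
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_mm = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), n_mm = length(hit))
}

#' Simulate CLIP-Seq reads with ground truth
#'
#' Draws junction-spanning reads across planted back-splice junctions (with
#' at least \code{min_overhang} bases on each side), linear reads from exon
#' interiors, and genomic reads from intergenic DNA; injects per-base
#' substitutions, emits a configured fraction antisense
#' (reverse-complemented), and PCR-duplicates reads with geometric copy
#' counts.  Every emitted read has exactly one truth row.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param classes Which read classes to emit (subset of
#'   \code{c("junction", "linear", "genomic")}).
#' @param fastq Optional FASTQ output path.
#' @return List with \code{reads} (data.frame: read_id, seq), \code{truth}
#'   (read_id, class, origin, start, end, sense, n_mm, parent_id),
#'   \code{bound_circs} (circ_ids receiving junction reads).
#' @export
simulate_clip_reads <- function(config, sim,
                                classes = c("junction", "linear", "genomic"),
                                fastq = NULL) {
  genome_uc <- vapply(sim$genome, toupper, character(1))
  ids <- character(); seqs <- character(); truth <- list()
  add <- function(class, origin, start, end, sense, seq, n_mm) {
    id <- sprintf("read_%06d", length(ids) + 1L)
    ids[[length(ids) + 1L]] <<- id
    seqs[[length(seqs) + 1L]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = id, class = class, origin = origin, start = start, end = end,
      sense = sense, n_mm = n_mm, parent_id = id, stringsAsFactors = FALSE)
  }
  rl_draw <- function() sample(config$read_len[1]:config$read_len[2], 1L)
  ## junction reads
  set.seed(.sub_seed(config$seed, 4L))
  bound <- character()
  if ("junction" %in% classes && config$n_bound_circ > 0) {
    bound <- sim$circs$circ_id[
      sample(nrow(sim$circs), config$n_bound_circ)]
    for (cid in bound) {
      circ <- sim$circs[sim$circs$circ_id == cid, ]
      jc <- build_junction_contig(circ, genome_uc)
      k <- jc$junction_offset
      n_j <- sample(config$reads_per_circ[1]:config$reads_per_circ[2], 1L)
      for (r in seq_len(n_j)) {
        rl <- rl_draw()
        lo <- max(0L, k - (rl - config$min_overhang))
        hi <- min(k - config$min_overhang, 2L * k - rl)
        if (lo > hi) {
          warning("circRNA ", cid, " too short for configured overhangs; skipped")
          next
        }
        s0 <- sample(lo:hi, 1L)
        raw <- substr(jc$seq, s0 + 1L, s0 + rl)
        sense <- stats::runif(1) >= config$antisense_fraction
        mut <- .mutate_seq(raw, config$mismatch_rate)
        out <- if (sense) mut$seq else revcomp(mut$seq)
        add("junction", cid, s0, s0 + rl, sense, out, mut$n_mm)
      }
    }
  }
  ## linear reads from exon interiors
  set.seed(.sub_seed(config$seed, 5L))
  if ("linear" %in% classes && config$n_linear_reads > 0) {
    ex <- sim$exons
    ew <- ex$end - ex$start
    for (r in seq_len(config$n_linear_reads)) {
      rl <- rl_draw()
      ok <- which(ew >= rl)
      e <- ex[sample(ok, 1L, prob = ew[ok]), ]
      s0 <- e$start + sample.int(e$end - e$start - rl + 1L, 1L) - 1L
      raw <- toupper(subseq0(genome_uc[[e$chrom]], s0, s0 + rl))
      tx_oriented <- if (e$strand == "+") raw else revcomp(raw)
      sense <- stats::runif(1) >= config$antisense_fraction
      mut <- .mutate_seq(tx_oriented, config$mismatch_rate)
      out <- if (sense) mut$seq else revcomp(mut$seq)
      add("linear", e$gene_id, s0, s0 + rl, sense, out, mut$n_mm)
    }
  }
  ## genomic reads from intergenic DNA (negative-control class)
  set.seed(.sub_seed(config$seed, 6L))
  if ("genomic" %in% classes && config$n_genomic_reads > 0) {
    inter <- list()
    for (ch in names(sim$genome)) {
      g <- sim$genes[sim$genes$chrom == ch, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      bounds <- c(0L, as.vector(rbind(g$start, g$end)), config$chrom_len)
      for (i in seq(1, length(bounds) - 1L, by = 2L)) {
        if (bounds[i + 1L] - bounds[i] >= config$read_len[2])
          inter[[length(inter) + 1L]] <- data.frame(
            chrom = ch, start = bounds[i], end = bounds[i + 1L],
            stringsAsFactors = FALSE)
      }
    }
    inter <- do.call(rbind, inter)
    iw <- inter$end - inter$start
    for (r in seq_len(config$n_genomic_reads)) {
      rl <- rl_draw()
      ok <- which(iw >= rl)
      iv <- inter[sample(ok, 1L, prob = iw[ok]), ]
      s0 <- iv$start + sample.int(iv$end - iv$start - rl + 1L, 1L) - 1L
      raw <- toupper(subseq0(genome_uc[[iv$chrom]], s0, s0 + rl))
      mut <- .mutate_seq(raw, config$mismatch_rate)
      out <- if (stats::runif(1) < 0.5) mut$seq else revcomp(mut$seq)
      add("genomic", iv$chrom, s0, s0 + rl, NA, out, mut$n_mm)
    }
  }
  ## PCR duplication with geometric copy counts
  set.seed(.sub_seed(config$seed, 7L))
  n0 <- length(ids)
  for (i in seq_len(n0)) {
    if (stats::runif(1) < config$pcr_dup_rate) {
      extra <- stats::rgeom(1, 0.5) + 1L
      for (d in seq_len(extra)) {
        id <- paste0(ids[[i]], "_dup", d)
        ids[[length(ids) + 1L]] <- id
        seqs[[length(seqs) + 1L]] <- seqs[[i]]
        tr <- truth[[i]]
        tr$read_id <- id
        tr$parent_id <- tr$parent_id[1]
        truth[[length(truth) + 1L]] <- tr
      }
    }
  }
  reads <- data.frame(read_id = unlist(ids), seq = unlist(seqs),
                      stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  if (!is.null(fastq)) write_fastq(reads$read_id, reads$seq, fastq)
  list(reads = reads, truth = truth, bound_circs = bound)
}

#' Write reads as FASTQ
#' @param ids,seqs Read identifiers and sequences.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

## MD tag for an ungapped alignment
.md_string <- function(ref_sub, aln_seq) {
  r <- strsplit(toupper(ref_sub), "", fixed = TRUE)[[1]]
  q <- strsplit(toupper(aln_seq), "", fixed = TRUE)[[1]]
  mmpos <- which(r != q)
  if (length(mmpos) == 0) return(as.character(length(r)))
  runs <- diff(c(0L, mmpos)) - 1L
  paste0(paste0(runs, r[mmpos], collapse = ""),
         length(r) - mmpos[length(mmpos)])
}

#' Exhaustively align reads to a small reference set
#'
#' Reports every ungapped full-length placement of each read (forward and
#' reverse complement) on every reference sequence with a mismatch count at
#' most \code{ceiling(max_mm_rate * read length)}, as SAM with correct CIGAR,
#' NM and MD fields; reads with no placement get an unmapped record.  The
#' best placement (fewest mismatches, then reference order, then leftmost) is
#' primary; the rest are secondary.  Intended as a complete testing oracle
#' for small references, not a production aligner.
#'
#' @param seqs Named character vector of read sequences (names become QNAME).
#' @param refs Named character vector of reference sequences (combined
#'   junction contigs + genome).
#' @param max_mm_rate Mismatch budget as a fraction of read length
#'   (default 0.2).
#' @param out_sam Optional SAM output path.
#' @return Character vector of SAM lines (invisibly written when
#'   \code{out_sam} is given).
#' @export
naive_align <- function(seqs, refs, max_mm_rate = 0.2, out_sam = NULL) {
  stopifnot(!is.null(names(seqs)), !is.null(names(refs)))
  refs_uc <- vapply(refs, toupper, character(1))
  reads_uc <- toupper(seqs)
  budget <- as.integer(ceiling(max_mm_rate * nchar(reads_uc)))
  hits <- cpp_scan_hits(unname(reads_uc), unname(refs_uc), budget)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs_uc)))
  recs <- vector("list", length(seqs))
  hit_by_read <- split(hits, factor(hits$read, levels = seq_along(seqs)))
  rc_cache <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads_uc)))
  for (i in seq_along(seqs)) {
    qname <- names(seqs)[i]
    h <- hit_by_read[[i]]
    L <- nchar(reads_uc[[i]])
    if (is.null(h) || nrow(h) == 0) {
      recs[[i]] <- paste(qname, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                         reads_uc[[i]], "*", sep = "\t")
      next
    }
    h <- h[order(h$mm, h$ref, h$pos, h$strand), , drop = FALSE]
    rev <- h$strand == "-"
    aln <- ifelse(rev, rc_cache[[i]], reads_uc[[i]])
    md <- character(nrow(h))
    for (j in seq_len(nrow(h)))
      md[j] <- .md_string(subseq0(refs_uc[[h$ref[j]]], h$pos[j], h$pos[j] + L),
                          aln[j])
    flag <- ifelse(rev, 16L, 0L) + c(0L, rep(256L, nrow(h) - 1L))
    recs[[i]] <- paste(qname, flag, names(refs)[h$ref], h$pos + 1L,
                       0L, paste0(L, "M"), "*", 0L, 0L, aln, "*",
                       paste0("NM:i:", h$mm), paste0("MD:Z:", md),
                       sep = "\t")
  }
  sam <- c(header, unlist(recs))
  if (!is.null(out_sam)) writeLines(sam, out_sam)
  invisible(sam)
}
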