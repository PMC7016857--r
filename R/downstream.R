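## Downstream characterizations of RBP-circRNA interactions: strand bias,
## motif foreground/background sequence export, binding-profile clustering of
## RBPs, and randomization-corrected hypergeometric gene-set enrichment.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k marked elements when sampling n from a universe of N containing K marked
#' elements.  Computed in log space via [stats::phyper()] for stability.
#'
#' @param k Observed overlap (vectorized).
#' @param K Number of marked elements (e.g. term size).
#' @param n Sample size (e.g. gene-set size).
#' @param N Universe size.
#' @param log10p Return log10 of the tail probability instead.
#' @return Numeric vector of probabilities in (0, 1\] (or their log10).
#' @export
hypergeom_tail <- function(k, K, n, N, log10p = FALSE) {
  if (any(k < 0 | k > pmin(K, n)) || any(K > N) || any(n > N) ||
      any(K < 0) || any(n < 0))
    stop("hypergeom_tail: invalid bounds (need 0 <= k <= min(K, n), K,n <= N)")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

## coerce a 0-based half-open annotation data.frame to GRanges
.anno_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  id_col <- intersect(c("gene_id", "transcript_id", "id", "name"), names(x))[1]
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand)
  S4Vectors::mcols(gr)$id <- if (!is.na(id_col)) x[[id_col]] else
    paste0("feat_", seq_len(nrow(x)))
  gr
}

#' Strand bias of circRNA-bound versus linear-transcript reads
#'
#' For one RBP/condition, computes the fraction of circRNA-assigned reads
#' oriented with the parental gene's sense strand, and the same fraction for
#' reads on a seeded uniform sample of annotated linear transcripts.  A
#' forward-orientation junction-contig hit follows the circRNA's own strand;
#' its sense/antisense call relative to the parental gene combines the hit
#' orientation with the circRNA and gene strands.
#'
#' @param assignments data.frame from [assign_reads()] (CIRC and LINEAR rows
#'   are used).
#' @param manifest Junction manifest (circRNA coordinates and strands).
#' @param annotation Transcript/gene annotation: a GRanges, or a data.frame
#'   with \code{chrom, start, end, strand} (0-based half-open) and an id
#'   column.
#' @param n_linear_sample Maximum number of transcripts sampled for the
#'   linear fraction (default 3000).
#' @param seed Seed for the transcript sample.
#' @return List with \code{circ_sense_fraction}, \code{linear_sense_fraction}
#'   (NA when the respective read count is zero), \code{n_circ_reads},
#'   \code{n_linear_reads}, \code{n_linear_transcripts_sampled}, and
#'   \code{n_excluded_no_parent}.
#' @export
strand_bias <- function(assignments, manifest, annotation,
                        n_linear_sample = 3000L, seed = 1L) {
  anno <- .anno_granges(annotation)
  ## --- circRNA side -------------------------------------------------------
  circ <- assignments[assignments$status == "CIRC", , drop = FALSE]
  n_excluded <- 0L
  sense <- logical(0)
  if (nrow(circ) > 0) {
    m <- manifest[match(circ$circ_id, manifest$circ_id), , drop = FALSE]
    cgr <- GenomicRanges::GRanges(m$chrom,
                                  IRanges::IRanges(m$start + 1L, m$end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(cgr, anno, type = "within",
                                  ignore.strand = TRUE))
    parent <- rep(NA_character_, nrow(circ))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    gene_strand <- as.character(GenomicRanges::strand(anno))
    for (i in unique(qh)) {
      cand <- sh[qh == i]
      same <- cand[gene_strand[cand] == m$strand[i]]
      pick <- if (length(same)) same[1] else cand[1]
      parent[i] <- gene_strand[pick]
    }
    n_excluded <- sum(is.na(parent))
    ok <- !is.na(parent)
    ## forward hit = read in circRNA orientation = on the circ's genomic strand
    read_genomic_strand <- ifelse(circ$orientation[ok] == "+",
                                  m$strand[ok],
                                  ifelse(m$strand[ok] == "+", "-", "+"))
    sense <- read_genomic_strand == parent[ok]
  }
  ## --- linear side --------------------------------------------------------
  lin <- assignments[assignments$status == "LINEAR", , drop = FALSE]
  n_tx <- min(n_linear_sample, length(anno))
  lin_sense <- logical(0)
  if (nrow(lin) > 0 && n_tx > 0) {
    set.seed(seed)
    tx <- anno[sample.int(length(anno), n_tx)]
    lgr <- GenomicRanges::GRanges(lin$ref,
                                  IRanges::IRanges(lin$ref_start + 1L,
                                                   lin$ref_end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(lgr, tx, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(ov)
    first <- !duplicated(qh)
    tx_strand <- as.character(GenomicRanges::strand(tx))
    lin_sense <- lin$orientation[qh[first]] ==
      tx_strand[S4Vectors::subjectHits(ov)[first]]
  }
  list(circ_sense_fraction = if (length(sense)) mean(sense) else NA_real_,
       linear_sense_fraction = if (length(lin_sense)) mean(lin_sense) else NA_real_,
       n_circ_reads = length(sense),
       n_linear_reads = length(lin_sense),
       n_linear_transcripts_sampled = n_tx,
       n_excluded_no_parent = n_excluded)
}

#' Background splice-junction sequences from annotated exons
#'
#' For every pair of adjacent exons of a multi-exon transcript, concatenates
#' the last \code{flank} bases of the upstream exon with the first
#' \code{flank} bases of the downstream exon (in transcript orientation),
#' yielding linear splice-junction sequences that mimic junction-spanning
#' reads; used as a stringent motif-search background.  Exons shorter than
#' \code{flank} contribute their full length.
#'
#' @param exons data.frame with \code{transcript_id, chrom, start, end,
#'   strand} (0-based half-open); exons of a transcript are ordered 5' to 3'
#'   by genomic coordinate and strand.
#' @param genome Named character vector (see [read_genome()]).
#' @param flank Bases taken from each exon side (default 15).
#' @return Named character vector of junction sequences
#'   (\code{<transcript_id>_j<i>}).
#' @export
build_background_junctions <- function(exons, genome, flank = 15L) {
  out <- character()
  for (tx in split(exons, exons$transcript_id)) {
    if (nrow(tx) < 2) next
    minus <- tx$strand[1] == "-"
    tx <- tx[order(tx$start, decreasing = minus), , drop = FALSE]
    chrom <- genome[[tx$chrom[1]]]
    for (i in seq_len(nrow(tx) - 1L)) {
      up <- tx[i, ]; dn <- tx[i + 1L, ]
      ku <- min(flank, up$end - up$start)
      kd <- min(flank, dn$end - dn$start)
      if (!minus) {
        s <- paste0(subseq0(chrom, up$end - ku, up$end),
                    subseq0(chrom, dn$start, dn$start + kd))
      } else {
        s <- paste0(revcomp(subseq0(chrom, up$start, up$start + ku)),
                    revcomp(subseq0(chrom, dn$end - kd, dn$end)))
      }
      out[[paste0(tx$transcript_id[1], "_j", i)]] <- toupper(s)
    }
  }
  out
}

#' Foreground sequences for motif search
#'
#' For each candidate circRNA, extracts the junction-contig subsequence(s)
#' covered by the union footprint of its supporting reads, one FASTA record
#' per contiguous covered block.
#'
#' @param candidates Candidate table (needs \code{rbp_condition},
#'   \code{circ_id}).
#' @param pooled Pooled supporting reads from [pool_assignments()].
#' @param contigs Named character vector of junction-contig sequences.
#' @param manifest Junction manifest mapping circ_id to contig.
#' @return Named character vector of covered subsequences
#'   (\code{<circ_id>|<start>-<end>}).
#' @export
export_motif_foreground <- function(candidates, pooled, contigs, manifest) {
  out <- character()
  contig_of <- stats::setNames(manifest$contig, manifest$circ_id)
  for (i in seq_len(nrow(candidates))) {
    ci <- candidates$circ_id[i]
    g <- pooled[pooled$circ_id == ci &
                  pooled$rbp_condition == candidates$rbp_condition[i], ,
                drop = FALSE]
    if (nrow(g) == 0) next
    r <- IRanges::reduce(IRanges::IRanges(g$ref_start + 1L, g$ref_end))
    seq <- contigs[[contig_of[[ci]]]]
    for (j in seq_along(r)) {
      s0 <- IRanges::start(r)[j] - 1L
      e0 <- IRanges::end(r)[j]
      out[[paste0(ci, "|", s0, "-", e0)]] <- subseq0(seq, s0, e0)
    }
  }
  out
}

#' Binary RBP x circRNA binding-profile matrix
#'
#' Builds the bound/unbound matrix over all circRNA species observed across
#' RBPs and removes the \code{drop_top_n} most promiscuously bound species
#' (bound by the most RBPs; ties broken by circ_id) — the most frequent
#' species tend to be non-specific targets that also show up in IgG
#' controls.  RBPs left without any bound species are dropped with a warning.
#'
#' @param candidates_by_rbp Named list: for each RBP, a candidate table (or a
#'   character vector of bound circ_ids).
#' @param drop_top_n Number of most-frequent species to discard (default 50).
#' @return List with \code{matrix} (binary, rows = RBPs), \code{dropped_circ}
#'   (pruned species), and \code{dropped_rbps}.
#' @export
binding_profile <- function(candidates_by_rbp, drop_top_n = 50L) {
  stopifnot(length(candidates_by_rbp) >= 2)
  sets <- lapply(candidates_by_rbp, function(x)
    unique(if (is.character(x)) x else x$circ_id))
  species <- sort(unique(unlist(sets)))
  if (length(species) <= drop_top_n)
    stop("only ", length(species), " circRNA species observed; ",
         "drop_top_n = ", drop_top_n, " would remove them all — ",
         "use a smaller drop_top_n")
  mat <- t(vapply(sets, function(s) as.integer(species %in% s),
                  integer(length(species))))
  colnames(mat) <- species
  freq <- colSums(mat)
  dropped <- character()
  if (drop_top_n > 0) {
    ord <- order(-freq, species)
    dropped <- species[ord[seq_len(drop_top_n)]]
    mat <- mat[, !colnames(mat) %in% dropped, drop = FALSE]
  }
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    warning("RBP(s) without bound species after pruning dropped: ",
            paste(rownames(mat)[zero], collapse = ", "))
    mat <- mat[!zero, , drop = FALSE]
  }
  list(matrix = mat, dropped_circ = dropped,
       dropped_rbps = names(zero)[zero])
}

#' Pairwise RBP distance matrix from binding profiles
#'
#' Distance between two RBPs is the upper-tail hypergeometric p-value of the
#' overlap of their bound circRNA sets within the universe of all species in
#' the matrix: similar profiles give small p (close), unrelated profiles give
#' p near 1 (distant).  Diagonal is 0.
#'
#' @param profile List from [binding_profile()] or a binary matrix.
#' @return Symmetric numeric matrix of p-value distances.
#' @export
rbp_distance_matrix <- function(profile) {
  mat <- if (is.list(profile)) profile$matrix else profile
  stopifnot(nrow(mat) >= 2)
  N <- ncol(mat)
  r <- nrow(mat)
  d <- matrix(0, r, r, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      k <- sum(mat[i, ] & mat[j, ])
      d[i, j] <- d[j, i] <- hypergeom_tail(k, sum(mat[i, ]), sum(mat[j, ]), N)
    }
  }
  d
}

#' Hierarchical clustering of RBPs
#'
#' Agglomerative clustering on a p-value distance matrix.
#'
#' @param distmat Square symmetric matrix with zero diagonal.
#' @param linkage_method Linkage passed to [stats::hclust()] (default
#'   "average").
#' @return List with \code{hclust} (the tree), \code{newick} (newick string
#'   with branch lengths), and \code{merge} (the merge table).
#' @export
hierarchical_cluster <- function(distmat, linkage_method = "average") {
  if (!isSymmetric(unname(as.matrix(distmat))))
    stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(distmat), method = linkage_method)
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)),
       merge = hc$merge)
}

#' Read a GMT gene-set file
#' @param path GMT path (one named gene set per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Randomization-corrected gene-set enrichment of parental genes
#'
#' Tests, per RBP, whether the parental genes of its bound circRNAs are
#' over-represented in each gene set, with an empirical background
#' correction: for each RBP, \code{n_rand} same-size random gene sets are
#' drawn from the universe and the mean log10 background p-value per term is
#' subtracted from the true log10 p-value.  Only RBPs with at least
#' \code{min_parental_genes} distinct parental genes and terms with at least
#' \code{min_term_genes} genes are tested.  Significance is Bonferroni on the
#' uncorrected true p-values across all tested (RBP, term) pairs.
#'
#' @param parental_sets Named list: per RBP, character vector of parental
#'   gene ids.
#' @param gmt Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of all genes considered.
#' @param n_rand Number of background randomizations (default 10).
#' @param min_term_genes Minimum term size (default 10).
#' @param min_parental_genes Minimum distinct parental genes per RBP
#'   (default 101, i.e. more than 100).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Master seed; per-RBP-per-replicate substreams are derived so
#'   results do not depend on evaluation order.
#' @return data.frame with one row per tested (RBP, term): \code{rbp,
#'   term_id, k_overlap, term_size, gene_set_size, universe_size, p_true,
#'   log_p_true, mean_log_p_background, corrected_score, significant}.
#' @export
go_enrichment <- function(parental_sets, gmt, universe, n_rand = 10L,
                          min_term_genes = 10L, min_parental_genes = 101L,
                          alpha = 0.05, seed = 1L) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty gene universe")
  terms <- lapply(gmt, function(g) intersect(unique(g), universe))
  n_lost <- sum(lengths(gmt) - lengths(terms))
  if (n_lost > 0)
    warning(n_lost, " term gene(s) outside the universe dropped")
  terms <- terms[lengths(terms) >= min_term_genes]
  sets <- lapply(parental_sets, function(g) intersect(unique(g), universe))
  sets <- sets[lengths(sets) >= min_parental_genes]
  if (length(terms) == 0 || length(sets) == 0)
    return(data.frame(rbp = character(), term_id = character(),
                      k_overlap = integer(), term_size = integer(),
                      gene_set_size = integer(), universe_size = integer(),
                      p_true = numeric(), log_p_true = numeric(),
                      mean_log_p_background = numeric(),
                      corrected_score = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  term_idx <- lapply(terms, function(g) match(g, universe))
  K <- lengths(terms)
  overlap_counts <- function(gene_set) {
    memb <- logical(N)
    memb[match(gene_set, universe)] <- TRUE
    vapply(term_idx, function(ix) sum(memb[ix]), integer(1))
  }
  n_tests <- length(sets) * length(terms)
  ## stable per-RBP hash so backgrounds do not depend on list order
  name_hash <- function(x) {
    h <- 0L
    for (ch in utf8ToInt(x)) h <- (h * 31L + ch) %% 30269L
    h
  }
  res <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    n <- length(s)
    k <- overlap_counts(s)
    log_p_true <- hypergeom_tail(k, K, n, N, log10p = TRUE)
    hh <- name_hash(names(sets)[i])
    bg <- matrix(NA_real_, n_rand, length(terms))
    for (r in seq_len(n_rand)) {
      set.seed((as.integer(seed) * 10007L + hh * 1009L + r) %% 2147483647L)
      rnd <- universe[sample.int(N, n)]
      bg[r, ] <- hypergeom_tail(overlap_counts(rnd), K, n, N, log10p = TRUE)
    }
    mean_bg <- colMeans(bg)
    res[[i]] <- data.frame(
      rbp = names(sets)[i], term_id = names(terms),
      k_overlap = k, term_size = K, gene_set_size = n, universe_size = N,
      p_true = 10^log_p_true, log_p_true = log_p_true,
      mean_log_p_background = mean_bg,
      corrected_score = log_p_true - mean_bg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$p_true <= alpha / n_tests
  out
}
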