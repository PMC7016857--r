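## Competitive classification of aligned tags.
##
## Tags are aligned simultaneously to the junction contigs and the normal
## genome.  A junction hit is only believed when the alignment crosses the
## back-splice seam with more than 5 aligned bases on both sides and a
## per-side mismatch rate below 0.15.  Tags with any genome hit, or valid
## hits to more than one circRNA, are discarded as evidence.

#' Mismatch profile of one alignment from CIGAR + MD
#'
#' Walks the CIGAR and MD strings of an ungapped-or-gapped SAM record and
#' returns the aligned reference span length together with the 0-based
#' reference offsets (relative to the alignment start) that count as
#' mismatches.  Conventions: MD substitutions are mismatches; deleted
#' reference bases count as mismatches; insertions contribute neither span
#' nor mismatches; soft/hard-clipped bases are excluded entirely.
#'
#' @param cigar CIGAR string.
#' @param md MD tag value, or \code{NA} to recompute from \code{seq} and
#'   \code{ref_seq}.
#' @param seq Read sequence as aligned (needed only for the MD-less
#'   fallback).
#' @param ref_seq Reference sequence of the aligned span (needed only for the
#'   MD-less fallback).
#' @return List with \code{span} (aligned reference length) and
#'   \code{mm_offsets} (integer vector of mismatch offsets in \[0, span)).
#' @export
mismatch_profile <- function(cigar, md = NA, seq = NULL, ref_seq = NULL) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(ops) != length(ops_len) || length(ops) == 0)
    stop("unparseable CIGAR: ", cigar)
  if (any(!ops %in% c("M", "=", "X", "I", "D", "S", "H")))
    stop("unsupported CIGAR operation in ", cigar)
  span <- sum(ops_len[ops %in% c("M", "=", "X", "D")])
  if (!is.na(md)) {
    ## MD covers exactly the ref-consuming bases of the alignment
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
    off <- 0L
    mm <- integer()
    for (t in toks) {
      if (grepl("^[0-9]+$", t)) {
        off <- off + as.integer(t)
      } else if (startsWith(t, "^")) {
        del <- nchar(t) - 1L
        mm <- c(mm, off + seq_len(del) - 1L)
        off <- off + del
      } else {
        mm <- c(mm, off)
        off <- off + 1L
      }
    }
    if (off != span)
      stop("MD tag (", md, ") inconsistent with CIGAR (", cigar, ")")
    return(list(span = span, mm_offsets = mm))
  }
  if (is.null(seq) || is.null(ref_seq))
    stop("no MD tag and no reference sequence to recompute mismatches")
  rch <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1]]
  qch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  qi <- 0L; ri <- 0L
  mm <- integer()
  for (i in seq_along(ops)) {
    n <- ops_len[i]
    op <- ops[i]
    if (op %in% c("M", "=", "X")) {
      idx <- seq_len(n)
      bad <- rch[ri + idx] != qch[qi + idx]
      mm <- c(mm, ri + idx[bad] - 1L)
      ri <- ri + n; qi <- qi + n
    } else if (op == "D") {
      mm <- c(mm, ri + seq_len(n) - 1L)
      ri <- ri + n
    } else if (op %in% c("I", "S")) {
      qi <- qi + n
    } ## H consumes nothing
  }
  list(span = span, mm_offsets = mm)
}

#' Parse SAM alignments against the combined reference
#'
#' Reads a SAM (or BAM) file of alignments to the combined junction + genome
#' reference and returns one row per mapped record (secondary and
#' supplementary records retained as distinct hits).  Mismatch profiles come
#' from CIGAR + MD, with a fallback recomputation against \code{refs} when MD
#' is absent.
#'
#' @param sam Path to a SAM or BAM file.
#' @param manifest Junction manifest (see [build_combined_reference()]).
#' @param refs Optional named character vector of reference sequences for the
#'   MD-less fallback.
#' @return data.frame with \code{tag_id}, \code{ref}, \code{ref_start}
#'   (0-based), \code{ref_end} (exclusive), \code{orientation} ('+'/'-'),
#'   \code{n_mm}, \code{is_junction_ref}, and list-column \code{mm_offsets};
#'   attribute \code{all_tags} lists every read name seen (mapped or not).
#' @export
parse_alignments <- function(sam, manifest, refs = NULL) {
  bam <- sam
  if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(hdr), c(manifest$contig, if (!is.null(refs)) names(refs)))
  ## with no genome given, non-contig header names are assumed genomic
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "MD")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  all_tags <- unique(res$qname)
  mapped <- !bitwAnd(res$flag, 4L)
  n <- sum(mapped)
  out <- data.frame(tag_id = res$qname[mapped],
                    ref = as.character(res$rname[mapped]),
                    ref_start = res$pos[mapped] - 1L,
                    ref_end = NA_integer_,
                    orientation = ifelse(bitwAnd(res$flag[mapped], 16L), "-", "+"),
                    n_mm = NA_integer_,
                    is_junction_ref = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(refs) || nrow(manifest) > 0) {
    bad <- setdiff(unique(out$ref), c(manifest$contig,
                                      if (!is.null(refs)) names(refs) else setdiff(names(hdr), manifest$contig)))
    if (length(bad))
      stop("SAM reference name(s) absent from genome and manifest: ",
           paste(bad, collapse = ", "))
  }
  out$is_junction_ref <- out$ref %in% manifest$contig
  cig <- res$cigar[mapped]
  md <- res$tag$MD[mapped]
  if (is.null(md)) md <- rep(NA_character_, n)
  seqs <- as.character(res$seq)[mapped]
  mm_offsets <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- NULL
    if (is.na(md[i])) {
      if (is.null(refs))
        stop("record ", out$tag_id[i],
             " has no MD tag and no reference sequences were supplied")
      ## need the span first; compute from CIGAR ops
      ops_len <- as.integer(regmatches(cig[i], gregexpr("[0-9]+", cig[i]))[[1]])
      ops <- regmatches(cig[i], gregexpr("[A-Z=]", cig[i]))[[1]]
      span <- sum(ops_len[ops %in% c("M", "=", "X", "D")])
      rs <- subseq0(refs[[out$ref[i]]], out$ref_start[i], out$ref_start[i] + span)
    }
    prof <- mismatch_profile(cig[i], md[i], seq = seqs[i], ref_seq = rs)
    out$ref_end[i] <- out$ref_start[i] + prof$span
    out$n_mm[i] <- length(prof$mm_offsets)
    mm_offsets[[i]] <- prof$mm_offsets
  }
  out$mm_offsets <- mm_offsets
  attr(out, "all_tags") <- all_tags
  out
}

#' Per-side overhang statistics of a junction-contig hit
#'
#' Splits an alignment span on a junction contig at the back-splice seam
#' (reference position \code{junction_offset}) and reports the aligned length
#' and mismatch rate on each side.
#'
#' @param ref_start,ref_end 0-based half-open alignment span.
#' @param mm_offsets Mismatch offsets relative to \code{ref_start}.
#' @param junction_offset Number of donor-side bases on the contig.
#' @return List with \code{left_len}, \code{right_len}, \code{left_mm_rate},
#'   \code{right_mm_rate} (a degenerate zero-length side has rate 0).
#' @export
overhang_stats <- function(ref_start, ref_end, mm_offsets, junction_offset) {
  left_len <- max(0L, min(ref_end, junction_offset) - ref_start)
  right_len <- max(0L, ref_end - max(ref_start, junction_offset))
  abs_pos <- ref_start + mm_offsets
  left_mm <- sum(abs_pos < junction_offset)
  right_mm <- length(abs_pos) - left_mm
  list(left_len = left_len, right_len = right_len,
       left_mm_rate = if (left_len > 0) left_mm / left_len else 0,
       right_mm_rate = if (right_len > 0) right_mm / right_len else 0)
}

#' Does an alignment qualify as junction-spanning?
#'
#' True when the alignment extends at least \code{min_overhang} reference
#' bases on both sides of the seam and the mismatch rate on each side is
#' strictly below \code{max_mm_rate}.  The defaults encode "more than 5
#' aligned bases" (so >= 6) and a strict 0.15 rate cutoff.
#'
#' @param stats List from [overhang_stats()].
#' @param min_overhang Minimum aligned bases per side (default 6).
#' @param max_mm_rate Strict upper bound on the per-side mismatch rate
#'   (default 0.15).
#' @return Logical scalar.
#' @export
is_junction_spanning <- function(stats, min_overhang = 6L, max_mm_rate = 0.15) {
  stats$left_len >= min_overhang && stats$right_len >= min_overhang &&
    stats$left_mm_rate < max_mm_rate && stats$right_mm_rate < max_mm_rate
}

## pick index of best hit: fewest mismatches, tie -> leftmost start, tie -> first
best_hit_idx <- function(h) {
  ord <- order(h$n_mm, h$ref_start)
  ord[1]
}

#' Competitively assign tags to circRNAs
#'
#' Applies the competitive classification rules per tag: genome hits and no
#' valid junction hit give LINEAR; a genome hit together with any valid
#' junction hit gives CIRC_AND_LINEAR (discarded); valid junction hits to
#' more than one circRNA give AMBIGUOUS_MULTI_CIRC (discarded); exactly one
#' circRNA with at least one valid junction hit and no genome hit gives CIRC;
#' junction hits none of which span validly give NONSPANNING; no hits at all
#' give UNALIGNED.  Multiple valid hits to the same circRNA count once; the
#' reported hit is the one with fewest mismatches (tie: leftmost).
#'
#' @param hits data.frame from [parse_alignments()].
#' @param manifest Junction manifest.
#' @param min_overhang,max_mm_rate Junction-spanning thresholds
#'   (see [is_junction_spanning()]).
#' @param sense_only If \code{TRUE}, only forward-orientation junction hits
#'   are accepted as valid (antisense binding excluded).
#' @param all_tags Optional character vector of every tag id (tags without
#'   any hit are reported UNALIGNED); defaults to
#'   \code{attr(hits, "all_tags")} or the tags present in \code{hits}.
#' @return data.frame with one row per tag: \code{tag_id}, \code{status},
#'   \code{circ_id} (NA unless CIRC), \code{ref}, \code{ref_start},
#'   \code{ref_end}, \code{orientation} of the winning hit (junction hit for
#'   CIRC, genome hit for LINEAR; NA otherwise).
#' @export
assign_reads <- function(hits, manifest, min_overhang = 6L, max_mm_rate = 0.15,
                         sense_only = FALSE, all_tags = NULL) {
  if (is.null(all_tags)) all_tags <- attr(hits, "all_tags") %||% unique(hits$tag_id)
  joff <- stats::setNames(manifest$junction_offset, manifest$contig)
  circ_of <- stats::setNames(manifest$circ_id, manifest$contig)
  n <- length(all_tags)
  status <- character(n); circ_id <- rep(NA_character_, n)
  ref <- rep(NA_character_, n); ref_start <- rep(NA_integer_, n)
  ref_end <- rep(NA_integer_, n); orientation <- rep(NA_character_, n)
  idx_by_tag <- split(seq_len(nrow(hits)), hits$tag_id)
  take_hit <- function(t, h) {
    i <- best_hit_idx(h)
    ref[t] <<- h$ref[i]; ref_start[t] <<- h$ref_start[i]
    ref_end[t] <<- h$ref_end[i]; orientation[t] <<- h$orientation[i]
  }
  for (t in seq_len(n)) {
    idx <- idx_by_tag[[all_tags[[t]]]]
    if (is.null(idx)) { status[t] <- "UNALIGNED"; next }
    h <- hits[idx, , drop = FALSE]
    is_j <- h$is_junction_ref
    genome <- h[!is_j, , drop = FALSE]
    junc <- h[is_j, , drop = FALSE]
    valid <- logical(nrow(junc))
    for (i in seq_len(nrow(junc))) {
      st <- overhang_stats(junc$ref_start[i], junc$ref_end[i],
                           junc$mm_offsets[[i]], joff[[junc$ref[i]]])
      valid[i] <- is_junction_spanning(st, min_overhang, max_mm_rate) &&
        (!sense_only || junc$orientation[i] == "+")
    }
    vj <- junc[valid, , drop = FALSE]
    n_circ <- length(unique(circ_of[vj$ref]))
    if (nrow(genome) > 0 && n_circ == 0) {
      status[t] <- "LINEAR"; take_hit(t, genome)
    } else if (nrow(genome) > 0 && n_circ >= 1) {
      status[t] <- "CIRC_AND_LINEAR"
    } else if (n_circ > 1) {
      status[t] <- "AMBIGUOUS_MULTI_CIRC"
    } else if (n_circ == 1) {
      i <- best_hit_idx(vj)
      status[t] <- "CIRC"; circ_id[t] <- unname(circ_of[[vj$ref[i]]])
      take_hit(t, vj)
    } else if (nrow(junc) > 0) {
      status[t] <- "NONSPANNING"
    } else {
      status[t] <- "UNALIGNED"
    }
  }
  data.frame(tag_id = all_tags, status = status, circ_id = circ_id,
             ref = ref, ref_start = ref_start, ref_end = ref_end,
             orientation = orientation, stringsAsFactors = FALSE)
}
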