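## CLIP-Seq read preprocessing: adapter trimming, length filtering, and
## collapsing of identical sequences into unique tags.  CLIP libraries have
## limited complexity and high PCR duplication; identical sequences are
## treated as one observation downstream.

#' Trim a 3' adapter from read sequences
#'
#' Scans each read left to right for the leftmost position where the read's
#' remaining suffix matches a prefix of the adapter (a suffix-prefix overlap,
#' or a full internal adapter occurrence) with overlap >= \code{min_overlap}
#' and mismatch rate <= \code{max_mm_rate}, and truncates the read before
#' that position.  Reads without a qualifying match are returned unchanged.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum read/adapter overlap length (default 5).
#' @param max_mm_rate Maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 5L, max_mm_rate = 0.1) {
  stopifnot(nzchar(adapter), min_overlap >= 1)
  ad <- strsplit(toupper(adapter), "", fixed = TRUE)[[1]]
  la <- length(ad)
  vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L < min_overlap) return(s)
    for (p in seq_len(L - min_overlap + 1L)) {
      ovl <- min(L - p + 1L, la)
      mm <- sum(ch[p:(p + ovl - 1L)] != ad[seq_len(ovl)])
      if (mm <= max_mm_rate * ovl) return(substr(s, 1L, p - 1L))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse identical read sequences into unique tags
#'
#' @param seqs Character vector of read sequences.
#' @param sample Sample label recorded on each tag.
#' @return data.frame with \code{tag_id}, \code{seq}, \code{multiplicity}
#'   (number of raw reads collapsed) and \code{sample}; the sum of
#'   multiplicities equals \code{length(seqs)}.
#' @export
collapse_duplicates <- function(seqs, sample = "sample1") {
  if (length(seqs) == 0)
    return(data.frame(tag_id = character(), seq = character(),
                      multiplicity = integer(), sample = character(),
                      stringsAsFactors = FALSE))
  tab <- table(factor(seqs, levels = unique(seqs)))  # first-seen order
  data.frame(
    tag_id = paste0("tag_", seq_along(tab), "_x", as.integer(tab)),
    seq = names(tab),
    multiplicity = as.integer(tab),
    sample = sample,
    stringsAsFactors = FALSE)
}

#' Remove tags shorter than a minimum length
#'
#' @param tags data.frame from [collapse_duplicates()].
#' @param min_read_len Minimum sequence length kept (default 18).
#' @return List with \code{kept} and \code{discarded} tag data.frames plus
#'   counts \code{n_discarded_tags} and \code{n_discarded_reads} (raw reads,
#'   i.e. summed multiplicities).
#' @export
length_filter <- function(tags, min_read_len = 18L) {
  stopifnot(min_read_len >= 1)
  short <- nchar(tags$seq) < min_read_len
  list(kept = tags[!short, , drop = FALSE],
       discarded = tags[short, , drop = FALSE],
       n_discarded_tags = sum(short),
       n_discarded_reads = sum(tags$multiplicity[short]))
}

#' Preprocess a CLIP-Seq FASTQ into unique tags
#'
#' Convenience wrapper: read FASTQ, optionally trim the 3' adapter, collapse
#' identical sequences to unique tags, and drop tags shorter than
#' \code{min_read_len}.  Base qualities are not used.
#'
#' @param fastq Path to a FASTQ file (gz-transparent).
#' @param adapter Optional adapter sequence; \code{NULL} skips trimming.
#' @param min_read_len Minimum post-trim length (default 18).
#' @param sample Sample label.
#' @param min_overlap,max_mm_rate Passed to [trim_adapter()].
#' @param out Optional path: kept tags written as FASTA with headers
#'   \code{tag_<k>_x<multiplicity>}.
#' @return List with \code{tags} (kept), \code{discarded},
#'   \code{n_raw_reads}, \code{n_discarded_tags}, \code{n_discarded_reads}.
#' @export
preprocess_fastq <- function(fastq, adapter = NULL, min_read_len = 18L,
                             sample = basename(fastq), min_overlap = 5L,
                             max_mm_rate = 0.1, out = NULL) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  if (!is.null(adapter))
    reads <- trim_adapter(reads, adapter, min_overlap, max_mm_rate)
  tags <- collapse_duplicates(reads, sample = sample)
  lf <- length_filter(tags, min_read_len)
  if (!is.null(out) && nrow(lf$kept) > 0) {
    seqs <- lf$kept$seq
    names(seqs) <- lf$kept$tag_id
    write_fasta(seqs, out)
  }
  list(tags = lf$kept, discarded = lf$discarded,
       n_raw_reads = length(reads),
       n_discarded_tags = lf$n_discarded_tags,
       n_discarded_reads = lf$n_discarded_reads)
}
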