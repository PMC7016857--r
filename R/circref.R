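## Junction pseudo-reference construction.
##
## Each circRNA is represented by an artificial "junction contig": the last k
## bases of the (strand-oriented) circRNA sequence concatenated with its first
## k bases, k = min(50, circRNA length).  A read aligning contiguously across
## the seam of that contig is evidence of the back-splice junction.

#' Load and deduplicate circRNA coordinate sets
#'
#' Reads one or more BED6-style files of circRNA coordinates and pools them
#' into a single deduplicated set.  Records identical in
#' (chrom, start, end, strand) collapse to one record whose \code{source}
#' concatenates the contributing file labels.  Identical spans on opposite
#' strands are distinct circRNAs.
#'
#' @param paths Character vector of BED-like file paths (tab-separated;
#'   chrom, start, end, name, score, strand; the name column supplies
#'   \code{circ_id}, generated when absent).
#' @param one_based Logical; if \code{TRUE} input coordinates are 1-based
#'   inclusive and are converted to the internal 0-based half-open convention.
#' @param min_circ_len Minimum circRNA length; shorter records are rejected
#'   with a warning (too short to ever carry the required junction overhangs).
#' @return A \code{data.frame} with columns \code{chrom, start, end, strand,
#'   circ_id, source} (0-based half-open coordinates) and attribute
#'   \code{n_rejected}.
#' @export
load_circrna_set <- function(paths, one_based = FALSE, min_circ_len = 12L) {
  stopifnot(length(paths) >= 1)
  rows <- list()
  n_rejected <- 0L
  for (p in paths) {
    lab <- basename(p)
    lines <- readLines(p)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    if (length(lines) == 0) next
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 4)
        stop("malformed line in ", p, " (line ", i, "): fewer than 4 columns")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end))
        stop("malformed line in ", p, " (line ", i, "): non-numeric coordinates")
      strand <- if (length(f) >= 6) f[6] else f[4]
      if (!strand %in% c("+", "-"))
        stop("malformed line in ", p, " (line ", i, "): strand must be '+' or '-'")
      name <- if (length(f) >= 6) f[4] else paste0(f[1], ":", f[2], "-", f[3], ":", strand)
      if (one_based) start <- start - 1L
      if (start >= end || start < 0L || (end - start) < min_circ_len) {
        n_rejected <- n_rejected + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[1], start = start, end = end, strand = strand,
        circ_id = name, source = lab, stringsAsFactors = FALSE)
    }
  }
  if (n_rejected > 0)
    warning(n_rejected, " record(s) rejected (invalid or < ", min_circ_len, " nt)")
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), circ_id = character(),
                      source = character(), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  df <- do.call(rbind, rows)
  key <- paste(df$chrom, df$start, df$end, df$strand, sep = "\r")
  src <- tapply(df$source, key, function(s) paste(unique(s), collapse = ","))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$source <- as.character(src[paste(out$chrom, out$start, out$end,
                                       out$strand, sep = "\r")])
  ## circ_id must be unique after dedup; disambiguate clashes across distinct spans
  dup <- duplicated(out$circ_id)
  if (any(dup))
    out$circ_id[dup] <- paste0(out$circ_id[dup], "_",
                               cumsum(dup)[dup] + 1L)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Masked (low-complexity) fraction of a sequence
#'
#' Fraction of bases that are soft-masked (lowercase) or ambiguous (N/n).
#' Low-complexity and repetitive content is taken from the genome's
#' soft-masking; circRNAs dominated by such content are excluded from the
#' junction library because alignments there are unreliable.
#'
#' @param seq Non-empty nucleotide string(s).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
masked_fraction <- function(seq) {
  if (any(!nzchar(seq)) || length(seq) == 0)
    stop("masked_fraction: empty sequence")
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(ch %in% c(letters, "N")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Canonical junction-contig name for a circRNA record
#' @param circ One-row data.frame with chrom, start, end, strand, circ_id.
#' @return Character contig name, collision-proof and self-describing.
#' @export
contig_name <- function(circ) {
  paste0("circ|", circ$circ_id, "|", circ$chrom, ":", circ$start, "-",
         circ$end, ":", circ$strand)
}

#' Build the linearized junction contig for one circRNA
#'
#' Extracts the last k bases of the strand-oriented circRNA sequence followed
#' by its first k bases, k = min(50, length).  A read crossing position k of
#' the contig therefore crosses the back-splice junction.  For minus-strand
#' circRNAs the oriented sequence is the reverse complement of the genomic
#' span.
#'
#' @param circ One-row data.frame (chrom, start, end, strand, circ_id).
#' @param genome Named character vector of chromosome sequences
#'   (see [read_genome()]).
#' @param flank Maximum bases taken from each side of the junction (default
#'   50).
#' @return List with \code{name}, \code{seq} (uppercase), and
#'   \code{junction_offset} (= k, the number of donor-side bases).
#' @export
build_junction_contig <- function(circ, genome, flank = 50L) {
  if (!circ$chrom %in% names(genome))
    stop("chromosome ", circ$chrom, " absent from genome")
  chrom_seq <- genome[[circ$chrom]]
  L <- circ$end - circ$start
  if (circ$end > nchar(chrom_seq) || circ$start < 0)
    stop("circRNA ", circ$circ_id, " out of chromosome bounds")
  k <- min(flank, L)
  if (circ$strand == "+") {
    left <- subseq0(chrom_seq, circ$end - k, circ$end)      # last k of circ
    right <- subseq0(chrom_seq, circ$start, circ$start + k) # first k of circ
  } else {
    left <- revcomp(subseq0(chrom_seq, circ$start, circ$start + k))
    right <- revcomp(subseq0(chrom_seq, circ$end - k, circ$end))
  }
  list(name = contig_name(circ), seq = toupper(paste0(left, right)),
       junction_offset = k)
}

#' Build the combined junction + genome reference
#'
#' Screens circRNAs by masked fraction over their full genomic span, builds a
#' junction contig per survivor, and writes the combined FASTA (genome
#' chromosomes followed by junction contigs, uppercased) together with a
#' manifest TSV mapping contig names to circRNA coordinates and junction
#' offsets.
#'
#' @param circ_set data.frame from [load_circrna_set()].
#' @param genome Named character vector (see [read_genome()]).
#' @param max_masked_frac circRNAs whose full-span masked fraction exceeds
#'   this are excluded (default 0.5).
#' @param out_prefix Optional path prefix; when given, writes
#'   \code{<prefix>.fa}, \code{<prefix>.manifest.tsv} and
#'   \code{<prefix>.excluded.tsv}.
#' @param flank Per-side junction flank (default 50).
#' @return List with \code{contigs} (named character vector),
#'   \code{manifest} (data.frame: contig, circ_id, chrom, start, end, strand,
#'   junction_offset), \code{excluded} (data.frame of excluded circ_ids with
#'   reasons), and the output \code{paths} when written.
#' @export
build_combined_reference <- function(circ_set, genome, max_masked_frac = 0.5,
                                     out_prefix = NULL, flank = 50L) {
  stopifnot(max_masked_frac > 0, max_masked_frac <= 1)
  contigs <- character()
  man <- list()
  excl <- list()
  if (nrow(circ_set) > 0) {
    for (i in seq_len(nrow(circ_set))) {
      circ <- circ_set[i, ]
      if (!circ$chrom %in% names(genome))
        stop("chromosome ", circ$chrom, " absent from genome")
      span <- subseq0(genome[[circ$chrom]], circ$start, circ$end)
      mf <- masked_fraction(span)
      if (mf > max_masked_frac) {
        excl[[length(excl) + 1L]] <- data.frame(
          circ_id = circ$circ_id, reason = "masked_fraction",
          value = mf, stringsAsFactors = FALSE)
        next
      }
      jc <- build_junction_contig(circ, genome, flank = flank)
      if (jc$name %in% names(contigs)) stop("duplicate contig name: ", jc$name)
      contigs[[jc$name]] <- jc$seq
      man[[length(man) + 1L]] <- data.frame(
        contig = jc$name, circ_id = circ$circ_id, chrom = circ$chrom,
        start = circ$start, end = circ$end, strand = circ$strand,
        junction_offset = jc$junction_offset, stringsAsFactors = FALSE)
    }
  }
  if (any(names(contigs) %in% names(genome)))
    stop("junction contig name collides with a genome chromosome name")
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(contig = character(), circ_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), junction_offset = integer(),
               stringsAsFactors = FALSE)
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(circ_id = character(), reason = character(), value = numeric(),
               stringsAsFactors = FALSE)
  paths <- NULL
  if (!is.null(out_prefix)) {
    fa <- paste0(out_prefix, ".fa")
    write_fasta(vapply(genome, toupper, character(1)), fa)
    if (length(contigs)) write_fasta(contigs, fa, append = TRUE)
    mtsv <- paste0(out_prefix, ".manifest.tsv")
    utils::write.table(manifest, mtsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    etsv <- paste0(out_prefix, ".excluded.tsv")
    utils::write.table(excluded, etsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- list(fasta = fa, manifest = mtsv, excluded = etsv)
  }
  list(contigs = contigs, manifest = manifest, excluded = excluded,
       paths = paths)
}

#' Read a junction-reference manifest TSV
#' @param path Manifest path written by [build_combined_reference()].
#' @return data.frame with contig, circ_id, chrom, start, end, strand,
#'   junction_offset.
#' @export
read_manifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer", "integer", "character",
                                   "integer"))
}
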