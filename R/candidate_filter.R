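## Candidate calling: pool junction-supporting tags per circRNA per
## RBP/condition and apply three filters — a minimum number of supporting
## tags, a minimum covered footprint on the junction contig, and positional
## diversity of alignment starts/ends (guards against residual PCR stacks).

#' Pool CIRC assignments by circRNA and RBP/condition
#'
#' Merges CIRC-status assignments from all samples belonging to the same
#' RBP/condition into per-circRNA read groups.
#'
#' @param assignments data.frame from [assign_reads()] with an added
#'   \code{sample} column (and optionally \code{multiplicity}).
#' @param sample_sheet data.frame with columns \code{sample} and
#'   \code{rbp_condition} (every sample must appear exactly once).
#' @return data.frame of pooled reads: \code{rbp_condition}, \code{circ_id},
#'   \code{tag_id}, \code{ref_start}, \code{ref_end}, \code{orientation},
#'   \code{multiplicity}.
#' @export
pool_assignments <- function(assignments, sample_sheet) {
  circ <- assignments[assignments$status == "CIRC", , drop = FALSE]
  if (!"multiplicity" %in% names(circ))
    circ[["multiplicity"]] <- rep(1L, nrow(circ))
  if (nrow(circ) == 0)
    return(data.frame(rbp_condition = character(), circ_id = character(),
                      tag_id = character(), ref_start = integer(),
                      ref_end = integer(), orientation = character(),
                      multiplicity = integer(), stringsAsFactors = FALSE))
  if (anyDuplicated(sample_sheet$sample))
    stop("duplicate sample label in sample sheet")
  cond <- stats::setNames(sample_sheet$rbp_condition, sample_sheet$sample)
  if (any(!circ$sample %in% names(cond)))
    stop("sample label(s) not in sample sheet: ",
         paste(setdiff(unique(circ$sample), names(cond)), collapse = ", "))
  data.frame(rbp_condition = unname(cond[circ$sample]),
             circ_id = circ$circ_id, tag_id = circ$tag_id,
             ref_start = circ$ref_start, ref_end = circ$ref_end,
             orientation = circ$orientation,
             multiplicity = circ$multiplicity, stringsAsFactors = FALSE)
}

#' Covered footprint of a set of reads on a junction contig
#'
#' Size (nt) of the union of half-open alignment intervals.
#'
#' @param starts,ends Integer vectors of 0-based half-open spans.
#' @return Integer: total covered bases.
#' @export
coverage_footprint <- function(starts, ends) {
  stopifnot(length(starts) == length(ends), length(starts) > 0)
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(r))
}

#' Positional diversity of a read group
#'
#' @param starts,ends Integer vectors of alignment starts/ends.
#' @return List with \code{n_unique_starts} and \code{n_unique_ends}.
#' @export
position_diversity <- function(starts, ends) {
  stopifnot(length(starts) > 0)
  list(n_unique_starts = length(unique(starts)),
       n_unique_ends = length(unique(ends)))
}

#' Call high-confidence RBP-bound circRNA candidates
#'
#' A pooled read group passes when (1) it has at least \code{min_reads}
#' supporting tags, (2) the union footprint of its alignments covers at least
#' \code{min_coverage} nt of the junction contig, and (3) the numbers of
#' unique alignment start and end positions are each at least
#' \code{diversity_frac} of the read count (evaluated as an exact rational
#' comparison, so 1 unique start among 3 reads passes at 1/3 but fails among
#' 4).  Read counts use collapsed unique tags by default; \code{count_raw}
#' counts raw multiplicities instead.
#'
#' @param pooled data.frame from [pool_assignments()].
#' @param min_reads Filter 1 threshold (default 2).
#' @param min_coverage Filter 2 threshold in nt (default 20).
#' @param diversity_frac Filter 3 fraction (default 1/3).
#' @param count_raw Count raw read multiplicities instead of unique tags.
#' @return List with \code{candidates} (data.frame: rbp_condition, circ_id,
#'   n_reads, covered_nt, n_unique_starts, n_unique_ends, sense_fraction,
#'   pass_min_reads, pass_coverage, pass_diversity) restricted to groups
#'   passing all three filters, \code{all_groups} (same columns, every
#'   group), and \code{report} (per-filter first-cause rejection counts).
#' @export
call_candidates <- function(pooled, min_reads = 2L, min_coverage = 20L,
                            diversity_frac = 1 / 3, count_raw = FALSE) {
  cols <- c("rbp_condition", "circ_id", "n_reads", "covered_nt",
            "n_unique_starts", "n_unique_ends", "sense_fraction",
            "pass_min_reads", "pass_coverage", "pass_diversity")
  if (nrow(pooled) == 0) {
    empty <- as.data.frame(stats::setNames(
      list(character(), character(), integer(), integer(), integer(),
           integer(), numeric(), logical(), logical(), logical()), cols),
      stringsAsFactors = FALSE)
    return(list(candidates = empty, all_groups = empty,
                report = data.frame(groups_in = 0L, rejected_min_reads = 0L,
                                    rejected_coverage = 0L,
                                    rejected_diversity = 0L,
                                    candidates_out = 0L)))
  }
  key <- paste(pooled$rbp_condition, pooled$circ_id, sep = "\r")
  groups <- split(pooled, key)
  rows <- lapply(groups, function(g) {
    ## one row per unique tag even if the aligner reported it twice
    g <- g[!duplicated(g$tag_id), , drop = FALSE]
    n <- if (count_raw) sum(g$multiplicity) else nrow(g)
    div <- position_diversity(g$ref_start, g$ref_end)
    data.frame(
      rbp_condition = g$rbp_condition[1], circ_id = g$circ_id[1],
      n_reads = n,
      covered_nt = coverage_footprint(g$ref_start, g$ref_end),
      n_unique_starts = div$n_unique_starts,
      n_unique_ends = div$n_unique_ends,
      sense_fraction = mean(g$orientation == "+"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$pass_min_reads <- tab$n_reads >= min_reads
  tab$pass_coverage <- tab$covered_nt >= min_coverage
  ## exact rational comparison: frac = p/q compared as q*n_unique >= p*n_reads
  fr <- .as_rational(diversity_frac)
  tab$pass_diversity <- (fr$q * tab$n_unique_starts >= fr$p * tab$n_reads) &
    (fr$q * tab$n_unique_ends >= fr$p * tab$n_reads)
  first_cause <- ifelse(!tab$pass_min_reads, "min_reads",
                 ifelse(!tab$pass_coverage, "coverage",
                 ifelse(!tab$pass_diversity, "diversity", "pass")))
  keep <- tab$pass_min_reads & tab$pass_coverage & tab$pass_diversity
  list(candidates = tab[keep, , drop = FALSE],
       all_groups = tab,
       report = data.frame(
         groups_in = nrow(tab),
         rejected_min_reads = sum(first_cause == "min_reads"),
         rejected_coverage = sum(first_cause == "coverage"),
         rejected_diversity = sum(first_cause == "diversity"),
         candidates_out = sum(keep)))
}

## small continued-fraction rationalization so thresholds like 1/3 are exact
.as_rational <- function(x, max_den = 1e6) {
  stopifnot(x >= 0, x <= 1)
  best <- c(p = round(x * max_den), q = max_den)
  for (q in 1:100) {
    p <- round(x * q)
    if (abs(p / q - x) < 1e-12) { best <- c(p = p, q = q); break }
  }
  list(p = unname(best["p"]), q = unname(best["q"]))
}

#' Subtract control-sample candidates
#'
#' Removes candidates whose circRNA also appears in a control run (for
#' example a matched non-poly-A RNA-Seq sample processed identically); an
#' explicit alternative to internal background modelling, which junction-read
#' counts are too sparse to support.
#'
#' @param candidates,control_candidates data.frames with a \code{circ_id}
#'   column.
#' @return \code{candidates} minus rows whose \code{circ_id} occurs in the
#'   control, with attribute \code{n_removed}.
#' @export
subtract_control <- function(candidates, control_candidates) {
  drop <- candidates$circ_id %in% control_candidates$circ_id
  out <- candidates[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}
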