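---
title: "Detecting RBP-bound circular RNAs from CLIP-Seq reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RBP-bound circular RNAs from CLIP-Seq reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlip)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice donor
joins an upstream acceptor, producing a covalently closed transcript. The
only read-level evidence that distinguishes a circRNA from its linear host
transcript is a read spanning the back-splice junction — a sequence that is
non-colinear with the genome. RNA-binding-protein (RBP) binding sites are
profiled genome-wide by CLIP-Seq (HITS-CLIP, PAR-CLIP, iCLIP), but CLIP
reads are short (often 20–50 nt), single-end, and heavily PCR-duplicated,
which defeats the split-read strategies used by circRNA callers designed for
long paired-end RNA-Seq. `circlip` takes the opposite approach: instead of
discovering junctions from reads, it starts from a library of *known*
circRNA coordinates, represents each junction as a short artificial
reference sequence on which junction reads align contiguously, and lets the
genome compete for every read. Only reads that the genome cannot explain,
and that cross a junction cleanly, count as evidence of RBP-circRNA binding.

The trade-off is deliberate: the method cannot discover circRNAs absent from
its input library, and it only sees binding at the junction itself (binding
elsewhere on the circle is indistinguishable from binding the linear
transcript). In exchange it works on exactly the data CLIP produces.

## Pipeline

### Junction pseudo-reference

For each circRNA with 0-based half-open genomic span `[start, end)` and
length `L = end − start`, the strand-oriented circRNA sequence is extracted
and its last `k` bases are concatenated with its first `k` bases,
`k = min(50, L)` (`build_junction_contig()`). Reads crossing position `k` of
this contig cross the back-splice junction. 50 bases per side is enough to
contain any CLIP-length read while keeping the contig too short to attract
reads that belong elsewhere; circles shorter than 50 nt per side contribute
`k = L` per side (the doubled circle), with no multi-wrap tiling. Circles
shorter than 12 nt are rejected outright — they cannot carry the minimum
junction overhang on both sides.

Input circRNA sets (BED6, possibly several published collections) are pooled
and deduplicated on `(chrom, start, end, strand)`; identical spans on
opposite strands are distinct circRNAs because back-splicing is
strand-specific. circRNAs dominated by repetitive or low-complexity sequence
produce unreliable alignments, so any circRNA whose full genomic span is
more than `max_masked_frac` (default 0.5) soft-masked (lowercase, from a
RepeatMasker/DUST-masked genome) or ambiguous (`N`) is excluded. The
fraction is computed over the whole circRNA span rather than only the
extracted 100 bp, since a repeat-dominated circle is suspect even when its
junction neighbourhood is clean; both the threshold and this choice are
configurable. No internal masking is implemented — the masking is taken from
the genome FASTA the user supplies.

Junction contigs are named `circ|<id>|<chrom>:<start>-<end>:<strand>`, which
cannot collide with chromosome names, and are emitted as uppercase FASTA
appended to the genome, with a manifest TSV mapping each contig to its
circRNA and junction offset. Any SAM-producing aligner can then align reads
to the combined reference; the package consumes the SAM.

### Read preprocessing

CLIP libraries have limited complexity, so identical sequences are almost
always PCR duplicates. After optional 3′-adapter trimming (leftmost
suffix-prefix overlap of at least 5 bases with mismatch rate at most 0.1, or
an internal adapter occurrence) and removal of reads shorter than
`min_read_len` (default 18 nt — below that, spurious junction placements
become likely), identical sequences collapse to unique tags carrying their
multiplicity (`collapse_duplicates()`). All downstream read counting is in
unique tags; multiplicities are carried but unused by default. No UMI or
quality-score handling is attempted — the targeted protocols predate UMIs,
and base qualities do not enter any decision.

### Competitive classification

Each tag's alignments against the combined reference are classified by
`assign_reads()`:

* A junction-contig hit is **valid** only if it extends *more than 5*
  aligned reference bases past the seam on both sides (so at least 6) and
  the mismatch rate within each side is *strictly below* 0.15. Mismatch
  accounting is from CIGAR + MD: substitutions and deleted reference bases
  count as mismatches against the aligned reference span; insertions and
  soft-clips contribute nothing. The per-side denominator is the aligned
  reference bases on that side.
* A tag with any genome hit and no valid junction hit is `LINEAR`.
* A tag with a genome hit *and* a valid junction hit is `CIRC_AND_LINEAR`
  and discarded — the genome competes successfully.
* Valid junction hits to more than one circRNA: `AMBIGUOUS_MULTI_CIRC`,
  discarded.
* Exactly one circRNA with a valid junction hit and no genome hit: `CIRC`.
* Otherwise `NONSPANNING` (junction hits, none valid) or `UNALIGNED`.

Multiple hits to the *same* circRNA count once (best hit: fewest mismatches,
then leftmost). Reverse-orientation junction hits are accepted — antisense
binding is a real, analyzable phenomenon (see strand bias below) — with
`sense_only = TRUE` available to restrict.

### Candidate filters

`CIRC` tags are pooled per circRNA per RBP/condition across samples and
three filters are applied (`call_candidates()`):

1. at least `min_reads = 2` supporting tags;
2. the union footprint of their alignments covers at least
   `min_coverage = 20` nt of the junction contig;
3. the numbers of distinct alignment starts and ends are each at least one
   third of the tag count — a guard against residual PCR stacks that
   survived collapsing by picking up sequencing errors.

The diversity comparison is evaluated as an exact rational inequality
(`3 × n_unique ≥ n_reads`), so 1 unique start among 3 reads passes and 1
among 4 fails; no floating-point boundary artifacts. There is no internal
background model — junction-spanning coverage is far too sparse for peak
calling — but `subtract_control()` removes circRNAs recurrent in a matched
control run processed identically.

## Downstream characterizations

**Strand bias.** For each RBP, the fraction of circRNA-assigned reads
oriented with the parental gene's sense strand is compared with the same
fraction for reads on up to 3000 uniformly sampled annotated transcripts
(`strand_bias()`). A forward hit on a junction contig follows the circRNA's
own genomic strand, so the sense call combines hit orientation, circRNA
strand, and parental-gene strand; circRNAs without an annotated containing
gene are excluded with a reported count.

**Motif sequence sets.** `export_motif_foreground()` writes, per candidate,
the junction-contig subsequences covered by supporting reads;
`build_background_junctions()` writes linear splice-junction analogues
(last 15 bp of each upstream exon + first 15 bp of the downstream exon), a
stringent background because it shares the "two concatenated segments"
structure. Motif discovery itself is left to external tools such as HOMER.

**RBP clustering.** RBPs are clustered on binary circRNA binding profiles.
The distance between two RBPs is the upper-tail hypergeometric p-value of
their shared bound species within the universe of all species in the matrix
— small p (improbably large overlap) means close. The `drop_top_n = 50`
most promiscuously bound species are pruned first: highly expressed
circRNAs appear across many CLIP datasets (and in IgG controls) without
implying specific binding. Ties at the pruning boundary break
lexicographically by circRNA id, and the linkage is average by default; both
are configurable since neither choice is canonical.

**Gene-set enrichment.** Parental genes of each RBP's bound circRNAs are
tested against gene sets (GMT) with the hypergeometric upper tail, for RBPs
with more than 100 distinct parental genes and terms with at least 10 genes.
Because parental-gene sets inherit structure (gene length, expression) that
generic backgrounds ignore, an empirical correction is applied: for each RBP,
10 same-size random gene sets are drawn from the universe, and the mean
background log10 p per term is subtracted from the true log10 p. Bonferroni
significance at 0.05 is evaluated on the uncorrected true p-values across
all tested (RBP, term) pairs. Randomization substreams are derived from a
master seed and a stable per-RBP name hash, so results are reproducible and
independent of evaluation order.

`hypergeom_tail()` evaluates P(X ≥ k) via `stats::phyper` in log space; the
test suite pins it against an exact factorial-summation oracle to relative
error ≤ 1e-9 over the N ≤ 60 range and against exact rational values.

## Synthetic data and the alignment oracle

The package carries its own generator (`simulate_genome()`,
`simulate_clip_reads()`) and an exhaustive aligner (`naive_align()`) so every
stage is testable with no external data. The generator emulates what makes
CLIP hard: short single-end reads, high PCR duplication (geometric copy
counts), a planted per-base error rate, an antisense fraction, linear reads
from exon interiors, and intergenic genomic reads as the negative-control
class, mirroring the use of DNA-Seq as a negative control for junction
calling. Each stage draws from an independent substream of the master seed,
so changing one stage's parameters does not perturb the others, and every
emitted read has exactly one ground-truth row.

Default conditions: a 200 kb two-chromosome genome, 40 three-exon genes, 20
circRNAs of 100–400 nt placed sense within distinct genes, 10 of them
receiving 4–8 junction reads each, 5000 linear reads, 2000 genomic reads,
1% per-base error, 40% duplication probability, 10% antisense.

Read geometry deserves a note, because it interacts with the aligner's
mismatch budget. `naive_align()` reports *every* ungapped full-length
placement (both orientations) with at most `ceil(0.2 × read length)`
mismatches — a complete oracle by construction, which is the point: the
classifier must see every hit the genome could claim. But completeness cuts
both ways: a junction read whose overhang on one side is shorter than the
mismatch budget can always be absorbed by the genome (the short side simply
counts as mismatches), turning a genuine junction read into discarded
`CIRC_AND_LINEAR` evidence. With read lengths 32–40 nt the budget is 7–8, so
the generator plants overhangs of at least 16 bases per side: the
probability that a 16-base random flank matches the genome within budget is
below 3%, and a planted circRNA with four or more reads essentially never
drops below the two-tag filter. These defaults were fixed from that
calculation, not tuned against test outcomes. What the synthetic data does
*not* model: cross-link-induced mutations (PAR-CLIP T→C, iCLIP
truncations), quality-score structure, non-uniform genomic composition,
repeats (so the low-complexity screen is exercised on constructed masked
fixtures, not emergent repeats), and spliced genome alignments. Passing
tests therefore demonstrate the pipeline's rule logic and bookkeeping, not
robustness to every artifact of real CLIP libraries.

The end-to-end property the suite enforces mirrors the negative-control
logic of the original study design: with at least two clean junction tags
per planted circRNA, the called candidate set equals the planted set
exactly, and a run containing only genomic reads yields zero candidates.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally (BED convention);
  1-based inclusive input is a flag on the BED reader.
* "More than 5 bp" and "smaller than 0.15" are strict inequalities; the
  overhang threshold is therefore ≥ 6 aligned bases.
* A zero-length overhang side reports mismatch rate 0 (the length test
  already fails the hit).
* Tags with equal-mismatch hits tie-break to the leftmost reference start.
* An empty circRNA set yields a genome-only reference; empty read groups,
  empty candidate sets, and a zero-read strand-bias fraction (reported `NA`)
  are all defined, tested outcomes rather than errors.
* The filter-report invariant `groups_in = candidates_out + Σ first-cause
  rejections` attributes each rejected group to the first failing filter in
  the order min-reads, coverage, diversity.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at its default
scale (200 kb genome, ~12,000–13,000 reads collapsing to ~7,000 tags), which
exercises every code path in a few minutes on one CPU; the rule-grid and
filter truth-table checks enumerate all ~400 overhang/mismatch combinations
and all 15,503 read-group multisets up to size 5 exhaustively. Larger
genomes and libraries change only runtime, not logic: the aligner is the
quadratic piece and is intended as an oracle for exactly this scale, while
production use feeds SAM from a real aligner.

## Limitations

Beyond the scope notes above: candidate confidence is not scored beyond the
three pass/fail filters; the clustering distance treats p-values as
distances without embedding guarantees (it is a similarity ordering, not a
metric); and control subtraction is binary presence/absence, not
abundance-aware.
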