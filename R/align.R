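#' Alignment scoring parameters
#'
#' Defaults (+2 match, -4 mismatch, -4 gap open, -1 gap extend; a gap of
#' length k costs `gap_open + k * gap_extend`) are tuned so that a long
#' splice-event indel (35-154 nt) survives as one contiguous gap operation
#' rather than a scatter of mismatches.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores/penalties
#'   (penalties negative).
#' @return list of class `gap_params`.
#' @export
gap_params <- function(match = 2L, mismatch = -4L, gap_open = -4L, gap_extend = -1L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
            class = "gap_params")
}

#' Align CCS reads to an amplicon reference
#'
#' Semi-global alignment (free end gaps on both the read and the reference)
#' with affine gap penalties. Orientation is decided by a k-mer vote against
#' the reference, with an exhaustive fallback when the vote is ambiguous or
#' the resulting identity is poor, so the better of the two orientations is
#' kept. Ties in the dynamic program are broken deterministically (diagonal
#' over gap, deletion over insertion) and indels are left-normalized.
#'
#' By default the dynamic program is banded around the expected diagonal
#' (band half-width `band_pad` plus the read/reference length difference),
#' which is exact for full-length amplicon reads whose indels fit in the
#' band; reads falling below `min_identity` are re-aligned exhaustively
#' before being declared unmapped. Set `banded = FALSE` to force exhaustive
#' alignment everywhere.
#'
#' @param reads a `ccs_reads` tibble (columns `id`, `sequence`), a plain data
#'   frame with those columns, a named character vector, or a
#'   [Biostrings::DNAStringSet].
#' @param amplicon an `amplicon`.
#' @param params a [gap_params()] object.
#' @param banded logical; use the banded dynamic program (default).
#' @param band_pad band half-width in diagonals beyond the read/reference
#'   length difference. The default 12 covers mid-read indel excursions of
#'   full-length amplicon reads with very large margin; single contiguous
#'   isoform events are handled through the length difference itself.
#' @param min_identity minimum identity (matches / aligned columns) for a
#'   read to count as mapped.
#' @param rescue_identity banded alignments below this identity are re-run
#'   exhaustively before the mapped/unmapped decision, so reads that violate
#'   the band assumption (e.g. multiple large opposite-sign events) are not
#'   silently misaligned.
#' @param end_tolerance bases of slack at each amplicon end when classifying
#'   reads as full-length (see [classify_full_length()]).
#' @return A tibble of class `amp_alignments`, one row per read: `id`,
#'   `mapped`, `strand`, `score`, `ref_start`, `ref_end` (0-based half-open),
#'   `cigar` (with `=`/`X` distinction), `identity`, `full_length`, and the
#'   orientation-normalized read sequence `aln_seq`. The amplicon is attached
#'   as attribute `amplicon`.
#' @export
align_reads <- function(reads, amplicon, params = gap_params(),
                        banded = TRUE, band_pad = 12L, min_identity = 0.75,
                        rescue_identity = 0.9, end_tolerance = 5L) {
  reads <- as_ccs_reads(reads)
  if (nrow(reads) == 0) abort("no reads to align")
  raw <- cpp_align_batch(reads$sequence, amplicon$sequence,
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend, as.integer(band_pad), banded,
                         min_identity, rescue_identity)
  aln <- tibble(
    id = reads$id, mapped = raw$mapped, strand = raw$strand,
    score = raw$score, ref_start = raw$ref_start, ref_end = raw$ref_end,
    cigar = raw$cigar, identity = raw$identity,
    n_match = raw$n_match, n_col = raw$n_col, aln_seq = raw$aln_seq
  )
  aln <- classify_full_length(aln, amplicon, end_tolerance = end_tolerance)
  structure(aln, class = c("amp_alignments", class(tibble())),
            amplicon = amplicon)
}

#' Classify alignments as full-length
#'
#' A read is full-length when its reference span reaches both primer regions,
#' i.e. starts within `end_tolerance` bases of the amplicon start and ends
#' within `end_tolerance` bases of the amplicon end. Full-length reads are
#' the unit of isoform analysis.
#'
#' @param alignments an alignment tibble from [align_reads()].
#' @param amplicon the `amplicon` aligned against.
#' @param end_tolerance allowed ragged-end slack in bases (default 5).
#' @return `alignments` with a logical `full_length` column.
#' @export
classify_full_length <- function(alignments, amplicon, end_tolerance = 5L) {
  alignments$full_length <- !is.na(alignments$ref_start) & alignments$mapped &
    alignments$ref_start <= end_tolerance &
    alignments$ref_end >= amplicon$length - end_tolerance
  alignments
}

#' Per-position pileup of aligned reads
#'
#' Counts, for every reference position, the aligned read bases (A/C/G/T) and
#' deletions; insertion observations are tallied separately, keyed by
#' (position, inserted sequence). Only mapped reads contribute.
#'
#' @param alignments an `amp_alignments` tibble.
#' @param amplicon the `amplicon`; defaults to the one stored on
#'   `alignments`.
#' @param indel_mask base observations within this many reference bases of
#'   an indel in the same read are not counted (default 5; 0 disables).
#'   Score-tied alignments can couple an indel sequencing error with a
#'   neighbouring mismatch and park the mismatch at a deterministic offset;
#'   at 10,000x coverage such couplings otherwise surface as systematic
#'   artefact alleles near true variants and homopolymer boundaries. The
#'   masking is the pileup-level analogue of indel-proximal base-quality
#'   capping in standard pileup engines, and of this assay's own
#'   perfect-flank rule for composition analysis. Deletion columns
#'   themselves are always tallied.
#' @return A tibble of class `amp_pileup`, one row per reference position:
#'   `position` (0-based), `ref`, `nA`, `nC`, `nG`, `nT`, `ndel`, and
#'   `coverage` (base calls only, excluding deletions). Insertion counts are
#'   attached as attribute `insertions`; the number of contributing reads as
#'   attribute `n_reads`.
#' @export
pileup <- function(alignments, amplicon = attr(alignments, "amplicon"),
                   indel_mask = 5L) {
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) == 0) abort("pileup requires at least one mapped alignment")
  raw <- cpp_pileup(m$aln_seq, m$cigar, m$ref_start, amplicon$length,
                    as.integer(indel_mask))
  cm <- raw$counts
  pu <- tibble(
    position = seq_len(amplicon$length) - 1L,
    ref = strsplit(amplicon$sequence, "")[[1]],
    nA = cm[1, ], nC = cm[2, ], nG = cm[3, ], nT = cm[4, ], ndel = cm[5, ]
  )
  pu$coverage <- pu$nA + pu$nC + pu$nG + pu$nT
  structure(pu, class = c("amp_pileup", class(tibble())),
            insertions = tibble(position = raw$ins_pos, seq = raw$ins_seq,
                                count = raw$ins_count),
            n_reads = nrow(m), amplicon = amplicon)
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM export with `=`/`X` CIGAR operators, soft
#' clips, and flags 0/16 for strand. Unmapped reads get flag 4.
#'
#' @param alignments an `amp_alignments` tibble (needs the original reads for
#'   unmapped records; mapped records store the oriented sequence).
#' @param amplicon the reference aligned against.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, amplicon = attr(alignments, "amplicon")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", amplicon$name, amplicon$length),
    "@PG\tID:ampliphase\tPN:ampliphase"
  ), con)
  a <- alignments
  flag <- ifelse(!a$mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   a$id, flag,
                   ifelse(a$mapped, amplicon$name, "*"),
                   ifelse(a$mapped, a$ref_start + 1L, 0L),
                   ifelse(a$mapped, 60L, 0L),
                   ifelse(a$mapped, a$cigar, "*"),
                   a$aln_seq)
  writeLines(lines, con)
  invisible(path)
}

#' Write alignments as a plain TSV table
#'
#' The internal tabular representation (one row per read, CIGAR with
#' `=`/`X`), without the sequence column.
#'
#' @param alignments an `amp_alignments` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  cols <- c("id", "mapped", "strand", "score", "ref_start", "ref_end",
            "cigar", "identity", "full_length")
  utils::write.table(as.data.frame(alignments[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignments back from SAM
#'
#' Parses single-reference SAM records as produced by [write_sam()] (CIGAR
#' restricted to the `S`/`=`/`X`/`I`/`D` operators) back into an alignment
#' tibble usable by [pileup()] and downstream steps.
#'
#' @param path SAM file.
#' @param amplicon the `amplicon` the file was aligned against.
#' @return an `amp_alignments` tibble.
#' @export
read_sam <- function(path, amplicon) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  f <- strsplit(ln, "\t")
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  if (any(grepl("[MNHP]", cigar))) {
    abort("unsupported CIGAR operator: only S/=/X/I/D records (as written by write_sam) are supported")
  }
  mapped <- !bitwAnd(flag, 4L)
  aln <- tibble(
    id = get(1), mapped = mapped,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    score = NA_integer_,
    ref_start = ifelse(mapped, as.integer(get(4)) - 1L, NA_integer_),
    ref_end = NA_integer_,
    cigar = ifelse(mapped, cigar, NA_character_),
    aln_seq = get(10)
  )
  stats <- cigar_stats(aln$cigar)
  aln$ref_end <- aln$ref_start + stats$ref_len
  aln$identity <- stats$n_match / pmax(stats$n_col, 1L)
  aln$n_match <- stats$n_match
  aln$n_col <- stats$n_col
  aln <- aln[, c("id", "mapped", "strand", "score", "ref_start", "ref_end",
                 "cigar", "identity", "n_match", "n_col", "aln_seq")]
  aln <- classify_full_length(aln, amplicon)
  structure(aln, class = c("amp_alignments", class(tibble())),
            amplicon = amplicon)
}

# lengths/matches implied by an S/=/X/I/D cigar vector
cigar_stats <- function(cigar) {
  parse1 <- function(cg) {
    if (is.na(cg)) return(c(0L, 0L, 0L))
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    c(sum(len[op %in% c("=", "X", "D")]),
      sum(len[op == "="]),
      sum(len[op %in% c("=", "X", "I", "D")]))
  }
  m <- vapply(cigar, parse1, integer(3), USE.NAMES = FALSE)
  list(ref_len = m[1, ], n_match = m[2, ], n_col = m[3, ])
}

#' @export
glance.amp_alignments <- function(x, ...) {
  tibble(
    n_reads = nrow(x),
    n_mapped = sum(x$mapped),
    pct_mapped = 100 * mean(x$mapped),
    n_full_length = sum(x$full_length),
    pct_full_length = 100 * mean(x$full_length),
    mean_identity = mean(x$identity[x$mapped])
  )
}
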