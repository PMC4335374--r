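#' Variant caller configuration
#'
#' The caller tests each (position, alternative base) against the sequencing
#' error floor with a one-sided binomial tail, Bonferroni-corrected over all
#' 3 x amplicon-length hypotheses, and additionally requires a minimum
#' frequency and absolute alternate-read count. `error_floor` is a
#' per-position substitution rate; when supplied explicitly, each specific
#' alternative base is assumed to occur at a third of it, and when left
#' `NULL` a robust per-alternative floor is estimated from the pileup
#' instead (see [call_variants()] for why the uniform third is not used
#' there).
#'
#' @param min_frequency minimum raw variant frequency (alt / coverage) for a
#'   call, in (0, 0.5]; default 0.005.
#' @param min_alt_count absolute minimum alternate-read count, a guard
#'   against spurious calls at low coverage; default 10.
#' @param error_floor per-position substitution rate; `NULL` (default) means
#'   estimate it from the pileup with [estimate_error_floor()].
#' @param alpha family-wise error rate for the Bonferroni-corrected binomial
#'   test; default 0.05.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_frequency = 0.005, min_alt_count = 10L,
                          error_floor = NULL, alpha = 0.05) {
  if (min_frequency <= 0 || min_frequency > 0.5) {
    abort("min_frequency must be in (0, 0.5]")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(list(min_frequency = min_frequency,
                 min_alt_count = as.integer(min_alt_count),
                 error_floor = error_floor, alpha = alpha),
            class = "caller_config")
}

#' Estimate the per-position substitution-error floor from a pileup
#'
#' Robust estimate: the median across positions of the non-reference base
#' fraction, after iteratively excluding candidate variant alleles (any
#' alternative base whose frequency exceeds five times a third of the current
#' floor estimate, i.e. five times the expected per-alternative error rate);
#' two exclusion rounds are performed. True variants therefore do not inflate
#' the floor.
#'
#' @param pileup an `amp_pileup` tibble.
#' @return the estimated per-position substitution rate (a single number).
#' @export
estimate_error_floor <- function(pileup) {
  if (sum(pileup$coverage) < 1000) {
    abort("insufficient coverage to estimate the error floor (need >= 1000 aligned columns)")
  }
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  ridx <- match(pileup$ref, c("A", "C", "G", "T"))
  cov <- pileup$coverage
  total_mm <- cov - counts[cbind(seq_len(nrow(counts)), ridx)]
  ok <- cov > 0
  floor_est <- median(total_mm[ok] / cov[ok])
  for (round in 1:2) {
    per_alt_floor <- floor_est / 3
    freq <- counts / pmax(cov, 1L)
    freq[cbind(seq_len(nrow(counts)), ridx)] <- 0
    candidate <- freq > 5 * per_alt_floor
    mm <- total_mm - rowSums(counts * candidate)
    floor_est <- median(mm[ok] / cov[ok])
  }
  floor_est
}

#' Call minor point variants from a pileup
#'
#' Emits every (position, alternative base) whose frequency and alternate
#' count clear the configured minima and whose one-sided binomial tail
#' probability `P(X >= alt count | n = coverage, p = per-alternative floor)`
#' falls below `alpha / (3 x amplicon length)` (Bonferroni). Calls are
#' annotated with gene/codon/amino-acid labels when the position lies in a
#' complete codon.
#'
#' When the floor is estimated from the pileup, the per-alternative null
#' rate is not taken as a third of the per-position substitution rate:
#' although simulated sequencing errors are uniform over the three
#' alternative bases, alignment of indel-bearing reads concentrates
#' residual errors onto context-dependent alternatives, so per-alternative
#' rates vary a few percent around the uniform value and a uniform-split
#' null is anti-conservative across thousands of Bonferroni tests. Instead
#' the per-alternative floor is estimated robustly as the median across
#' positions of the *largest* per-alternative mismatch rate (candidate
#' variant alleles excluded, two refinement rounds) — an upper envelope
#' that is self-calibrating: under truly uniform errors it exceeds rate/3
#' only by the expected maximum of three binomial noise terms, and it
#' widens automatically where coverage is low. An explicitly supplied
#' `error_floor` bypasses this and uses `error_floor / 3`.
#'
#' Two frequencies are reported: `frequency`, the raw alt count over
#' coverage, and `freq_adjusted`, a method-of-moments estimate of the
#' underlying clone fraction that subtracts the error-floor contribution and
#' rescales for errors lost from true variant reads
#' (`(freq - s/3) / (1 - 4s/3)` for substitution rate `s`).
#'
#' @param pileup an `amp_pileup`.
#' @param config a [caller_config()].
#' @param amplicon the `amplicon`; defaults to the one stored on the pileup.
#' @return tibble of class `variant_calls`, sorted by position: `position`
#'   (0-based), `ref`, `alt`, `alt_count`, `coverage`, `frequency`,
#'   `freq_adjusted`, `p_adjusted`, plus annotation columns `gene`, `codon`,
#'   `ref_aa`, `alt_aa`, `label`, `synonymous`. The error floor used is
#'   attached as attribute `error_floor`.
#' @export
call_variants <- function(pileup, config = caller_config(),
                          amplicon = attr(pileup, "amplicon")) {
  if (nrow(pileup) == 0) abort("empty pileup")
  if (is.null(config$error_floor)) {
    floor_est <- estimate_error_floor(pileup)
    p_alt <- estimate_per_alt_floor(pileup)
  } else {
    floor_est <- config$error_floor
    p_alt <- floor_est / 3
  }
  n_tests <- 3 * nrow(pileup)

  long <- tidyr::pivot_longer(
    pileup[, c("position", "ref", "nA", "nC", "nG", "nT", "coverage")],
    cols = c("nA", "nC", "nG", "nT"), names_to = "alt", values_to = "alt_count"
  )
  long$alt <- substr(long$alt, 2, 2)
  long <- long[long$alt != long$ref & long$alt_count > 0, , drop = FALSE]
  long$frequency <- long$alt_count / long$coverage
  keep <- long$frequency >= config$min_frequency &
    long$alt_count >= config$min_alt_count
  long <- long[keep, , drop = FALSE]
  if (nrow(long) > 0) {
    long$p_value <- pbinom(long$alt_count - 1L, long$coverage, p_alt,
                           lower.tail = FALSE)
    long <- long[long$p_value < config$alpha / n_tests, , drop = FALSE]
  }
  calls <- tibble(
    position = integer(0), ref = character(0), alt = character(0),
    alt_count = integer(0), coverage = integer(0),
    frequency = numeric(0), freq_adjusted = numeric(0), p_adjusted = numeric(0)
  )
  if (nrow(long) > 0) {
    long <- long[order(long$position, long$alt), , drop = FALSE]
    calls <- tibble(
      position = as.integer(long$position), ref = long$ref, alt = long$alt,
      alt_count = as.integer(long$alt_count), coverage = as.integer(long$coverage),
      frequency = long$frequency,
      freq_adjusted = pmin(1, pmax(0, (long$frequency - floor_est / 3) /
                                     (1 - 4 * floor_est / 3))),
      p_adjusted = pmin(1, long$p_value * n_tests)
    )
  }
  calls <- annotate_variants(calls, amplicon)
  structure(calls, class = c("variant_calls", class(tibble())),
            error_floor = floor_est, per_alt_floor = p_alt,
            amplicon = amplicon, config = config)
}

# robust per-alternative error floor: median across positions of the
# largest per-alternative non-reference rate, candidate alleles excluded
# iteratively (see call_variants for rationale)
estimate_per_alt_floor <- function(pileup) {
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  ridx <- match(pileup$ref, c("A", "C", "G", "T"))
  cov <- pileup$coverage
  ok <- cov > 0
  rate <- counts / pmax(cov, 1L)
  rate[cbind(seq_len(nrow(counts)), ridx)] <- 0
  p_alt <- median(apply(rate[ok, , drop = FALSE], 1, max))
  for (round in 1:2) {
    r <- rate
    r[r > 5 * pmax(p_alt, 1e-12)] <- 0
    p_alt <- median(apply(r[ok, , drop = FALSE], 1, max))
  }
  p_alt
}

#' Annotate variant calls with amino-acid changes
#'
#' Adds gene, clinical codon index, reference and alternate amino acid and a
#' `"T315I"`-style label (via the amplicon's codon anchors and the standard
#' genetic code applied to the mutated codon). Positions in partial codons at
#' the amplicon edge are flagged by `NA` annotation instead of an error.
#'
#' @param calls a `variant_calls` tibble (or any tibble with `position`,
#'   `ref`, `alt`).
#' @param amplicon the `amplicon`.
#' @return `calls` with columns `gene`, `codon`, `ref_aa`, `alt_aa`, `label`,
#'   `synonymous`.
#' @export
annotate_variants <- function(calls, amplicon) {
  n <- nrow(calls)
  calls$gene <- rep(NA_character_, n)
  calls$codon <- rep(NA_integer_, n)
  calls$ref_aa <- rep(NA_character_, n)
  calls$alt_aa <- rep(NA_character_, n)
  calls$label <- rep(NA_character_, n)
  calls$synonymous <- rep(NA, n)
  if (n == 0) return(calls)
  cs <- codon_start_at(amplicon, calls$position)
  translatable <- !is.na(cs)
  if (any(translatable)) {
    ann <- annotate_codon(amplicon, calls$position[translatable])
    alt_codon <- ann$ref_codon
    off <- calls$position[translatable] - ann$codon_start
    substr(alt_codon, off + 1, off + 1) <- calls$alt[translatable]
    alt_aa <- translate_codons(alt_codon)
    calls$gene[translatable] <- ann$gene
    calls$codon[translatable] <- ann$codon
    calls$ref_aa[translatable] <- ann$ref_aa
    calls$alt_aa[translatable] <- alt_aa
    calls$label[translatable] <- sprintf("%s%d%s", ann$ref_aa, ann$codon, alt_aa)
    calls$synonymous[translatable] <- ann$ref_aa == alt_aa
  }
  calls
}

#' Write variant calls as TSV
#'
#' Human-readable table: 1-based position, ref, alt, counts, frequency in
#' percent, adjusted p-value and label.
#'
#' @param calls a `variant_calls` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  out <- tibble(
    position = calls$position + 1L, ref = calls$ref, alt = calls$alt,
    alt_count = calls$alt_count, coverage = calls$coverage,
    frequency_pct = round(100 * calls$frequency, 4),
    freq_adjusted_pct = round(100 * calls$freq_adjusted, 4),
    p_adjusted = signif(calls$p_adjusted, 4), label = calls$label
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant calls as minimal VCF
#'
#' Transcript-space (amplicon-coordinate) VCFv4.2 with `AF`, `DP` and
#' `LABEL` INFO fields.
#'
#' @param calls a `variant_calls` tibble.
#' @param path output file.
#' @param amplicon the `amplicon`; defaults to the one stored on `calls`.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(calls, path, amplicon = attr(calls, "amplicon")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", amplicon$name, amplicon$length),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Base coverage\">",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Amino-acid change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f;DP=%d;LABEL=%s",
    amplicon$name, calls$position + 1L, calls$ref, calls$alt,
    calls$frequency, calls$coverage,
    ifelse(is.na(calls$label), ".", calls$label)
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}
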