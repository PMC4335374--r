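#' Fusion-transcript reference models
#'
#' A transcript model holds the ordered exon structure of a chimeric fusion
#' transcript (upstream-gene exons followed by downstream-gene exons, e.g.
#' BCR then ABL1), its breakpoint variant tag, and the reading-frame phase.
#' All coordinates are 0-based half-open internally; 1-based positions appear
#' only in human-readable report files.
#'
#' @param exons data frame with columns `gene`, `name`, `ordinal`, `sequence`
#'   (uppercase DNA). Exons must be ordered: all upstream-gene exons first,
#'   ordinals strictly increasing within each gene.
#' @param breakpoint breakpoint variant tag, e.g. `"e14a2"` or `"e13a2"`.
#' @param frame_offset integer in 0..2: transcript position where the reading
#'   frame starts (codons begin at `frame_offset`, `frame_offset + 3`, ...).
#' @param codon_anchors optional data frame with columns `gene`, `exon`,
#'   `offset`, `codon` anchoring the clinical codon numbering (e.g. ABL1-1a
#'   numbering in which T315 is codon 315) to a transcript position. Anchored
#'   positions must be codon starts.
#' @return An object of class `transcript_model`: a list with the exon table
#'   (with transcript start/end per exon), the concatenated `sequence`, and a
#'   `junctions` tibble (one row per internal exon boundary).
#' @examples
#' m <- build_transcript(
#'   data.frame(gene = c("BCR", "ABL1"), name = c("BCR-x", "ABL1-y"),
#'              ordinal = c(1L, 1L), sequence = c("ACG", "TTT")),
#'   breakpoint = "e14a2")
#' m$sequence
#' @export
build_transcript <- function(exons, breakpoint = "e14a2", frame_offset = 0L,
                             codon_anchors = NULL) {
  exons <- as_tibble(exons)
  need <- c("gene", "name", "ordinal", "sequence")
  if (!all(need %in% names(exons)) || nrow(exons) == 0) {
    abort("`exons` must be a non-empty data frame with columns gene, name, ordinal, sequence")
  }
  exons$sequence <- toupper(exons$sequence)
  if (any(!nzchar(exons$sequence)) || any(grepl("[^ACGT]", exons$sequence))) {
    abort("exon sequences must be non-empty and contain only A, C, G, T")
  }
  if (anyDuplicated(paste(exons$gene, exons$name))) {
    abort("(gene, name) pairs must be unique within a transcript model")
  }
  genes <- rle(as.character(exons$gene))$values
  if (length(genes) > 2 || anyDuplicated(genes)) {
    abort("exons must be ordered: all upstream-gene exons, then all downstream-gene exons")
  }
  for (g in genes) {
    o <- exons$ordinal[exons$gene == g]
    if (is.unsorted(o, strictly = TRUE)) {
      abort(sprintf("exon ordinals out of order within gene %s", g))
    }
  }
  if (!frame_offset %in% 0:2) abort("`frame_offset` must be 0, 1 or 2")

  exons$length <- nchar(exons$sequence)
  exons$end <- cumsum(exons$length)
  exons$start <- exons$end - exons$length
  junctions <- tibble(
    position = exons$end[-nrow(exons)],
    upstream = exons$name[-nrow(exons)],
    downstream = exons$name[-1]
  )
  anchors <- NULL
  if (!is.null(codon_anchors)) {
    anchors <- as_tibble(codon_anchors)
    anchors <- dplyr::left_join(anchors,
      dplyr::select(exons, exon = "name", exon_start = "start"), by = "exon")
    if (anyNA(anchors$exon_start)) abort("codon anchor refers to an unknown exon")
    anchors$position <- anchors$exon_start + anchors$offset
    if (any((anchors$position - frame_offset) %% 3L != 0L)) {
      abort("codon anchors must sit at codon start positions")
    }
  }
  structure(
    list(
      exons = exons, breakpoint = breakpoint,
      frame_offset = as.integer(frame_offset),
      sequence = paste(exons$sequence, collapse = ""),
      junctions = junctions, anchors = anchors
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s, %d exons, %d nt\n",
              x$breakpoint, nrow(x$exons), nchar(x$sequence)))
  invisible(x)
}

#' Read a fusion-transcript reference description
#'
#' Parses a structured YAML reference description: exon list (gene, name,
#' ordinal, sequence), breakpoint tag, frame offset, primer pair and codon
#' anchors. For the `e13a2` breakpoint variant the last upstream-gene exon
#' present only in `e14a2` is dropped.
#'
#' @param path path to the YAML reference description.
#' @param breakpoint optionally override the breakpoint variant
#'   (`"e14a2"` keeps all exons; `"e13a2"` drops exon BCR-e14).
#' @return A `transcript_model` with the primer pair attached as
#'   `fwd_primer` / `rev_primer`.
#' @export
read_reference <- function(path, breakpoint = NULL) {
  if (!file.exists(path)) abort(sprintf("reference file not found: %s", path))
  y <- yaml::read_yaml(path)
  exons <- dplyr::bind_rows(lapply(y$exons, as_tibble))
  breakpoint <- breakpoint %||% y$breakpoint
  if (identical(breakpoint, "e13a2")) {
    bcr <- exons$gene == exons$gene[1]
    exons <- exons[-max(which(bcr)), ]
  }
  anchors <- if (!is.null(y$codon_anchors)) {
    dplyr::bind_rows(lapply(y$codon_anchors, as_tibble))
  }
  m <- build_transcript(exons, breakpoint = breakpoint,
                        frame_offset = y$frame_offset %||% 0L,
                        codon_anchors = anchors)
  m$name <- y$name
  m$fwd_primer <- toupper(y$fwd_primer)
  m$rev_primer <- toupper(y$rev_primer)
  m
}

#' Write a transcript model back to a YAML reference description
#' @param model a `transcript_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(model, path) {
  anchors <- model$anchors
  y <- list(
    name = model$name %||% "unnamed-reference",
    breakpoint = model$breakpoint,
    frame_offset = model$frame_offset,
    fwd_primer = model$fwd_primer,
    rev_primer = model$rev_primer,
    codon_anchors = if (!is.null(anchors)) {
      lapply(seq_len(nrow(anchors)), function(i) {
        as.list(anchors[i, c("gene", "exon", "offset", "codon")])
      })
    },
    exons = lapply(seq_len(nrow(model$exons)), function(i) {
      as.list(model$exons[i, c("gene", "name", "ordinal", "sequence")])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' In-silico PCR: extract the amplicon a primer pair defines
#'
#' The forward primer must match the sense strand exactly once; the reverse
#' primer's reverse complement must match exactly once, downstream of the
#' forward site. Matching is exact (no mismatch tolerance): the assay uses one
#' specific primer pair. The amplicon spans from the forward-primer start
#' through the end of the reverse-primer match, inclusive of both primer
#' sites.
#'
#' @param transcript a `transcript_model`.
#' @param fwd_primer,rev_primer primer sequences (5'->3', at least 10 nt);
#'   default to the primers stored in the model, if any.
#' @return An object of class `amplicon`: sequence, transcript offset, primer
#'   spans, per-exon amplicon intervals, junctions, codon anchors (all in
#'   amplicon coordinates) and the reading-frame start.
#' @export
in_silico_pcr <- function(transcript,
                          fwd_primer = transcript$fwd_primer,
                          rev_primer = transcript$rev_primer) {
  if (is.null(fwd_primer) || is.null(rev_primer)) {
    abort("primer sequences are required (none stored in the model)")
  }
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  if (nchar(fwd_primer) < 10 || nchar(rev_primer) < 10) {
    abort("primers must be at least 10 nt long")
  }
  seq <- transcript$sequence
  fhits <- find_all(seq, fwd_primer)
  if (length(fhits) == 0) abort("no product: forward primer not found on the sense strand")
  if (length(fhits) > 1) abort("ambiguous product: forward primer matches more than once")
  rrc <- revcomp_chr(rev_primer)
  rhits <- find_all(seq, rrc)
  rhits <- rhits[rhits >= fhits + nchar(fwd_primer)]
  if (length(rhits) == 0) abort("no product: reverse primer site not found downstream of the forward primer")
  if (length(rhits) > 1) abort("ambiguous product: reverse primer site matches more than once")

  a0 <- fhits                      # 0-based amplicon start on the transcript
  a1 <- rhits + nchar(rrc)         # half-open end
  amp_seq <- substr(seq, a0 + 1, a1)
  len <- a1 - a0

  ex <- transcript$exons
  ex$amp_start <- pmax(ex$start - a0, 0L)
  ex$amp_end <- pmin(ex$end - a0, len)
  ex <- ex[ex$amp_end > ex$amp_start, ]
  jn <- transcript$junctions
  jn$amp_position <- jn$position - a0
  jn <- jn[jn$amp_position > 0 & jn$amp_position < len, ]

  frame_start <- (transcript$frame_offset - a0) %% 3L
  anchors <- transcript$anchors
  if (!is.null(anchors)) {
    anchors$amp_position <- anchors$position - a0
    anchors <- anchors[anchors$amp_position >= 0 & anchors$amp_position < len, ]
  }
  structure(
    list(
      sequence = amp_seq, length = len, offset = a0,
      fwd_primer_span = c(0L, nchar(fwd_primer)),
      rev_primer_span = c(len - nchar(rrc), len),
      exons = ex, junctions = jn, frame_start = frame_start,
      anchors = anchors, breakpoint = transcript$breakpoint,
      name = transcript$name %||% "amplicon"
    ),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s (%s), %d bp, %d exons, frame start %d\n",
              x$name, x$breakpoint, x$length, nrow(x$exons), x$frame_start))
  invisible(x)
}

#' Map amplicon positions to exons
#' @param amplicon an `amplicon`.
#' @param positions integer vector of 0-based amplicon positions.
#' @return tibble with one row per position: `position`, `exon`,
#'   `offset_in_exon` (offset within the full exon, not the clipped part).
#' @export
exon_at <- function(amplicon, positions) {
  ex <- amplicon$exons
  idx <- findInterval(positions, ex$amp_start)
  bad <- positions < 0 | positions >= amplicon$length
  if (any(bad)) abort("position outside the amplicon")
  tibble(
    position = as.integer(positions),
    exon = ex$name[idx],
    offset_in_exon = as.integer(positions + amplicon$offset - ex$start[idx])
  )
}

#' Annotate an amplicon position with its codon
#'
#' Maps a position to (gene, codon index, reference amino acid) using the
#' model's codon anchors: the clinical numbering (e.g. ABL1-1a numbering, in
#' which the gatekeeper threonine is codon 315) is supplied by the reference
#' description and propagated arithmetically along the frame.
#'
#' @param amplicon an `amplicon` built from a model with codon anchors.
#' @param positions integer vector of 0-based amplicon positions; each must
#'   fall inside a complete codon of the amplicon's coding frame.
#' @return tibble: `position`, `gene`, `codon`, `codon_start`, `ref_codon`,
#'   `ref_aa` (one-letter).
#' @export
annotate_codon <- function(amplicon, positions) {
  if (is.null(amplicon$anchors) || nrow(amplicon$anchors) == 0) {
    abort("amplicon has no codon anchors; annotation is not possible")
  }
  cs <- codon_start_at(amplicon, positions)
  if (anyNA(cs)) {
    abort(sprintf("untranslatable position: %s lies in a partial codon at the amplicon edge",
                  paste(positions[is.na(cs)], collapse = ", ")))
  }
  an <- amplicon$anchors
  # gene of a codon = gene of the exon holding its first base
  gene <- exon_gene_at(amplicon, cs)
  codon <- vapply(seq_along(cs), function(i) {
    a <- an[an$gene == gene[i], , drop = FALSE]
    if (nrow(a) == 0) return(NA_integer_)
    d <- cs[i] - a$amp_position[1]
    if (d %% 3L != 0L) return(NA_integer_)
    as.integer(a$codon[1] + d %/% 3L)
  }, integer(1))
  ref_codon <- substr(rep(amplicon$sequence, length(cs)), cs + 1, cs + 3)
  tibble(
    position = as.integer(positions), gene = gene, codon = codon,
    codon_start = as.integer(cs), ref_codon = ref_codon,
    ref_aa = translate_codons(ref_codon)
  )
}

#' Pick a single-base substitution that produces a given amino-acid change
#'
#' Enumerates the nine single-nucleotide changes of the codon and returns the
#' first (by position in codon, then base) whose translation equals `alt_aa`.
#' Useful for constructing simulation spike-ins named in clinical notation,
#' e.g. `aa_substitution(amp, "ABL1", 315, "I")` for a T315I-like change.
#'
#' @param amplicon an `amplicon` with codon anchors.
#' @param gene,codon gene symbol and clinical codon index.
#' @param alt_aa target amino acid (one-letter code).
#' @param label optional variant label; defaults to `"<ref><codon><alt>"`.
#' @return one-row tibble: `position` (0-based), `ref`, `alt`, `label`.
#' @export
aa_substitution <- function(amplicon, gene, codon, alt_aa, label = NULL) {
  an <- amplicon$anchors[amplicon$anchors$gene == gene, , drop = FALSE]
  if (nrow(an) == 0) abort(sprintf("no codon anchor for gene %s", gene))
  cs <- an$amp_position[1] + 3L * (codon - an$codon[1])
  if (cs < 0 || cs + 3 > amplicon$length) abort("codon lies outside the amplicon")
  ref_codon <- substr(amplicon$sequence, cs + 1, cs + 3)
  ref_aa <- translate_codons(ref_codon)
  for (k in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(ref_codon, k, k) == b) next
      mut <- ref_codon
      substr(mut, k, k) <- b
      if (translate_codons(mut) == alt_aa) {
        return(tibble(
          position = as.integer(cs + k - 1L),
          ref = substr(ref_codon, k, k), alt = b,
          label = label %||% sprintf("%s%d%s", ref_aa, codon, alt_aa)
        ))
      }
    }
  }
  abort(sprintf("%s -> %s is not reachable by a single-base change", ref_aa, alt_aa))
}

#' Bundled synthetic reference
#'
#' A fully synthetic ~1.6 kb stand-in for the BCR-ABL1 p210 fusion-transcript
#' amplicon, shipped with the package so that every analysis can run without
#' external downloads. It mimics the real amplicon's architecture: 11 exons
#' (three upstream BCR exons, eight downstream ABL1 exons), both breakpoint
#' variants, the published primer pair embedded so that in-silico PCR yields a
#' 1578 bp product, an open reading frame with no internal stop codon, and
#' codon anchors placing the clinically numbered ABL1 kinase-domain codons
#' (253, 255, 276, 315, 359, 396) at fixed offsets. It is not a human
#' sequence; analyses of real data must supply the real reference mRNAs.
#'
#' @param breakpoint `"e14a2"` (default) or `"e13a2"`.
#' @return `toy_reference()` returns a `transcript_model`; `toy_amplicon()`
#'   the corresponding `amplicon`.
#' @export
toy_reference <- function(breakpoint = "e14a2") {
  read_reference(
    system.file("extdata", "synthetic_reference.yaml", package = "ampliphase"),
    breakpoint = breakpoint
  )
}

#' @rdname toy_reference
#' @export
toy_amplicon <- function(breakpoint = "e14a2") {
  in_silico_pcr(toy_reference(breakpoint))
}

#' Write an amplicon sequence as FASTA
#' @param amplicon an `amplicon`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(amplicon, path) {
  s <- Biostrings::DNAStringSet(setNames(amplicon$sequence, amplicon$name))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

## ---- internal helpers -------------------------------------------------

find_all <- function(haystack, needle) {
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m) - 1L
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# 0-based start of the complete codon containing each position, NA if partial
codon_start_at <- function(amplicon, positions) {
  cs <- positions - ((positions - amplicon$frame_start) %% 3L)
  cs[cs < 0 | cs + 3 > amplicon$length] <- NA_integer_
  as.integer(cs)
}

exon_gene_at <- function(amplicon, positions) {
  ex <- amplicon$exons
  ex$gene[findInterval(positions, ex$amp_start)]
}

# translate an arbitrary-length in-frame DNA string (trailing partial codon
# dropped); returns a single character string of one-letter codes
translate_frame <- function(seq, frame_start = 0L) {
  coding <- substr(seq, frame_start + 1, nchar(seq))
  n <- nchar(coding) - nchar(coding) %% 3L
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(coding, 1, n)), no.init.codon = TRUE
  ))
}
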