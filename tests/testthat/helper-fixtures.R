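# Shared fixtures, built in code. The bundled synthetic reference is loaded
# once; smaller constructs are derived from it.

AMP <- toy_amplicon()
T315I <- aa_substitution(AMP, "ABL1", 315, "I")
F359C <- aa_substitution(AMP, "ABL1", 359, "C")

# the undiluted patient-like mixture used across sensitivity tests:
# a dominant single-mutant clone, a minor second-mutant clone, residual WT
p3_clones <- function() {
  list(
    clone_spec(0.889, mutations = T315I),
    clone_spec(0.042, mutations = F359C),
    clone_spec(0.069, label = "WT")
  )
}

# deterministic random DNA
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small three-exon transcript model for fast unit tests
mini_model <- function(e1 = 60, e2 = 45, e3 = 60, seed = 5150) {
  set.seed(seed)
  build_transcript(
    data.frame(
      gene = c("BCR", "BCR", "ABL1"),
      name = c("BCR-x1", "BCR-x2", "ABL1-y1"),
      ordinal = c(1L, 2L, 1L),
      sequence = c(rand_dna(e1), rand_dna(e2), rand_dna(e3))
    ),
    breakpoint = "e14a2", frame_offset = 0L,
    codon_anchors = data.frame(gene = c("BCR", "ABL1"),
                               exon = c("BCR-x1", "ABL1-y1"),
                               offset = c(0L, 0L), codon = c(1L, 100L))
  )
}

# perfect reads (id'd) from a sequence vector
perfect_reads <- function(seqs, prefix = "p") {
  tibble::tibble(id = sprintf("%s%03d", prefix, seq_along(seqs)), sequence = seqs)
}

# parse a cigar string into an op tibble
cigar_ops <- function(cg) {
  len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
  tibble::tibble(op = op, len = len)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
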