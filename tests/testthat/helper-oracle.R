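# Independent oracles, deliberately implemented without touching the
# package's alignment or annotation code paths.

# exhaustive affine-gap semi-global alignment, score only: three dense
# matrices, free end gaps on both sequences, gap(k) = open + k * extend
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -4, gap_extend = -1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap consuming ref
  F <- matrix(NEG, m + 1, n + 1)  # gap consuming read
  H[1, ] <- 0
  H[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ], H[, n + 1])
}

# translate an in-frame DNA string by direct codon lookup
oracle_translate <- function(seq, frame_start = 0) {
  s <- substr(seq, frame_start + 1, nchar(seq))
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# mutate a sequence with point errors / indels for alignment test cases
mutate_seq <- function(seq, n_sub = 0, ins = NULL, del = NULL) {
  s <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(seq_along(s), n_sub)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  out <- paste(s, collapse = "")
  if (!is.null(del)) out <- paste0(substr(out, 1, del[1]), substr(out, del[1] + del[2] + 1, nchar(out)))
  if (!is.null(ins)) out <- paste0(substr(out, 1, ins[[1]]), ins[[2]], substr(out, ins[[1]] + 1, nchar(out)))
  out
}
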