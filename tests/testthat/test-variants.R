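# hand-built pileup for caller unit tests: uniform coverage with specified
# alternate counts spiked in
make_test_pileup <- function(amp, coverage, alts = NULL, noise = 0) {
  ref <- strsplit(amp$sequence, "")[[1]]
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, length(ref), 4, dimnames = list(NULL, bases))
  counts[cbind(seq_along(ref), match(ref, bases))] <- as.integer(coverage)
  if (noise > 0) {
    set.seed(1234)
    for (b in bases) {
      n <- rbinom(length(ref), coverage, noise / 3)
      ok <- ref != b
      counts[ok, b] <- counts[ok, b] + n[ok]
      counts[cbind(seq_along(ref), match(ref, bases))] <-
        pmax(counts[cbind(seq_along(ref), match(ref, bases))] - n, 0L)
    }
  }
  if (!is.null(alts)) {
    for (i in seq_len(nrow(alts))) {
      p <- alts$position[i] + 1L
      counts[p, alts$alt[i]] <- counts[p, alts$alt[i]] + as.integer(alts$count[i])
      counts[p, ref[p]] <- counts[p, ref[p]] - as.integer(alts$count[i])
    }
  }
  pu <- tibble::tibble(position = seq_along(ref) - 1L, ref = ref,
                       nA = counts[, "A"], nC = counts[, "C"],
                       nG = counts[, "G"], nT = counts[, "T"], ndel = 0L)
  pu$coverage <- pu$nA + pu$nC + pu$nG + pu$nT
  structure(pu, class = c("amp_pileup", class(tibble::tibble())),
            insertions = tibble::tibble(position = integer(0), seq = character(0),
                                        count = integer(0)),
            n_reads = coverage, amplicon = amp)
}

test_that("the error floor is zero on clean pileups and candidate variants are excluded", {
  clean <- make_test_pileup(AMP, 1000)
  expect_equal(estimate_error_floor(clean), 0)

  with_var <- make_test_pileup(AMP, 1000, alts = data.frame(position = 542L, alt = "T",
                                                            count = 500L))
  expect_equal(estimate_error_floor(with_var), 0)

  shallow <- make_test_pileup(mini_model() |> (\(m) in_silico_pcr(
    m, substr(m$sequence, 1, 10), revcomp(substr(m$sequence, nchar(m$sequence) - 9,
                                                 nchar(m$sequence)))))(), 2)
  expect_error(estimate_error_floor(shallow), "insufficient", ignore.case = TRUE)
})

test_that("the error floor recovers a simulated substitution rate within 20%", {
  rd <- simulate_sample(AMP, clone_spec(1, label = "WT"), 1200,
                        errors = error_model(0.013, 0.01, 0.005), seed = 12)
  pu <- pileup(align_reads(rd, AMP))
  est <- estimate_error_floor(pu)
  expect_lt(abs(est - 0.013), 0.2 * 0.013)
})

test_that("clear variants are called with correct frequency; clean samples yield no calls", {
  pu <- make_test_pileup(AMP, 1000, alts = data.frame(position = 542L, alt = "T",
                                                      count = 100L))
  calls <- call_variants(pu, caller_config(error_floor = 0.004 * 3))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 542L)
  expect_equal(calls$frequency, 0.1)
  expect_identical(calls$label, "T315I")

  # 1% spike at 30,000x against a 0.4% per-alternative floor: power ~ 1
  pu2 <- make_test_pileup(AMP, 30000, noise = 0.012,
                          alts = data.frame(position = 542L, alt = "T", count = 300L))
  calls2 <- call_variants(pu2, caller_config(error_floor = 0.012))
  expect_true("T315I" %in% calls2$label)

  clean <- make_test_pileup(AMP, 1000)
  expect_equal(nrow(call_variants(clean, caller_config(error_floor = 0.012))), 0L)
})

test_that("sub-threshold signals are rejected by each guard", {
  cfg <- caller_config(error_floor = 0.012)
  # below min frequency
  low_freq <- make_test_pileup(AMP, 30000, alts = data.frame(position = 542L, alt = "T",
                                                             count = 120L))
  expect_equal(nrow(call_variants(low_freq, cfg)), 0L)
  # below min alt count
  low_count <- make_test_pileup(AMP, 300, alts = data.frame(position = 542L, alt = "T",
                                                            count = 6L))
  expect_equal(nrow(call_variants(low_count, cfg)), 0L)
  # above min frequency but within the error floor at low coverage:
  # binomial test must reject
  floorish <- make_test_pileup(AMP, 2000, alts = data.frame(position = 542L, alt = "T",
                                                            count = 12L))
  expect_equal(nrow(call_variants(floorish, caller_config(error_floor = 0.015))), 0L)
})

test_that("amino-acid annotation matches a whole-frame re-translation oracle", {
  set.seed(99)
  pos <- sample(AMP$frame_start:(AMP$length - 4), 40)
  ref <- substring(AMP$sequence, pos + 1, pos + 1)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  calls <- annotate_variants(tibble::tibble(position = pos, ref = ref, alt = alt), AMP)
  for (i in seq_along(pos)) {
    mutated <- AMP$sequence
    substr(mutated, pos[i] + 1, pos[i] + 1) <- alt[i]
    prot <- oracle_translate(mutated, AMP$frame_start)
    ci <- (annotate_codon(AMP, pos[i])$codon_start - AMP$frame_start) %/% 3 + 1
    expect_identical(calls$alt_aa[i], substring(prot, ci, ci))
    expect_identical(calls$synonymous[i], calls$ref_aa[i] == calls$alt_aa[i])
  }
  # synonymous labels carry identical amino acids
  syn <- calls[which(calls$synonymous)[1], ]
  if (nrow(syn) == 1 && !is.na(syn$label)) {
    expect_identical(syn$ref_aa, syn$alt_aa)
  }
})

test_that("caller output is invariant to read input order", {
  cl <- list(clone_spec(0.9, mutations = T315I), clone_spec(0.1, label = "WT"))
  rd <- simulate_sample(AMP, cl, 1500, seed = 13)
  set.seed(1)
  shuffled <- rd[sample.int(nrow(rd)), ]
  c1 <- call_variants(pileup(align_reads(rd, AMP)), amplicon = AMP)
  c2 <- call_variants(pileup(align_reads(shuffled, AMP)), amplicon = AMP)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("variant tables export to TSV and minimal VCF", {
  pu <- make_test_pileup(AMP, 1000, alts = data.frame(position = 542L, alt = "T",
                                                      count = 100L))
  calls <- call_variants(pu, caller_config(error_floor = 0.012))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_tsv(calls, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$position, 543L)  # 1-based in reports
  expect_equal(tab$frequency_pct, 10)
  write_variants_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_true(any(startsWith(lines, "##fileformat=VCF")))
  body <- lines[!startsWith(lines, "#")]
  expect_match(body, "\t543\t.*LABEL=T315I")
})
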