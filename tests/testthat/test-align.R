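test_that("self-alignment is a single perfect match run on the plus strand", {
  al <- align_reads(perfect_reads(AMP$sequence), AMP)
  expect_true(al$mapped)
  expect_identical(al$strand, "+")
  expect_identical(al$cigar, "1578=")
  expect_equal(al$identity, 1)
  expect_true(al$full_length)
  expect_equal(al$score, 2 * 1578)
})

test_that("a constructed substitution yields exactly one mismatch column at the known offset", {
  s <- AMP$sequence
  substr(s, 543, 543) <- "T"  # 0-based position 542
  al <- align_reads(perfect_reads(s), AMP)
  expect_identical(al$cigar, "542=1X1035=")
})

test_that("a 35 nt junction insertion aligns as one insertion operation of length 35", {
  set.seed(21)
  ins <- rand_dna(35)
  s <- paste0(substr(AMP$sequence, 1, 1431), ins, substr(AMP$sequence, 1432, 1578))
  al <- align_reads(perfect_reads(s), AMP)
  ops <- cigar_ops(al$cigar)
  expect_equal(sum(ops$op == "I"), 1L)
  expect_equal(ops$len[ops$op == "I"], 35L)
  expect_equal(sum(ops$op %in% c("X", "D")), 0L)

  # cross-checked against the exhaustive dynamic-programming oracle on a
  # 200 nt truncation around the junction
  ref200 <- substr(AMP$sequence, 1332, 1531)
  read200 <- paste0(substr(ref200, 1, 100), ins, substr(ref200, 101, 200))
  al200 <- align_reads(perfect_reads(read200), AMP200 <- local({
    m <- build_transcript(data.frame(gene = "BCR", name = "t", ordinal = 1L,
                                     sequence = ref200))
    in_silico_pcr(m, substr(ref200, 1, 12), revcomp(substr(ref200, 189, 200)))
  }), banded = FALSE)
  expect_equal(al200$score, oracle_align_score(read200, ref200))
})

test_that("alignment scores equal the exhaustive DP oracle on random instances", {
  set.seed(77)
  for (case in 1:10) {
    n <- sample(60:300, 1)
    ref <- rand_dna(n)
    model <- build_transcript(data.frame(gene = "BCR", name = "r", ordinal = 1L,
                                         sequence = ref))
    amp <- in_silico_pcr(model, substr(ref, 1, 12), revcomp(substr(ref, n - 11, n)))
    read <- mutate_seq(ref, n_sub = sample(0:5, 1),
                       ins = if (case %% 2) list(sample(10:(n - 10), 1), rand_dna(sample(1:6, 1))),
                       del = if (case %% 3 == 0) c(sample(10:(n - 15), 1), sample(1:5, 1)))
    expected <- oracle_align_score(read, ref)
    exhaustive <- align_reads(perfect_reads(read), amp, banded = FALSE)
    expect_equal(exhaustive$score, expected, info = sprintf("case %d exhaustive", case))
    banded <- align_reads(perfect_reads(read), amp)
    expect_equal(banded$score, expected, info = sprintf("case %d banded", case))
  }
})

test_that("aligning the reverse complement gives the same span and operations", {
  set.seed(31)
  read <- mutate_seq(AMP$sequence, n_sub = 12, ins = list(700L, "ACG"), del = c(300L, 2L))
  a <- align_reads(perfect_reads(read), AMP)
  b <- align_reads(perfect_reads(revcomp(read)), AMP)
  expect_identical(b$strand, "-")
  expect_identical(a$ref_start, b$ref_start)
  expect_identical(a$ref_end, b$ref_end)
  expect_identical(a$cigar, b$cigar)
  expect_identical(a$score, b$score)
})

test_that("junk reads are reported unmapped", {
  al <- align_reads(perfect_reads(rand_dna(1500, seed = 8)), AMP)
  expect_false(al$mapped)
})

test_that("full-length classification respects the end tolerance boundary exactly", {
  tol <- 5L
  for (trim in 0:7) {
    read <- substr(AMP$sequence, 1, AMP$length - trim)
    al <- align_reads(perfect_reads(read), AMP, end_tolerance = tol)
    expect_identical(al$full_length, trim <= tol, info = sprintf("3' trim %d", trim))
    read5 <- substr(AMP$sequence, trim + 1, AMP$length)
    al5 <- align_reads(perfect_reads(read5), AMP, end_tolerance = tol)
    expect_identical(al5$full_length, trim <= tol, info = sprintf("5' trim %d", trim))
  }
  mid <- substr(AMP$sequence, 201, AMP$length)
  expect_false(align_reads(perfect_reads(mid), AMP)$full_length)
})

test_that("pileup counts perfect and mixed reads correctly", {
  al <- align_reads(perfect_reads(rep(AMP$sequence, 10)), AMP)
  pu <- pileup(al)
  ref_counts <- as.matrix(pu[, c("nA", "nC", "nG", "nT")])[
    cbind(seq_len(nrow(pu)), match(pu$ref, c("A", "C", "G", "T")))]
  expect_true(all(ref_counts == 10L))
  expect_true(all(pu$ndel == 0L))

  alt <- AMP$sequence
  substr(alt, 543, 543) <- "T"
  al2 <- align_reads(perfect_reads(c(rep(AMP$sequence, 9), alt)), AMP)
  pu2 <- pileup(al2)
  expect_equal(pu2$nC[pu2$position == 542], 9L)
  expect_equal(pu2$nT[pu2$position == 542], 1L)
})

test_that("unmasked pileup conserves reference-consumed length", {
  set.seed(55)
  reads <- vapply(1:30, function(i) {
    mutate_seq(AMP$sequence, n_sub = rpois(1, 15),
               ins = list(sample(100:1400, 1), rand_dna(sample(1:3, 1))),
               del = c(sample(100:1400, 1), sample(1:3, 1)))
  }, character(1))
  al <- align_reads(perfect_reads(reads), AMP)
  pu <- pileup(al, indel_mask = 0L)
  expect_equal(sum(pu$coverage) + sum(pu$ndel), sum(al$ref_end - al$ref_start))
  # per-position totals never exceed the number of mapped reads
  expect_true(all(pu$coverage + pu$ndel <= nrow(al)))
})

test_that("alignments export to a plain TSV table", {
  al <- align_reads(perfect_reads(rep(AMP$sequence, 2)), AMP)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(al, path)
  tab <- read.delim(path)
  expect_equal(tab$cigar, rep("1578=", 2))
  expect_true(all(tab$full_length))
})

test_that("SAM export round-trips through the reader", {
  set.seed(66)
  reads <- c(AMP$sequence,
             mutate_seq(AMP$sequence, n_sub = 5, ins = list(500L, "TT")),
             revcomp(mutate_seq(AMP$sequence, n_sub = 3)))
  al <- align_reads(perfect_reads(reads), AMP)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(al, path)
  back <- read_sam(path, AMP)
  expect_identical(back$cigar, al$cigar)
  expect_identical(back$ref_start, al$ref_start)
  expect_identical(back$strand, al$strand)
  expect_identical(as.data.frame(pileup(back)), as.data.frame(pileup(al)))
})
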