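# a deterministic test harness: perfect reads carrying chosen alleles plus
# one optional extra mismatch at a chosen offset from the variant site
site_read <- function(variant, allele = c("alt", "ref"), extra_offset = NULL) {
  allele <- match.arg(allele)
  s <- AMP$sequence
  if (allele == "alt") substr(s, variant$position + 1, variant$position + 1) <- variant$alt
  if (!is.null(extra_offset)) {
    p <- variant$position + extra_offset + 1
    cur <- substr(s, p, p)
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, substr(AMP$sequence, p, p)))[1]
    substr(s, p, p) <- repl
  }
  s
}

calls_for <- function(variants) {
  annotate_variants(variants, AMP)
}

test_that("clean reads receive their allele; a flank mismatch inside the window excludes the read", {
  vars <- calls_for(T315I)
  al <- align_reads(perfect_reads(c(site_read(T315I, "alt"),
                                    site_read(T315I, "ref"),
                                    site_read(T315I, "alt", extra_offset = 5),
                                    site_read(T315I, "alt", extra_offset = -5),
                                    site_read(T315I, "alt", extra_offset = 15))), AMP)
  sig <- read_signatures(al, vars)
  expect_identical(sig$signature[1], "T315I")
  expect_identical(sig$signature[2], "")
  expect_false(sig$evaluable[3])  # mismatch 5 bases downstream
  expect_false(sig$evaluable[4])  # mismatch 5 bases upstream
  expect_true(sig$evaluable[5])   # mismatch outside the +/-10 window
  expect_identical(sig$signature[5], "T315I")
})

test_that("exactly 20 flanking bases control exclusion (boundary at +/-10 vs +/-11)", {
  vars <- calls_for(T315I)
  offsets <- c(-11L, -10L, 10L, 11L)
  reads <- vapply(offsets, function(d) site_read(T315I, "alt", extra_offset = d),
                  character(1))
  sig <- read_signatures(align_reads(perfect_reads(reads), AMP), vars)
  expect_identical(sig$evaluable, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("raising the window half-width never increases the evaluable read count", {
  cl <- list(clone_spec(0.8, mutations = T315I), clone_spec(0.2, label = "WT"))
  rd <- simulate_sample(AMP, cl, 600, seed = 31)
  al <- align_reads(rd, AMP)
  vars <- calls_for(T315I)
  n_eval <- vapply(c(2L, 5L, 10L, 20L, 40L), function(w) {
    sum(read_signatures(al, vars, window_half_width = w)$evaluable)
  }, integer(1))
  expect_true(all(diff(n_eval) <= 0))
  # evaluable + excluded always partitions the mapped reads
  expect_true(all(n_eval + vapply(c(2L, 5L, 10L, 20L, 40L), function(w) {
    sum(!read_signatures(al, vars, window_half_width = w)$evaluable)
  }, integer(1)) == sum(al$mapped)))
})

test_that("composition groups signatures with frequencies summing to 100 and classifies pairs", {
  vars <- calls_for(dplyr::bind_rows(T315I, F359C))
  reads <- c(rep(site_read(T315I, "alt"), 90),
             rep(site_read(F359C, "alt"), 5),
             rep(AMP$sequence, 5))
  sig <- read_signatures(align_reads(perfect_reads(reads), AMP), vars)
  tab <- composition(sig)
  expect_equal(sum(tab$frequency), 100, tolerance = 1e-10)
  expect_equal(tab$frequency[tab$signature == "T315I"], 90)
  pairs <- attr(tab, "pairs")
  expect_identical(pairs$class, "independent")

  both <- site_read(T315I, "alt")
  substr(both, F359C$position + 1, F359C$position + 1) <- F359C$alt
  sig2 <- read_signatures(align_reads(perfect_reads(c(rep(both, 50), rep(AMP$sequence, 50))), AMP), vars)
  tab2 <- composition(sig2)
  expect_identical(attr(tab2, "pairs")$class, "compound")

  none <- sig[0, ]
  expect_error(composition(none), "zero evaluable")
})

test_that("a noiseless three-clone mixture is recovered exactly against truth labels", {
  cl <- list(clone_spec(0.918, mutations = T315I),
             clone_spec(0.042, mutations = F359C),
             clone_spec(0.040, label = "WT"))
  rd <- simulate_sample(AMP, cl, 3000, errors = error_model(0, 0, 0), seed = 41)
  al <- align_reads(rd, AMP)
  vars <- calls_for(dplyr::bind_rows(T315I, F359C))
  tab <- composition(read_signatures(al, vars))
  truth <- table(read_truth(rd)$clone)
  expect_equal(attr(tab, "n_excluded"), 0L)
  expect_equal(tab$n_reads[tab$signature == "T315I"], unname(truth[["T315I"]]))
  expect_equal(tab$n_reads[tab$signature == "F359C"], unname(truth[["F359C"]]))
  expect_equal(tab$n_reads[tab$signature == ""], unname(truth[["WT"]]))
})

test_that("composition frequencies are invariant to read order", {
  cl <- list(clone_spec(0.9, mutations = T315I), clone_spec(0.1, label = "WT"))
  rd <- simulate_sample(AMP, cl, 400, seed = 51)
  vars <- calls_for(T315I)
  t1 <- composition(read_signatures(align_reads(rd, AMP), vars))
  set.seed(2)
  t2 <- composition(read_signatures(align_reads(rd[sample.int(nrow(rd)), ], AMP), vars))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("chimera diagnostic reports double-positive rates against the independence baseline", {
  vars <- calls_for(dplyr::bind_rows(T315I, F359C))
  # no double positives
  reads <- c(rep(site_read(T315I, "alt"), 20), rep(site_read(F359C, "alt"), 20))
  sig <- read_signatures(align_reads(perfect_reads(reads), AMP), vars)
  expect_equal(chimera_diagnostic(sig, "T315I", "F359C")$rate_both, 0)

  # two mutations always co-simulated: co-occurrence ~ clone fraction
  both_cl <- list(clone_spec(0.3, mutations = dplyr::bind_rows(T315I, F359C),
                             label = "double"),
                  clone_spec(0.7, label = "WT"))
  rd <- simulate_sample(AMP, both_cl, 1000, errors = error_model(0, 0, 0), seed = 61)
  sigc <- read_signatures(align_reads(rd, AMP), vars)
  diag <- chimera_diagnostic(sigc, "T315I", "F359C")
  truth_frac <- mean(read_truth(rd)$clone == "double")
  expect_equal(diag$rate_both, truth_frac, tolerance = 1e-9)
})

test_that("simulated PCR recombination produces the double-positive rate a Monte-Carlo oracle predicts", {
  cl <- list(clone_spec(0.9, mutations = T315I), clone_spec(0.1, mutations = F359C))
  rate <- 0.02
  rd <- simulate_sample(AMP, cl, 4000, errors = error_model(0, 0, 0),
                        chimera = chimera_model(rate), seed = 71)
  vars <- calls_for(dplyr::bind_rows(T315I, F359C))
  sig <- read_signatures(align_reads(rd, AMP), vars)
  obs <- chimera_diagnostic(sig, "T315I", "F359C")$rate_both

  # direct Monte-Carlo oracle of the template-switching process: a chimera
  # carries both mutations iff its two templates donate one mutation each
  # and the breakpoint separates the two sites
  set.seed(72)
  L <- AMP$length
  n_mc <- 2e5
  chim <- runif(n_mc) < rate
  a <- sample(1:2, n_mc, TRUE, prob = c(0.9, 0.1))
  b <- sample(1:2, n_mc, TRUE, prob = c(0.9, 0.1))
  brk <- 1 + floor(runif(n_mc) * (L - 1))
  p1 <- T315I$position; p2 <- F359C$position
  has1 <- ifelse(chim, ifelse(brk > p1, a == 1, b == 1), a == 1)
  has2 <- ifelse(chim, ifelse(brk > p2, a == 2, b == 2), a == 2)
  exp_rate <- mean(has1 & has2)
  se <- sqrt(exp_rate * (1 - exp_rate) / 4000)
  expect_lt(abs(obs - exp_rate), 3 * se + 1e-6)
})
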