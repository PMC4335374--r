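ins35_seq <- rand_dna(35, seed = 350)
ins35 <- isoform_event("insertion", position = 1431L, seq = ins35_seq)
ins154 <- isoform_event("insertion", position = 301L, seq = rand_dna(154, seed = 154))
del72 <- isoform_event("deletion", position = 1200L, length = 72L)

with_event <- function(event) {
  ampliphase:::apply_events(AMP$sequence, event)
}

test_that("isoforms group by sequence (strict) and by event structure (event) with exact frequencies", {
  reads <- perfect_reads(c(rep(with_event(ins35), 2), rep(AMP$sequence, 8)))
  al <- align_reads(reads, AMP)
  for (mode in c("strict", "event")) {
    iso <- detect_isoforms(al, mode = mode)
    expect_equal(nrow(iso), 2L, info = mode)
    expect_equal(iso$frequency[iso$label == "WT"], 80, info = mode)
    expect_equal(iso$frequency[iso$label == "35INS"], 20, info = mode)
  }
})

test_that("the minimum read support for a reported isoform is exactly two", {
  for (support in 1:3) {
    reads <- perfect_reads(c(rep(with_event(ins35), support), rep(AMP$sequence, 10)))
    iso <- detect_isoforms(align_reads(reads, AMP), mode = "event")
    expect_identical("35INS" %in% iso$label, support >= 2,
                     info = sprintf("support %d", support))
  }
  wt_only <- perfect_reads(rep(AMP$sequence, 3))
  expect_error(detect_isoforms(align_reads(perfect_reads(AMP$sequence), AMP)),
               "at least two")
})

test_that("a noiseless four-isoform mixture is recovered with truth-label frequencies", {
  clones <- list(clone_spec(0.80, label = "WT"),
                 clone_spec(0.12, events = ins35, label = "i35"),
                 clone_spec(0.06, events = ins154, label = "i154"),
                 clone_spec(0.02, events = del72, label = "d72"))
  rd <- simulate_sample(AMP, clones, 600, errors = error_model(0, 0, 0), seed = 81)
  al <- align_reads(rd, AMP)
  truth <- table(read_truth(rd)$clone)
  for (mode in c("event", "strict")) {
    iso <- detect_isoforms(al, mode = mode)
    expect_equal(nrow(iso), 4L, info = mode)
    expect_equal(sort(iso$n_reads), sort(as.integer(truth)), info = mode)
    expect_equal(iso$n_reads[iso$label == "WT"], unname(truth[["WT"]]), info = mode)
    expect_equal(sum(iso$frequency), 100, tolerance = 1e-9, info = mode)
  }
})

test_that("event annotation anchors junctions and derives frame and truncation effects", {
  ann35 <- annotate_events(ins35, AMP)
  expect_identical(ann35$junction, "ABL1-a8/ABL1-a9")
  expect_identical(ann35$frame, "frameshift")   # 35 mod 3 = 2
  expect_identical(ann35$label, "35INS")

  ann154 <- annotate_events(ins154, AMP)
  expect_identical(ann154$junction, "BCR-e14/ABL1-a2")

  ann72 <- annotate_events(del72, AMP)
  expect_identical(ann72$frame, "in-frame")     # 72 nt = 24 codons
  expect_match(ann72$label, "72DEL")

  # off-junction insertion gets a coordinate label
  off <- isoform_event("insertion", position = 900L, seq = "ACGTT")
  expect_match(annotate_events(off, AMP)$label, "5INS@901")
})

test_that("truncation flags agree with a re-translation oracle on random events", {
  set.seed(91)
  for (i in 1:25) {
    kind <- sample(c("insertion", "deletion"), 1)
    ev <- if (kind == "insertion") {
      isoform_event("insertion", position = sample(30:1500, 1),
                    seq = rand_dna(sample(1:60, 1)))
    } else {
      isoform_event("deletion", position = sample(30:1400, 1),
                    length = sample(1:60, 1))
    }
    ann <- annotate_events(ev, AMP)
    prot <- oracle_translate(with_event(ev), AMP$frame_start)
    stop_at <- regexpr("*", prot, fixed = TRUE)
    oracle_trunc <- stop_at > 0 && stop_at < nchar(prot)
    expect_identical(ann$truncating, oracle_trunc,
                     info = sprintf("%s len %d at %d", ev$kind, ev$length, ev$position))
    expect_identical(ann$frame,
                     if (ev$length %% 3 == 0) "in-frame" else "frameshift")
  }
})

test_that("event mode refines strict mode: each strict group maps into one event group", {
  clones <- list(clone_spec(0.7, label = "WT"), clone_spec(0.3, events = ins35))
  rd <- simulate_sample(AMP, clones, 300, errors = error_model(0.005, 0.002, 0.002),
                        seed = 101)
  al <- align_reads(rd, AMP)
  fl <- al[al$full_length, ]
  ev <- ampliphase:::cpp_events(fl$aln_seq, fl$cigar, fl$ref_start, 3L)
  ev_key <- rep("", nrow(fl))
  if (nrow(ev)) {
    agg <- stats::aggregate(list(sig = sprintf("%s:%d:%d", ev$kind, ev$position, ev$length)),
                            by = list(read = ev$read_idx), FUN = paste, collapse = ";")
    ev_key[agg$read] <- agg$sig
  }
  split_keys <- split(ev_key, fl$aln_seq)
  expect_true(all(vapply(split_keys, function(k) length(unique(k)) == 1L, logical(1))))
})

test_that("isoform results are invariant to read order and orientation", {
  clones <- list(clone_spec(0.7, label = "WT"), clone_spec(0.3, events = ins35))
  rd <- simulate_sample(AMP, clones, 200, errors = error_model(0, 0, 0), seed = 111)
  iso1 <- detect_isoforms(align_reads(rd, AMP), mode = "event")
  set.seed(3)
  rd2 <- rd[sample.int(nrow(rd)), ]
  rd2$sequence <- vapply(rd2$sequence, revcomp, character(1))
  iso2 <- detect_isoforms(align_reads(rd2, AMP), mode = "event")
  expect_identical(as.data.frame(iso1[, c("label", "n_reads", "frequency")]),
                   as.data.frame(iso2[, c("label", "n_reads", "frequency")]))
})

test_that("isoform tables export as TSV, JSON, FASTA and BED", {
  reads <- perfect_reads(c(rep(with_event(ins35), 3), rep(AMP$sequence, 7)))
  iso <- detect_isoforms(align_reads(reads, AMP), mode = "event")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_isoforms(iso, tsv); write_isoforms(iso, js)
  write_isoforms(iso, fa); write_isoforms(iso, bed)
  expect_equal(nrow(read.delim(tsv)), 2L)
  expect_equal(jsonlite::read_json(js)$n_full_length, 10L)
  cons <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(cons[["35INS"]]), with_event(ins35))
  expect_match(readLines(bed), "35INS")
})
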