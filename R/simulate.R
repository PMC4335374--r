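#' Specify a clone's point mutations and splice events
#'
#' A clone is one molecular species in a simulated sample: the amplicon with
#' a set of point mutations and/or isoform events applied, present at a given
#' fraction of molecules.
#'
#' @param fraction fraction of molecules in the sample drawn from this clone.
#' @param mutations data frame of point mutations (columns `position` 0-based,
#'   `ref`, `alt`, `label`), e.g. from [aa_substitution()]; `NULL` for none.
#' @param events data frame of isoform events (columns `kind`
#'   (`"insertion"`/`"deletion"`), `position` 0-based (junction point for
#'   insertions, interval start for deletions), `length`, `seq` (inserted
#'   sequence, `""` for deletions)); `NULL` for none.
#' @param label clone label used in read-id truth tags; defaults to the
#'   concatenated mutation labels, or `"WT"`.
#' @return list of class `clone_spec`.
#' @export
clone_spec <- function(fraction, mutations = NULL, events = NULL, label = NULL) {
  if (fraction < 0 || fraction > 1) abort("clone fraction must be in [0, 1]")
  mutations <- if (!is.null(mutations)) as_tibble(mutations)
  events <- if (!is.null(events)) as_tibble(events)
  if (is.null(label)) {
    label <- if (!is.null(mutations) && nrow(mutations) > 0) {
      paste(mutations$label, collapse = ".")
    } else if (!is.null(events) && nrow(events) > 0) {
      paste0("iso", paste(events$length, substr(events$kind, 1, 3), collapse = "."))
    } else "WT"
  }
  structure(list(fraction = fraction, mutations = mutations,
                 events = events, label = label),
            class = "clone_spec")
}

#' Describe an isoform event for simulation
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param position 0-based amplicon coordinate: the junction point for an
#'   insertion (inserted sequence goes before this position), the interval
#'   start for a deletion.
#' @param length event length in nt (for insertions, inferred from `seq`).
#' @param seq inserted sequence (insertions only).
#' @return one-row tibble usable in [clone_spec()]'s `events`.
#' @export
isoform_event <- function(kind = c("insertion", "deletion"), position,
                          length = nchar(seq), seq = "") {
  kind <- match.arg(kind)
  if (kind == "insertion" && !nzchar(seq)) abort("insertions need an inserted sequence")
  if (length < 1) abort("event length must be >= 1")
  tibble(kind = kind, position = as.integer(position),
         length = as.integer(length), seq = toupper(seq))
}

#' Per-base sequencing error model
#'
#' Errors are injected i.i.d. per base: a deletion with probability
#' `del_rate`, otherwise a substitution with probability `sub_rate` (uniform
#' over the three alternative bases), and after each emitted base a
#' single-base insertion with probability `ins_rate`. Defaults emulate a
#' CCS-like consensus accuracy chosen to stress minor-variant calling at
#' sub-percent frequencies.
#'
#' @param sub_rate,ins_rate,del_rate per-base rates, each in \[0, 0.2\].
#' @return list of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.013, ins_rate = 0.01, del_rate = 0.005) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) abort("error rates must be in [0, 0.2]")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate),
            class = "error_model")
}

#' PCR-recombination (chimera) model
#'
#' A chimeric read takes its prefix from one clone template and its suffix
#' from a second, independently drawn, clone template, switching at a single
#' breakpoint drawn uniformly over internal positions — the simplest model of
#' PCR-mediated template switching.
#'
#' @param rate per-read recombination probability in \[0, 1\].
#' @return list of class `chimera_model`.
#' @export
chimera_model <- function(rate = 0) {
  if (rate < 0 || rate > 1) abort("chimera rate must be in [0, 1]")
  structure(list(rate = rate), class = "chimera_model")
}

# apply a clone's mutations and events to the amplicon sequence
clone_template <- function(amplicon, clone) {
  s <- amplicon$sequence
  mu <- clone$mutations
  if (!is.null(mu) && nrow(mu) > 0) {
    if (anyDuplicated(mu$position)) abort("conflicting mutations at the same position")
    ref <- substring(s, mu$position + 1, mu$position + 1)
    if (any(ref != mu$ref)) {
      abort(sprintf("mutation ref base mismatch at position %s",
                    paste(mu$position[ref != mu$ref], collapse = ", ")))
    }
    if (any(mu$alt == mu$ref)) abort("alt base must differ from ref")
    for (i in seq_len(nrow(mu))) substr(s, mu$position[i] + 1, mu$position[i] + 1) <- mu$alt[i]
  }
  ev <- clone$events
  if (!is.null(ev) && nrow(ev) > 0) {
    ev <- ev[order(-ev$position), , drop = FALSE]  # right-to-left keeps coords valid
    for (i in seq_len(nrow(ev))) {
      p <- ev$position[i]
      if (ev$kind[i] == "insertion") {
        if (p < 0 || p > nchar(s)) abort("insertion anchor outside the amplicon")
        s <- paste0(substr(s, 1, p), ev$seq[i], substr(s, p + 1, nchar(s)))
      } else {
        if (p < 0 || p + ev$length[i] > nchar(s)) abort("deletion outside the amplicon")
        s <- paste0(substr(s, 1, p), substr(s, p + ev$length[i] + 1, nchar(s)))
      }
    }
  }
  s
}

#' Simulate a sample of CCS reads from a clone mixture
#'
#' Each read is drawn from a clone according to the clone fractions; with
#' probability `chimera$rate` it is instead a chimera of two independently
#' drawn clone templates joined at a uniform internal breakpoint. Per-base
#' errors follow [error_model()]; about half the reads are emitted
#' reverse-complemented. Read ids encode the (hidden) simulation truth so
#' that test oracles can recover it via [read_truth()]. Output is fully
#' reproducible given `seed`.
#'
#' @param amplicon an `amplicon`.
#' @param clones list of [clone_spec()]s; fractions must sum to 1.
#' @param n_reads number of reads to draw.
#' @param errors an [error_model()].
#' @param chimera a [chimera_model()].
#' @param seed integer seed (required: simulation is a reproducibility
#'   contract).
#' @param sample_id prefix for read ids.
#' @return tibble of class `ccs_reads` (`id`, `sequence`) with attribute
#'   `truth` (per-read clone labels, chimera structure, strand).
#' @export
simulate_sample <- function(amplicon, clones, n_reads, errors = error_model(),
                            chimera = chimera_model(0), seed, sample_id = "s") {
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  fr <- vapply(clones, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) abort("clone fractions must sum to 1")
  if (n_reads < 1) abort("n_reads must be >= 1")
  if (missing(seed)) abort("`seed` is required")
  labels <- vapply(clones, `[[`, character(1), "label")
  templates <- vapply(clones, function(cl) clone_template(amplicon, cl), character(1))

  withr::with_seed(seed, {
    idx_a <- sample.int(length(clones), n_reads, replace = TRUE, prob = fr)
    is_chim <- runif(n_reads) < chimera$rate
    idx_b <- integer(n_reads)
    brk <- integer(n_reads)
    if (any(is_chim)) {
      idx_b[is_chim] <- sample.int(length(clones), sum(is_chim), replace = TRUE, prob = fr)
      min_len <- pmin(nchar(templates)[idx_a[is_chim]], nchar(templates)[idx_b[is_chim]])
      brk[is_chim] <- 1L + floor(runif(sum(is_chim)) * (min_len - 1L))
    }
    strand <- ifelse(runif(n_reads) < 0.5, "-", "+")
    seqs <- cpp_simulate_reads(templates, idx_a, idx_b, brk, strand == "-",
                               errors$sub_rate, errors$ins_rate, errors$del_rate)
  })

  clone_tag <- ifelse(is_chim,
                      sprintf("%s~%s@%d", labels[idx_a], labels[pmax(idx_b, 1L)], brk),
                      labels[idx_a])
  ids <- sprintf("%s_%06d|clone=%s|chim=%d|strand=%s",
                 sample_id, seq_len(n_reads), clone_tag, as.integer(is_chim), strand)
  truth <- tibble(
    id = ids, clone = labels[idx_a],
    clone2 = ifelse(is_chim, labels[pmax(idx_b, 1L)], NA_character_),
    chimeric = is_chim, breakpoint = ifelse(is_chim, brk, NA_integer_),
    strand = strand
  )
  structure(tibble(id = ids, sequence = as.character(seqs)),
            class = c("ccs_reads", class(tibble())),
            truth = truth, sample_id = sample_id, seed = seed)
}

#' Recover simulation truth labels from read ids
#'
#' @param reads a `ccs_reads` tibble from [simulate_sample()], or a character
#'   vector of its read ids.
#' @return tibble: `id`, `clone`, `clone2` (chimera partner or `NA`),
#'   `chimeric`, `strand`.
#' @export
read_truth <- function(reads) {
  tr <- attr(reads, "truth")
  if (!is.null(tr)) return(tr)
  ids <- if (is.data.frame(reads)) reads$id else reads
  fields <- stringr::str_match(ids, "\\|clone=([^|]+)\\|chim=([01])\\|strand=([+-])")
  clone <- fields[, 2]
  chim <- fields[, 3] == "1"
  main <- ifelse(chim, sub("~.*$", "", clone), clone)
  partner <- ifelse(chim, sub("@.*$", "", sub("^[^~]*~", "", clone)), NA_character_)
  tibble(id = ids, clone = main, clone2 = partner, chimeric = chim,
         strand = fields[, 4])
}

#' Simulate a serial dilution series
#'
#' Dilutes a mutant clone mixture into a wild-type background: at dilution
#' fraction `f`, each mutant-sample clone contributes `f` times its original
#' fraction and the wild-type clones fill the remainder — the in-silico
#' equivalent of serially diluting a patient sample into a wild-type sample
#' after equalising transcript copies.
#'
#' @param mutant_clones list of [clone_spec()]s describing the undiluted
#'   mutant sample (fractions sum to 1).
#' @param wildtype_clones list of [clone_spec()]s for the background (default
#'   a single wild-type clone).
#' @param fractions strictly decreasing dilution fractions in (0, 1].
#' @param n_reads reads per sample.
#' @param errors an [error_model()].
#' @param chimera a [chimera_model()].
#' @param seed master seed; per-sample sub-seeds are derived
#'   deterministically from it.
#' @param amplicon an `amplicon`.
#' @return list of class `dilution_series`: tibble `samples` with columns
#'   `fraction`, `seed`, and a list-column `reads` of `ccs_reads`.
#' @export
make_dilution_series <- function(amplicon, mutant_clones, fractions, n_reads,
                                 wildtype_clones = list(clone_spec(1, label = "WT")),
                                 errors = error_model(), chimera = chimera_model(0),
                                 seed) {
  if (length(fractions) == 0) abort("at least one dilution fraction is required")
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must be in (0, 1]")
  if (is.unsorted(rev(fractions), strictly = TRUE)) {
    abort("fractions must be strictly decreasing")
  }
  if (inherits(mutant_clones, "clone_spec")) mutant_clones <- list(mutant_clones)
  samples <- purrr::imap(fractions, function(f, i) {
    mix <- c(
      lapply(mutant_clones, function(cl) { cl$fraction <- cl$fraction * f; cl }),
      lapply(wildtype_clones, function(cl) { cl$fraction <- cl$fraction * (1 - f); cl })
    )
    mix <- mix[vapply(mix, `[[`, numeric(1), "fraction") > 0]
    sseed <- derive_seed(seed, i)
    simulate_sample(amplicon, mix, n_reads, errors = errors, chimera = chimera,
                    seed = sseed, sample_id = sprintf("dil%g", f * 100))
  })
  structure(
    list(samples = tibble(fraction = fractions,
                          seed = vapply(seq_along(fractions), function(i) derive_seed(seed, i), integer(1)),
                          reads = samples),
         mutant_clones = mutant_clones, n_reads = n_reads,
         errors = errors, chimera = chimera, seed = seed),
    class = "dilution_series"
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %d samples (%s%%), %d reads each\n",
              nrow(x$samples), paste(x$samples$fraction * 100, collapse = "/"),
              x$n_reads))
  invisible(x)
}

#' Read and write CCS reads
#'
#' FASTQ (Sanger/Phred+33) and FASTA via Biostrings. Base qualities are not
#' used anywhere in the pipeline (filters are sequence-match based), so
#' written FASTQ carries a constant placeholder quality.
#'
#' @param reads a `ccs_reads` tibble.
#' @param path file path; format chosen by extension (`.fq`/`.fastq` vs
#'   `.fa`/`.fasta`).
#' @return `path` invisibly for the writer; a `ccs_reads` tibble for the
#'   reader.
#' @export
write_reads <- function(reads, path) {
  s <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) {
    q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(s, path)
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  s <- Biostrings::readDNAStringSet(path, format = fmt)
  structure(tibble(id = names(s), sequence = unname(as.character(s))),
            class = c("ccs_reads", class(tibble())))
}

#' Write simulation truth labels as a sidecar table
#'
#' Per-read clone assignment, chimera structure and strand, for test
#' oracles; the same information is encoded in the read ids.
#'
#' @param reads a `ccs_reads` tibble from [simulate_sample()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path) {
  utils::write.table(as.data.frame(read_truth(reads)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dilution series to disk with a sample manifest
#'
#' One FASTQ per sample plus `manifest.yaml` (sample id, dilution fraction,
#' seed, file) and one truth sidecar per sample.
#'
#' @param series a `dilution_series`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_len(nrow(series$samples)), function(i) {
    f <- series$samples$fraction[i]
    id <- sprintf("dilution_%g", f * 100)
    fq <- file.path(dir, paste0(id, ".fastq"))
    write_reads(series$samples$reads[[i]], fq)
    write_truth(series$samples$reads[[i]], file.path(dir, paste0(id, ".truth.tsv")))
    list(sample = id, fraction = f, seed = series$samples$seed[i],
         file = basename(fq), truth = paste0(id, ".truth.tsv"))
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(n_reads = series$n_reads, samples = entries), manifest)
  invisible(manifest)
}

# normalize read input to a tibble(id, sequence)
as_ccs_reads <- function(reads) {
  if (is.data.frame(reads)) {
    if (!all(c("id", "sequence") %in% names(reads))) {
      abort("read data frames need `id` and `sequence` columns")
    }
    out <- as_tibble(reads[, c("id", "sequence")])
  } else if (inherits(reads, "DNAStringSet")) {
    out <- tibble(id = names(reads) %||% as.character(seq_along(reads)),
                  sequence = as.character(reads))
  } else if (is.character(reads)) {
    out <- tibble(id = names(reads) %||% as.character(seq_along(reads)),
                  sequence = unname(reads))
  } else {
    abort("unsupported read container")
  }
  if (any(!nzchar(out$sequence)) || any(grepl("[^ACGTN]", out$sequence))) {
    abort("read sequences must be non-empty and contain only A, C, G, T, N")
  }
  out
}
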