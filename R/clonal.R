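#' Per-read mutational signatures under the perfect-flank rule
#'
#' For every called variant, a read contributes only if its aligned columns
#' over the window of `window_half_width` bases on each side of the variant
#' position (20 flanking bases in total at the default of 10, the variant
#' position itself excluded) are all perfect matches with no indels and the
#' read covers the whole window. The read's status at a variant is then `alt`
#' or `ref` according to the base at the site; any other outcome — a flank
#' mismatch or indel, an uncovered window, a deletion or third allele at the
#' site — excludes the read from composition analysis. This keeps only reads
#' of high local quality, suppressing sequencing-error artefacts in the
#' clonal composition.
#'
#' Reads need not be full-length: they must align cleanly across every
#' variant's window.
#'
#' @param alignments an `amp_alignments` tibble.
#' @param variants a `variant_calls` tibble (>= 1 row).
#' @param window_half_width flanking bases checked on each side (default 10).
#' @return tibble of class `read_signatures`: `id`, `evaluable`, `signature`
#'   (`+`-joined variant labels, `""` for none), plus one `status_<label>`
#'   column per variant with values `"ref"`, `"alt"`, `"excluded"`.
#' @export
read_signatures <- function(alignments, variants, window_half_width = 10L) {
  if (nrow(variants) == 0) abort("at least one called variant is required")
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) == 0) abort("no mapped alignments")
  amplicon <- attr(alignments, "amplicon")
  labels <- variant_labels(variants)
  st <- cpp_window_status(m$aln_seq, m$cigar, m$ref_start, amplicon$length,
                          variants$position, variants$ref, variants$alt,
                          as.integer(window_half_width))
  status_chr <- matrix(c("ref", "alt", "excluded")[st + 1L], nrow = nrow(st))
  evaluable <- rowSums(st == 2L) == 0
  sig <- vapply(seq_len(nrow(st)), function(i) {
    if (!evaluable[i]) NA_character_
    else paste(labels[st[i, ] == 1L], collapse = "+")
  }, character(1))
  out <- tibble(id = m$id, evaluable = evaluable, signature = sig)
  colnames(status_chr) <- paste0("status_", labels)
  out <- bind_cols(out, as_tibble(status_chr))
  structure(out, class = c("read_signatures", class(tibble())),
            variants = variants, window_half_width = as.integer(window_half_width))
}

variant_labels <- function(variants) {
  ifelse(is.na(variants$label),
         sprintf("%d%s>%s", variants$position + 1L, variants$ref, variants$alt),
         variants$label)
}

#' Clonal composition from read signatures
#'
#' Groups evaluable reads by identical signature set and reports each
#' signature's frequency among evaluable reads. Every variant pair is
#' classified: *compound* when the double-positive frequency reaches the
#' evidence bar (at least 2 reads and at least `pair_min_frequency` of
#' evaluable reads), *independent* when each single-positive signature
#' reaches the bar while the double stays below it, *mixed* otherwise. The
#' 0.5% default bar matches the assay's detection floor.
#'
#' @param signatures a `read_signatures` tibble.
#' @param pair_min_frequency evidence bar for pair classification (fraction
#'   of evaluable reads, default 0.005).
#' @return tibble of class `clone_table`, sorted by descending frequency:
#'   `signature`, `n_reads`, `frequency` (percent of evaluable reads).
#'   Attributes: `n_evaluable`, `n_excluded`, `pairs` (pairwise
#'   classification tibble).
#' @export
composition <- function(signatures, pair_min_frequency = 0.005) {
  ev <- signatures[signatures$evaluable, , drop = FALSE]
  n_ev <- nrow(ev)
  if (n_ev == 0) abort("zero evaluable reads: no composition can be computed")
  tab <- ev |>
    count(.data$signature, name = "n_reads") |>
    mutate(frequency = 100 * .data$n_reads / n_ev) |>
    arrange(desc(.data$frequency), .data$signature)

  variants <- attr(signatures, "variants")
  labels <- variant_labels(variants)
  pairs <- NULL
  if (length(labels) >= 2) {
    has <- function(sig, lab) {
      vapply(strsplit(sig, "+", fixed = TRUE), function(p) lab %in% p, logical(1))
    }
    bar <- max(2, pair_min_frequency * n_ev)
    combs <- utils::combn(labels, 2)
    pairs <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
      a <- combs[1, k]; b <- combs[2, k]
      in_a <- has(ev$signature, a); in_b <- has(ev$signature, b)
      n_both <- sum(in_a & in_b)
      n_a_only <- sum(in_a & !in_b)
      n_b_only <- sum(!in_a & in_b)
      class <- if (n_both >= bar) "compound"
      else if (n_a_only >= bar && n_b_only >= bar) "independent"
      else "mixed"
      tibble(label1 = a, label2 = b, class = class,
             n_both = n_both, n_only1 = n_a_only, n_only2 = n_b_only)
    })
  }
  structure(tab, class = c("clone_table", class(tibble())),
            n_evaluable = n_ev,
            n_excluded = sum(!signatures$evaluable),
            pairs = pairs, variants = variants)
}

#' @export
glance.clone_table <- function(x, ...) {
  tibble(
    n_signatures = nrow(x),
    n_evaluable = attr(x, "n_evaluable"),
    n_excluded = attr(x, "n_excluded"),
    top_signature = if (nrow(x)) x$signature[1] else NA_character_,
    top_frequency = if (nrow(x)) x$frequency[1] else NA_real_
  )
}

#' PCR-chimera diagnostic for a variant pair
#'
#' Reports the frequency of reads carrying both variants of a pair alongside
#' each single-mutant frequency and the product of the singles — the
#' double-positive rate expected by chance if the two mutations were
#' assorted independently across molecules. A double-positive rate far below
#' the individual clone frequencies (e.g. ~0.1% doubles against 91% and 4%
#' singles) indicates that PCR-mediated recombination, which would fabricate
#' compound-mutant molecules, is rare in the library.
#'
#' @param signatures a `read_signatures` tibble.
#' @param label1,label2 labels of the two variants; default the first pair.
#' @return one-row tibble: per-variant carrier frequencies (as fractions of
#'   evaluable reads), the observed double-positive rate, and the
#'   expected-by-chance product.
#' @export
chimera_diagnostic <- function(signatures, label1 = NULL, label2 = NULL) {
  variants <- attr(signatures, "variants")
  labels <- variant_labels(variants)
  if (length(labels) < 2) abort("a variant pair is required")
  label1 <- label1 %||% labels[1]
  label2 <- label2 %||% labels[2]
  ev <- signatures[signatures$evaluable, , drop = FALSE]
  parts <- strsplit(ev$signature, "+", fixed = TRUE)
  in1 <- vapply(parts, function(p) label1 %in% p, logical(1))
  in2 <- vapply(parts, function(p) label2 %in% p, logical(1))
  n <- nrow(ev)
  tibble(
    label1 = label1, label2 = label2, n_evaluable = n,
    rate1 = mean(in1), rate2 = mean(in2),
    rate_both = mean(in1 & in2),
    expected_independent = mean(in1) * mean(in2)
  )
}

#' Write a clone table as TSV or JSON
#' @param clone_table a `clone_table`.
#' @param path output file; `.json` selects JSON (including the pairwise
#'   classification and a circle-plot-style label-to-percent summary),
#'   anything else TSV.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clone_table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pairs <- attr(clone_table, "pairs")
    obj <- list(
      clones = as.data.frame(clone_table),
      n_evaluable = attr(clone_table, "n_evaluable"),
      n_excluded = attr(clone_table, "n_excluded"),
      pairs = if (!is.null(pairs)) as.data.frame(pairs),
      circle_plot = setNames(as.list(clone_table$frequency),
                             ifelse(clone_table$signature == "", "none",
                                    clone_table$signature))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(clone_table), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
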