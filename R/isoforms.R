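#' Detect splice isoforms from full-length reads
#'
#' Only full-length reads (spanning the amplicon end to end) are considered,
#' and a non-reference isoform is reported only when supported by at least
#' `min_support` independent reads (default 2).
#'
#' Two grouping modes are provided. `"strict"` implements the literal
#' identical-sequence rule: reads are grouped by exact full-length sequence
#' identity after orientation normalization — exact, but at realistic
#' per-base error rates near-duplicate full reads are rare, so strict-mode
#' frequencies understate isoform abundance on noisy data. `"event"` (the
#' default) groups reads by identical indel-event structure extracted from
#' their alignments (indel operations of at least `min_event_length` nt,
#' default 3 — comfortably above 1-2 nt sequencing-noise indels and far below
#' the smallest reported splice events of ~35 nt). Point substitutions are
#' never isoform-defining in either mode: isoform and variant analyses are
#' orthogonal.
#'
#' @param alignments an `amp_alignments` tibble with `full_length` flags.
#' @param mode `"event"` or `"strict"`.
#' @param min_support minimum supporting reads for a reported non-reference
#'   isoform.
#' @param min_event_length smallest indel (nt) treated as an isoform event.
#' @param amplicon the `amplicon`; defaults to the one stored on
#'   `alignments`.
#' @return tibble of class `isoform_table`, sorted by descending frequency:
#'   `label`, `n_reads`, `frequency` (percent of full-length reads),
#'   `n_events`, `frame`, `truncating`, and a list-column `events` of
#'   annotated event tibbles. Attributes: `mode`, `n_full_length`,
#'   `n_unassigned` (full-length reads in groups below `min_support`),
#'   `consensus` (named character vector of isoform consensus sequences).
#' @export
detect_isoforms <- function(alignments, mode = c("event", "strict"),
                            min_support = 2L, min_event_length = 3L,
                            amplicon = attr(alignments, "amplicon")) {
  mode <- match.arg(mode)
  fl <- alignments[alignments$full_length, , drop = FALSE]
  n_fl <- nrow(fl)
  if (n_fl < 2) abort("isoform detection requires at least two full-length reads")

  ev <- as_tibble(cpp_events(fl$aln_seq, fl$cigar, fl$ref_start,
                             as.integer(min_event_length)))
  if (mode == "event") {
    key <- rep("", n_fl)
    if (nrow(ev) > 0) {
      ev_sig <- ev |>
        arrange(.data$read_idx, .data$position) |>
        group_by(.data$read_idx) |>
        summarise(sig = paste(sprintf("%s:%d:%d", .data$kind, .data$position,
                                      .data$length), collapse = ";"),
                  .groups = "drop")
      key[ev_sig$read_idx] <- ev_sig$sig
    }
  } else {
    key <- fl$aln_seq
  }

  groups <- tibble(key = key) |>
    count(.data$key, name = "n_reads") |>
    arrange(desc(.data$n_reads), .data$key)
  ref_key <- if (mode == "event") "" else amplicon$sequence
  keep <- groups$n_reads >= min_support | groups$key == ref_key
  kept <- groups[keep, , drop = FALSE]

  # representative read per group, for event extraction and consensus
  rep_idx <- match(kept$key, key)
  rec <- purrr::map(seq_len(nrow(kept)), function(g) {
    ri <- rep_idx[g]
    gev <- ev[ev$read_idx == ri, c("kind", "position", "length", "seq"), drop = FALSE]
    ann <- annotate_events(gev, amplicon)
    label <- if (nrow(ann) == 0) "WT" else paste(ann$label, collapse = "+")
    list(ann = ann, label = label)
  })
  labels <- vapply(rec, `[[`, character(1), "label")
  # disambiguate identical labels from distinct groups (e.g. same-length
  # insertions of different sequence in strict mode)
  labels <- make.unique(labels, sep = "#")

  out <- tibble(
    label = labels,
    n_reads = kept$n_reads,
    frequency = 100 * kept$n_reads / n_fl,
    n_events = vapply(rec, function(r) nrow(r$ann), integer(1)),
    frame = vapply(rec, function(r) {
      if (nrow(r$ann) == 0) "in-frame"
      else if (any(r$ann$frame == "frameshift")) "frameshift" else "in-frame"
    }, character(1)),
    truncating = vapply(rec, function(r) any(r$ann$truncating), logical(1)),
    events = purrr::map(rec, "ann")
  ) |>
    arrange(desc(.data$frequency), .data$label)

  consensus <- vapply(seq_len(nrow(kept)), function(g) {
    if (mode == "strict") fl$aln_seq[rep_idx[g]]
    else apply_events(amplicon$sequence, rec[[g]]$ann)
  }, character(1))
  names(consensus) <- labels

  structure(out, class = c("isoform_table", class(tibble())),
            mode = mode, n_full_length = n_fl,
            n_unassigned = n_fl - sum(kept$n_reads),
            consensus = consensus[out$label], amplicon = amplicon)
}

#' Annotate isoform events against the exon structure
#'
#' Anchors each event to the exon map (an insertion within 3 nt of an exon
#' junction is reported at that junction, matching how splice-isoform
#' insertions between two exons present in amplicon coordinates), determines
#' the frame effect from `length mod 3`, and decides truncation by
#' translating the event-modified amplicon and scanning for a premature stop
#' codon.
#'
#' @param events tibble with columns `kind`, `position`, `length`, `seq`.
#' @param amplicon the `amplicon`.
#' @param junction_tolerance distance (nt) within which an insertion is
#'   considered junction-anchored.
#' @return the events with `junction`, `exon`, `frame`, `truncating` and
#'   `label` columns.
#' @export
annotate_events <- function(events, amplicon, junction_tolerance = 3L) {
  events <- as_tibble(events)
  n <- nrow(events)
  if (n == 0) {
    return(tibble(kind = character(0), position = integer(0), length = integer(0),
                  seq = character(0), junction = character(0), exon = character(0),
                  frame = character(0), truncating = logical(0), label = character(0)))
  }
  jn <- amplicon$junctions
  junction <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    d <- abs(jn$amp_position - events$position[i])
    if (length(d) && min(d) <= junction_tolerance) {
      k <- which.min(d)
      junction[i] <- sprintf("%s/%s", jn$upstream[k], jn$downstream[k])
    }
  }
  events$junction <- junction
  events$exon <- exon_at(amplicon, pmin(events$position, amplicon$length - 1L))$exon
  events$frame <- ifelse(events$length %% 3L == 0L, "in-frame", "frameshift")
  events$truncating <- vapply(seq_len(n), function(i) {
    mod <- apply_events(amplicon$sequence, events[i, , drop = FALSE])
    premature_stop(mod, amplicon$frame_start)
  }, logical(1))
  events$label <- ifelse(
    events$kind == "insertion",
    ifelse(is.na(events$junction),
           sprintf("%dINS@%d", events$length, events$position + 1L),
           sprintf("%dINS", events$length)),
    sprintf("%dDEL@%d-%d", events$length, events$position + 1L,
            events$position + events$length)
  )
  events
}

# apply insertion/deletion events (amplicon coordinates) to a sequence
apply_events <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  ev <- events[order(-events$position), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    p <- ev$position[i]
    if (ev$kind[i] == "insertion") {
      seq <- paste0(substr(seq, 1, p), ev$seq[i], substr(seq, p + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, p), substr(seq, p + ev$length[i] + 1, nchar(seq)))
    }
  }
  seq
}

# TRUE if the frame contains a stop codon before its final codon
premature_stop <- function(seq, frame_start) {
  prot <- translate_frame(seq, frame_start)
  if (nchar(prot) < 2) return(FALSE)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  stop_at > 0 && stop_at < nchar(prot)
}

#' @export
glance.isoform_table <- function(x, ...) {
  tibble(
    n_isoforms = nrow(x),
    n_full_length = attr(x, "n_full_length"),
    n_unassigned = attr(x, "n_unassigned"),
    mode = attr(x, "mode"),
    wt_frequency = if ("WT" %in% x$label) x$frequency[x$label == "WT"] else 0
  )
}

#' Write isoform results
#'
#' @param isoforms an `isoform_table`.
#' @param path output file: `.json` for JSON, `.fa`/`.fasta` for per-isoform
#'   consensus sequences, `.bed` for events as BED intervals in amplicon
#'   space, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_isoforms <- function(isoforms, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      isoforms = lapply(seq_len(nrow(isoforms)), function(i) {
        list(label = isoforms$label[i], n_reads = isoforms$n_reads[i],
             frequency = isoforms$frequency[i],
             events = as.data.frame(isoforms$events[[i]][, c("kind", "position", "length", "junction", "frame", "truncating")]))
      }),
      n_full_length = attr(isoforms, "n_full_length"),
      n_unassigned = attr(isoforms, "n_unassigned"),
      mode = attr(isoforms, "mode")
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (grepl("\\.f(ast)?a$", path, ignore.case = TRUE)) {
    cons <- attr(isoforms, "consensus")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cons), path)
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    amp <- attr(isoforms, "amplicon")
    ev <- dplyr::bind_rows(purrr::map2(isoforms$events, isoforms$label,
                                       function(e, l) { if (nrow(e)) mutate(e, iso = l) else NULL }))
    lines <- if (!is.null(ev) && nrow(ev)) {
      sprintf("%s\t%d\t%d\t%s|%s", amp$name, ev$position,
              ifelse(ev$kind == "deletion", ev$position + ev$length, ev$position + 1L),
              ev$iso, ev$label)
    } else character(0)
    writeLines(lines, path)
  } else {
    out <- isoforms[, c("label", "n_reads", "frequency", "n_events", "frame", "truncating")]
    utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
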