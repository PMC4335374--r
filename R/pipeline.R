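#' Pipeline run configuration
#'
#' @param reference path to a YAML reference description (see
#'   [read_reference()]).
#' @param reads path to a FASTA/FASTQ file of CCS reads, or a `ccs_reads`
#'   tibble.
#' @param output_dir directory for result tables (created if missing).
#' @param breakpoint optional breakpoint-variant override for the reference.
#' @param caller a [caller_config()].
#' @param params a [gap_params()].
#' @param window_half_width flank half-width for the composition filter.
#' @param isoform_mode `"event"` or `"strict"`.
#' @param min_support minimum reads supporting a reported isoform.
#' @param end_tolerance full-length classification slack (bases).
#' @param write_sam also write the alignments as SAM (can be large).
#' @param seed optional seed recorded in the summary (the pipeline itself is
#'   deterministic; the seed documents upstream simulation).
#' @return list of class `run_config`.
#' @export
run_config <- function(reference, reads, output_dir, breakpoint = NULL,
                       caller = caller_config(), params = gap_params(),
                       window_half_width = 10L, isoform_mode = "event",
                       min_support = 2L, end_tolerance = 5L,
                       write_sam = FALSE, seed = NULL) {
  if (is.character(reference) && !file.exists(reference)) {
    abort(sprintf("reference file not found: %s", reference))
  }
  if (is.character(reads) && !file.exists(reads)) {
    abort(sprintf("reads file not found: %s", reads))
  }
  structure(list(reference = reference, reads = reads, output_dir = output_dir,
                 breakpoint = breakpoint, caller = caller, params = params,
                 window_half_width = as.integer(window_half_width),
                 isoform_mode = isoform_mode, min_support = as.integer(min_support),
                 end_tolerance = as.integer(end_tolerance),
                 write_sam = write_sam, seed = seed),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on one sample
#'
#' Executes align -> pileup -> variant calling -> per-read phasing ->
#' isoform detection, writes all result tables (TSV/VCF/JSON/FASTA) to the
#' configured output directory plus a JSON summary, and returns the results.
#' Stage failures are reported with a stage-tagged message.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with elements `alignments`, `pileup`, `variants`,
#'   `signatures`, `clones`, `isoforms`, `summary`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  amplicon <- with_stage("reference", {
    model <- if (is.character(config$reference)) {
      read_reference(config$reference, breakpoint = config$breakpoint)
    } else config$reference
    if (inherits(model, "amplicon")) model else in_silico_pcr(model)
  })
  reads <- with_stage("input", {
    if (is.character(config$reads)) read_reads(config$reads) else as_ccs_reads(config$reads)
  })
  aln <- with_stage("align", {
    align_reads(reads, amplicon, params = config$params,
                end_tolerance = config$end_tolerance)
  })
  pu <- with_stage("pileup", pileup(aln, amplicon))
  calls <- with_stage("call", call_variants(pu, config$caller, amplicon))

  sigs <- NULL; clones <- NULL
  if (nrow(calls) > 0) {
    sigs <- with_stage("phase", {
      read_signatures(aln, calls, window_half_width = config$window_half_width)
    })
    clones <- with_stage("phase", composition(sigs))
  }
  isoforms <- with_stage("isoforms", {
    if (sum(aln$full_length) >= 2) {
      detect_isoforms(aln, mode = config$isoform_mode,
                      min_support = config$min_support, amplicon = amplicon)
    } else NULL
  })

  out <- function(f) file.path(config$output_dir, f)
  with_stage("report", {
    write_variants_tsv(calls, out("variants.tsv"))
    write_variants_vcf(calls, out("variants.vcf"), amplicon)
    if (!is.null(clones)) {
      write_clone_table(clones, out("clones.tsv"))
      write_clone_table(clones, out("clones.json"))
    }
    if (!is.null(isoforms)) {
      write_isoforms(isoforms, out("isoforms.tsv"))
      write_isoforms(isoforms, out("isoforms.json"))
      write_isoforms(isoforms, out("isoforms.fa"))
    }
    if (isTRUE(config$write_sam)) write_sam(aln, out("alignments.sam"), amplicon)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("ampliphase")),
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("reads", "output_dir"))]),
    reference = amplicon$name, breakpoint = amplicon$breakpoint,
    amplicon_length = amplicon$length,
    n_reads = nrow(reads),
    n_mapped = sum(aln$mapped), pct_mapped = 100 * mean(aln$mapped),
    n_full_length = sum(aln$full_length),
    pct_full_length = 100 * mean(aln$full_length),
    error_floor = attr(calls, "error_floor"),
    n_variants = nrow(calls),
    variants = if (nrow(calls)) {
      setNames(as.list(round(100 * calls$frequency, 4)),
               ifelse(is.na(calls$label),
                      sprintf("%d%s>%s", calls$position + 1L, calls$ref, calls$alt),
                      calls$label))
    } else list(),
    clones = if (!is.null(clones)) {
      setNames(as.list(round(clones$frequency, 4)),
               ifelse(clones$signature == "", "none", clones$signature))
    },
    n_excluded_reads = if (!is.null(clones)) attr(clones, "n_excluded"),
    isoforms = if (!is.null(isoforms)) {
      setNames(as.list(round(isoforms$frequency, 4)), isoforms$label)
    },
    seed = config$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(alignments = aln, pileup = pu, variants = calls,
                 signatures = sigs, clones = clones, isoforms = isoforms,
                 summary = summary))
}
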