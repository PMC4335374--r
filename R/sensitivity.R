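#' Run the serial-dilution sensitivity experiment
#'
#' Aligns, piles up and calls variants in every sample of a dilution series,
#' marks each tracked variant detected or not per sample, derives per-variant
#' detection limits, and tallies calls at untracked positions as false
#' positives.
#'
#' The detection limit is the smallest expected fraction from which the
#' variant is detected in an unbroken run down from the largest fraction: a
#' detection below an undetected fraction does not lower the limit.
#'
#' @param series a `dilution_series` from [make_dilution_series()], or a
#'   tibble with columns `fraction` and `reads` (list of `ccs_reads` or file
#'   paths).
#' @param tracked tibble of tracked variants: `position` (0-based), `ref`,
#'   `alt`, `label`, and `carrier_fraction` — the fraction of mutant-sample
#'   molecules carrying the variant, so that its expected frequency in a
#'   sample equals `dilution fraction x carrier_fraction`. If omitted, it is
#'   reconstructed from the series' clone specifications.
#' @param amplicon the `amplicon` reads were simulated from / align to.
#' @param config a [caller_config()].
#' @param params,band_pad alignment settings passed to [align_reads()].
#' @return object of class `sensitivity_report`: list with `results` (one
#'   row per tracked variant per sample: expected and observed percent,
#'   detected flag), `detection_limits` (per variant, percent expected
#'   frequency or `NA` when never reliably detected), `false_positives`
#'   (total untracked calls across samples), `n_samples`, and the per-sample
#'   call tables.
#' @export
run_sensitivity <- function(series, amplicon, tracked = NULL,
                            config = caller_config(), params = gap_params(),
                            band_pad = 12L) {
  samples <- if (inherits(series, "dilution_series")) series$samples else as_tibble(series)
  if (is.null(tracked)) {
    if (!inherits(series, "dilution_series")) {
      abort("`tracked` is required when `series` is not a dilution_series")
    }
    tracked <- tracked_from_clones(series$mutant_clones)
  }
  tracked <- as_tibble(tracked)

  per_sample <- purrr::map(seq_len(nrow(samples)), function(i) {
    reads <- samples$reads[[i]]
    if (is.character(reads)) {
      if (!file.exists(reads)) abort(sprintf("missing sample file: %s", reads))
      reads <- read_reads(reads)
    }
    aln <- align_reads(reads, amplicon, params = params, band_pad = band_pad)
    calls <- call_variants(pileup(aln, amplicon), config, amplicon)
    calls
  })

  results <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    calls <- per_sample[[i]]
    hit <- match(paste(tracked$position, tracked$alt),
                 paste(calls$position, calls$alt))
    tibble(
      fraction = samples$fraction[i],
      label = tracked$label,
      expected_pct = 100 * samples$fraction[i] * tracked$carrier_fraction,
      detected = !is.na(hit),
      observed_pct = ifelse(is.na(hit), NA_real_, 100 * calls$frequency[hit]),
      observed_adj_pct = ifelse(is.na(hit), NA_real_, 100 * calls$freq_adjusted[hit])
    )
  })

  limits <- results |>
    group_by(.data$label) |>
    arrange(desc(.data$expected_pct), .by_group = TRUE) |>
    summarise(detection_limit_pct = unbroken_limit(.data$expected_pct, .data$detected),
              .groups = "drop")

  fp <- sum(vapply(per_sample, function(calls) {
    sum(!paste(calls$position, calls$alt) %in%
          paste(tracked$position, tracked$alt))
  }, numeric(1)))

  structure(
    list(results = results, detection_limits = limits,
         false_positives = fp, n_samples = nrow(samples),
         calls = per_sample, tracked = tracked, config = config),
    class = "sensitivity_report"
  )
}

# smallest expected fraction of the unbroken detected run from the top
unbroken_limit <- function(expected_sorted_desc, detected) {
  if (length(detected) == 0 || !detected[1]) return(NA_real_)
  run <- cumprod(detected) == 1
  min(expected_sorted_desc[run])
}

# tracked-variant table implied by the mutant-sample clone specs
tracked_from_clones <- function(clones) {
  rows <- purrr::map_dfr(clones, function(cl) {
    if (is.null(cl$mutations) || nrow(cl$mutations) == 0) return(NULL)
    mutate(cl$mutations, fraction = cl$fraction)
  })
  if (is.null(rows) || nrow(rows) == 0) abort("no tracked mutations in the mutant clones")
  rows |>
    group_by(.data$position, .data$ref, .data$alt, .data$label) |>
    summarise(carrier_fraction = sum(.data$fraction), .groups = "drop")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d samples, %d tracked variants, %d false positive(s)\n",
              x$n_samples, nrow(x$detection_limits), x$false_positives))
  lim <- x$detection_limits
  for (i in seq_len(nrow(lim))) {
    cat(sprintf("  %s: detection limit %s%% expected frequency\n",
                lim$label[i],
                ifelse(is.na(lim$detection_limit_pct[i]), "not reached at any",
                       format(lim$detection_limit_pct[i]))))
  }
  invisible(x)
}

#' @export
tidy.sensitivity_report <- function(x, ...) x$results

#' @export
glance.sensitivity_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$detection_limits,
                             names_from = "label",
                             values_from = "detection_limit_pct",
                             names_prefix = "limit_pct_")
  bind_cols(tibble(n_samples = x$n_samples,
                   false_positives = x$false_positives), wide)
}

#' Write a sensitivity report as JSON plus a human-readable table
#' @param report a `sensitivity_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path) {
  obj <- list(
    results = as.data.frame(report$results),
    detection_limits = as.data.frame(report$detection_limits),
    false_positives = report$false_positives,
    n_samples = report$n_samples
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
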