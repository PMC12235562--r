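#' Run the spectral pipeline for one subject
#'
#' Chains artifact rejection (optional), windowed spectra, aperiodic fits
#' and cue-induced shifts for a single subject's epochs.
#'
#' @param es an `epochset` (one subject).
#' @param cfg an `analysis_config`.
#' @param reject apply [reject_epochs()] first?
#' @param by_cue split spectra by cue type (`TRUE`) or pool all trials
#'   (`FALSE`, cue type `"all"`).
#' @param variants spectrum variants to fit.
#' @return list with elements `spectra` (a `spectrum_set`), `slopes`
#'   (slope table) and `shifts` (shift table, ERP-removed variant).
#' @export
run_pipeline <- function(es, cfg = analysis_config(), reject = TRUE,
                         by_cue = TRUE,
                         variants = c("total", "erp_removed")) {
  if (reject) es <- reject_epochs(es, cfg)
  ss <- compute_spectrumset(es, cfg, by_cue = by_cue)
  st <- fit_spectrumset(ss, cfg, variants = variants)
  sh <- compute_shifts(st, baseline = cfg$baseline_window,
                       variant = if ("erp_removed" %in% variants)
                         "erp_removed" else variants[1])
  list(spectra = ss, slopes = st, shifts = sh)
}

#' Slope and shift tables for a simulated cohort
#'
#' Synthesizes each subject's epochs, runs the spectral pipeline and
#' stacks the per-subject slope and shift tables, attaching the age group.
#' The workhorse behind the package's recovery experiments.
#'
#' @param truths list of `sim_truth` objects (see [simulate_cohort()]).
#' @param cfg an `analysis_config`.
#' @param design a shared trial design, or `NULL` to generate one per
#'   subject from `design` spec `dspec`.
#' @param dspec `design_spec` used when `design` is `NULL`.
#' @param channels channels to synthesize.
#' @param by_cue split by cue type (default `FALSE`: pooled, faster and
#'   matching analyses collapsed over cue types).
#' @return list with `slopes` and `shifts` data.frames (columns include
#'   `age_group`).
#' @export
cohort_tables <- function(truths, cfg = analysis_config(), design = NULL,
                          dspec = design_spec(n_strategic_blocks = 1,
                                              n_affective_blocks = 1,
                                              trials_per_block = 20),
                          channels = "Cz", by_cue = FALSE) {
  res <- lapply(truths, function(tr) {
    des <- if (is.null(design)) generate_design(dspec, seed = tr$seed)
           else design
    es <- synthesize_epochs(tr, des, cfg, channels = channels)
    out <- run_pipeline(es, cfg, reject = FALSE, by_cue = by_cue)
    out$slopes$age_group <- tr$age_group
    out$shifts$age_group <- tr$age_group
    out
  })
  list(slopes = do.call(rbind, lapply(res, `[[`, "slopes")),
       shifts = do.call(rbind, lapply(res, `[[`, "shifts")))
}

#' Verify the Jensen inequality on a spectrum set
#'
#' For every (subject, window, channel, cue type) key, the trial-averaged
#' total power must be at least the ERP power at every bin (the mean of
#' squared magnitudes bounds the squared magnitude of the mean), within a
#' relative tolerance.
#'
#' @param ss a `spectrum_set`.
#' @param rtol relative tolerance.
#' @return `TRUE` invisibly if the invariant holds; otherwise an error.
#' @export
check_jensen <- function(ss, rtol = 1e-12) {
  key <- interaction(ss$index$subject, ss$index$window, ss$index$channel,
                     ss$index$cue_type, drop = TRUE)
  for (k in levels(key)) {
    rows <- which(key == k)
    tot <- ss$power[rows[ss$index$variant[rows] == "total"], ]
    erp <- ss$power[rows[ss$index$variant[rows] == "erp"], ]
    if (any(erp - tot > rtol * pmax(tot, .Machine$double.xmin)))
      stop("Jensen violation for key ", k, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read pipeline tables as TSV
#'
#' Tab-separated, UTF-8, header row, `.` decimal separator, `NA` for
#' missing values: the on-disk format of all tabular pipeline outputs.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
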