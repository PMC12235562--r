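#' Default analysis configuration
#'
#' Builds the `analysis_config` object holding every tunable setting of the
#' pipeline: epoch windowing, FFT length and analysis band, spectral
#' parameterization settings, artifact-rejection thresholds, behavioral
#' trimming bounds, permutation count, RNG seed, electrode clusters and
#' fit-quality QC threshold.
#'
#' The defaults reproduce the published analysis settings this package
#' implements: four 500-ms windows partitioning the -500..1498 ms epoch,
#' a 256-point zero-padded FFT (1.95-Hz resolution), analysis band
#' 1.95-44.92 Hz, fixed-mode parameterization with peak width limits 3-8 Hz,
#' at most 3 peaks and a 2-SD peak threshold, 200 uV peak-to-peak artifact
#' rejection in sliding 600-ms windows stepped by 100 ms, reaction-time
#' trimming at 200/1400 ms, 10,000 permutations and a model-R2 QC threshold
#' of 0.90.
#'
#' Window intervals are half-open `[start, end)` in ms so that the four
#' windows partition the 2-ms sample grid cleanly.
#'
#' @param ... named overrides for any configuration field (unknown names
#'   are an error).
#' @return an object of class `analysis_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$fft_len
#' analysis_config(freq_hi = 40)$freq_hi
analysis_config <- function(...) {
  cfg <- list(
    windows = list(
      pre_cue     = c(-500, 0),
      post_cue_1  = c(0, 500),
      post_cue_2  = c(500, 1000),
      post_cue_3  = c(1000, 1500)
    ),
    baseline_window = "pre_cue",
    fft_len = 256L,
    freq_lo = 1.95,
    freq_hi = 44.92,
    peak_width_limits = c(3, 8),   # full width, Hz; Gaussian SD bounds are half
    max_n_peaks = 3L,
    peak_threshold = 2,            # in SD of the flattened spectrum
    aperiodic_mode = "fixed",
    artifact_threshold_uv = 200,
    artifact_window_ms = 600,
    artifact_step_ms = 100,
    prev_rt_max_ms = 1400,
    rt_min_ms = 200,
    rt_max_ms = 1400,
    n_permutations = 10000L,
    seed = 1L,
    clusters = list(
      fronto_central = c("F3", "F1", "Fz", "F2", "F4",
                         "FC3", "FC1", "FCz", "FC2", "FC4",
                         "C3", "C1", "Cz", "C2", "C4"),
      centro_parietal = c("CP3", "CP1", "CPz", "CP2", "CP4",
                          "P3", "P1", "Pz", "P2", "P4")
    ),
    qc_r2_threshold = 0.90,
    excluded_channels = c("P7", "P8", "PO7", "PO8")
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           "; accepted keys are: ", paste(names(cfg), collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg <- validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  wl <- cfg$windows
  if (!length(wl) || is.null(names(wl)))
    stop("windows must be a named list of [start, end) pairs (ms)", call. = FALSE)
  for (w in names(wl)) {
    b <- as.numeric(wl[[w]])
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("window '", w, "' must be a finite [start, end) pair with start < end",
           call. = FALSE)
    cfg$windows[[w]] <- b
  }
  ## non-overlap of half-open intervals
  ord <- order(vapply(cfg$windows, `[`, numeric(1), 1))
  bnd <- do.call(rbind, cfg$windows[ord])
  if (nrow(bnd) > 1 && any(bnd[-1, 1] < bnd[-nrow(bnd), 2]))
    stop("window intervals overlap", call. = FALSE)
  if (!cfg$baseline_window %in% names(cfg$windows))
    stop("baseline_window '", cfg$baseline_window, "' is not a defined window",
         call. = FALSE)

  cfg$fft_len <- as.integer(cfg$fft_len)
  num_pos <- c("fft_len", "artifact_threshold_uv", "artifact_window_ms",
               "artifact_step_ms", "prev_rt_max_ms", "rt_min_ms", "rt_max_ms",
               "n_permutations", "peak_threshold", "qc_r2_threshold",
               "max_n_peaks")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("configuration value '", k, "' must be a single positive number",
           call. = FALSE)
  }
  if (!is.numeric(cfg$freq_lo) || !is.numeric(cfg$freq_hi) ||
      cfg$freq_lo <= 0 || cfg$freq_lo >= cfg$freq_hi)
    stop("require 0 < freq_lo < freq_hi", call. = FALSE)
  pw <- as.numeric(cfg$peak_width_limits)
  if (length(pw) != 2 || any(pw <= 0) || pw[1] >= pw[2])
    stop("peak_width_limits must be increasing positive [lo, hi] (Hz)",
         call. = FALSE)
  cfg$peak_width_limits <- pw
  if (!identical(cfg$aperiodic_mode, "fixed"))
    stop("only aperiodic_mode = 'fixed' is supported", call. = FALSE)
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  cfg$max_n_peaks <- as.integer(cfg$max_n_peaks)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load an analysis configuration from a TOML file
#'
#' An empty file yields the full default configuration (see
#' [analysis_config()]). Keys present in the file override the corresponding
#' defaults; unknown keys are an error that lists the accepted keys. The
#' `windows` and `clusters` tables, when given, replace the defaults
#' entirely.
#'
#' @param path path to a TOML file.
#' @return an `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- RcppTOML::parseTOML(path)
  raw <- unclass(raw)
  attr(raw, "file") <- NULL
  if (!is.null(raw$windows))
    raw$windows <- lapply(raw$windows, as.numeric)
  if (!is.null(raw$clusters))
    raw$clusters <- lapply(raw$clusters, as.character)
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  windows      :",
      paste(sprintf("%s [%g, %g)", names(x$windows),
                    vapply(x$windows, `[`, numeric(1), 1),
                    vapply(x$windows, `[`, numeric(1), 2)),
            collapse = ", "), "\n")
  cat(sprintf("  fft_len %d | band %.2f-%.2f Hz | mode %s\n",
              x$fft_len, x$freq_lo, x$freq_hi, x$aperiodic_mode))
  cat(sprintf("  peaks: width %g-%g Hz, max %d, threshold %g SD\n",
              x$peak_width_limits[1], x$peak_width_limits[2],
              x$max_n_peaks, x$peak_threshold))
  cat(sprintf("  artifact %g uV (%g/%g ms) | RT trim %g-%g ms | prev RT > %g ms\n",
              x$artifact_threshold_uv, x$artifact_window_ms, x$artifact_step_ms,
              x$rt_min_ms, x$rt_max_ms, x$prev_rt_max_ms))
  cat(sprintf("  %d permutations | seed %d | QC R2 >= %.2f\n",
              x$n_permutations, x$seed, x$qc_r2_threshold))
  invisible(x)
}
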