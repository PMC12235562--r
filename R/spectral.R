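#' Single-segment FFT power spectrum
#'
#' Zero-pads the segment to `fft_len` points, takes the discrete Fourier
#' transform and returns one-sided linear power per retained bin. The
#' normalization convention is `power = |X_k|^2 * 2 / n_eff^2` with `n_eff`
#' the pre-padding segment length, so a unit-amplitude sinusoid at a bin
#' frequency carries power ~0.5 at that bin. Bin spacing is
#' `srate / fft_len`. Band endpoints are compared at 0.01-Hz precision, the
#' precision at which analysis bands are conventionally quoted (the 23rd bin
#' of a 256-point transform at 500 Hz, 44.921875 Hz, is the bin "44.92 Hz").
#'
#' @param segment numeric vector (uV), length <= `fft_len`.
#' @param srate sampling rate (Hz).
#' @param fft_len transform length (points); the segment is zero-padded to
#'   this length, never truncated.
#' @param band `c(lo, hi)` analysis band in Hz; bins with
#'   `lo <= f <= hi` (at 0.01-Hz precision) are retained.
#' @return an object of class `power_spectrum`: list with `freqs`, `power`,
#'   `n_trials` (= 1) and `meta` (variant `"total"`).
#' @export
#' @examples
#' ps <- fft_power(sin(2 * pi * 10 * (0:249) / 500), 500, 256, c(1.95, 44.92))
#' ps$freqs[which.max(ps$power)]  # ~10 Hz
fft_power <- function(segment, srate, fft_len, band) {
  if (length(segment) > fft_len)
    stop("segment longer than fft_len (", length(segment), " > ", fft_len,
         "); refusing to truncate", call. = FALSE)
  if (!all(is.finite(segment)))
    stop("segment contains non-finite values", call. = FALSE)
  pw <- drop(fft_power_matrix(matrix(segment, nrow = 1), srate, fft_len, band)$power)
  freqs <- fft_band_freqs(srate, fft_len, band)
  power_spectrum(freqs, pw, variant = "total", n_trials = 1L)
}

## Frequencies of the retained bins (band compared at 0.01-Hz precision).
fft_band_freqs <- function(srate, fft_len, band) {
  f <- (0:(fft_len %/% 2)) * srate / fft_len
  f[round(f, 2) >= band[1] & round(f, 2) <= band[2]]
}

## Vectorized per-trial power: segs is trials x samples; returns list with
## freqs and power (trials x bins). Shared by fft_power and the pipeline.
fft_power_matrix <- function(segs, srate, fft_len, band) {
  n_eff <- ncol(segs)
  if (n_eff > fft_len)
    stop("segment longer than fft_len", call. = FALSE)
  padded <- matrix(0, nrow = fft_len, ncol = nrow(segs))
  padded[seq_len(n_eff), ] <- t(segs)
  X <- stats::mvfft(padded)
  f <- (0:(fft_len %/% 2)) * srate / fft_len
  keep <- which(round(f, 2) >= band[1] & round(f, 2) <= band[2])
  pw <- t(Mod(X[keep, , drop = FALSE])^2) * 2 / n_eff^2
  list(freqs = f[keep], power = pw)
}

#' @rdname fft_power
#' @param freqs,power,variant,n_trials,meta fields of a spectrum object
#'   (constructor for internal and advanced use).
#' @export
power_spectrum <- function(freqs, power, variant = "total", n_trials = 1L,
                           meta = list()) {
  if (length(freqs) != length(power))
    stop("freqs and power lengths differ", call. = FALSE)
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 variant = variant, n_trials = as.integer(n_trials),
                 meta = meta),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum: %s> %d bins, %.2f-%.2f Hz, n_trials = %d\n",
              x$variant, length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_trials))
  invisible(x)
}

#' Average per-trial spectra into a total spectrum
#'
#' Per-bin arithmetic mean of linear power across trials.
#'
#' @param spectra a list of `power_spectrum` objects sharing identical
#'   frequency axes, or a trials x bins power matrix.
#' @param freqs frequency axis, required when `spectra` is a matrix.
#' @return a `power_spectrum` of variant `"total"` with `n_trials` set.
#' @export
average_spectra <- function(spectra, freqs = NULL) {
  if (is.matrix(spectra)) {
    if (is.null(freqs))
      stop("freqs required when averaging a power matrix", call. = FALSE)
    if (nrow(spectra) < 1) stop("need at least one trial", call. = FALSE)
    return(power_spectrum(freqs, colMeans(spectra), variant = "total",
                          n_trials = nrow(spectra)))
  }
  if (!length(spectra)) stop("need at least one trial", call. = FALSE)
  f0 <- spectra[[1]]$freqs
  for (ps in spectra)
    if (!isTRUE(all.equal(ps$freqs, f0, tolerance = 1e-12)))
      stop("inconsistent frequency axes across trials", call. = FALSE)
  pw <- colMeans(do.call(rbind, lapply(spectra, `[[`, "power")))
  power_spectrum(f0, pw, variant = "total", n_trials = length(spectra))
}

#' Spectrum of the event-related potential
#'
#' Averages trials in the time domain first (the ERP, i.e. the phase-locked
#' response), then computes its power spectrum with [fft_power()].
#'
#' @param trials trials x samples matrix of voltage (uV), one channel.
#' @inheritParams fft_power
#' @return a `power_spectrum` of variant `"erp"`.
#' @export
erp_spectrum <- function(trials, srate, fft_len, band) {
  if (!is.matrix(trials) || nrow(trials) < 1)
    stop("need a trials x samples matrix with >= 1 trial", call. = FALSE)
  ps <- fft_power(colMeans(trials), srate, fft_len, band)
  ps$variant <- "erp"
  ps$n_trials <- nrow(trials)
  ps
}

#' Remove the ERP spectrum from a total power spectrum
#'
#' Per-bin difference `total - erp`, isolating induced (non-phase-locked)
#' power. When both spectra come from the same trial set the difference is
#' nonnegative up to floating error (the mean of squared magnitudes is at
#' least the squared magnitude of the mean); negative residuals beyond a
#' 1e-12 relative tolerance therefore signal mismatched trial sets and
#' raise a consistency error, while tiny negatives are clamped to 0.
#'
#' @param total a `power_spectrum` of variant `"total"` (trial-averaged).
#' @param erp the `power_spectrum` of the same trials' ERP.
#' @return a `power_spectrum` of variant `"erp_removed"`.
#' @export
remove_erp_spectrum <- function(total, erp) {
  if (!isTRUE(all.equal(total$freqs, erp$freqs, tolerance = 1e-12)))
    stop("frequency axes of total and ERP spectra differ", call. = FALSE)
  diffp <- total$power - erp$power
  tol <- 1e-12 * pmax(total$power, .Machine$double.xmin)
  if (any(diffp < -tol))
    stop("consistency error: ERP power exceeds mean trial power beyond ",
         "floating tolerance; total and ERP spectra must come from the ",
         "same trial set", call. = FALSE)
  diffp[diffp < 0] <- 0
  power_spectrum(total$freqs, diffp, variant = "erp_removed",
                 n_trials = total$n_trials)
}

#' Reject artifactual and post-slow-response epochs
#'
#' Two rejection rules: (1) any channel's peak-to-peak voltage within any
#' sliding window (default 600-ms width, 100-ms step) exceeds the artifact
#' threshold (default 200 uV); (2) the preceding trial's response latency
#' exceeded `prev_rt_max_ms` (late response-related activity would distort
#' the pre-cue baseline). Trials with correct and incorrect responses are
#' both retained. Counts removed per rule are reported via [message()].
#'
#' @param es an `epochset`.
#' @param cfg an `analysis_config`.
#' @return the `epochset` restricted to retained trials, with an attribute
#'   `rejection` holding the per-rule counts.
#' @export
reject_epochs <- function(es, cfg = analysis_config()) {
  validate_epochset(es)
  nt <- dim(es$data)[1]; nc <- dim(es$data)[2]; ns <- dim(es$data)[3]
  wlen <- round(cfg$artifact_window_ms * es$srate / 1000)
  wstep <- round(cfg$artifact_step_ms * es$srate / 1000)
  if (wlen > ns)
    stop("artifact window (", cfg$artifact_window_ms,
         " ms) longer than the epoch", call. = FALSE)
  artifact <- rep(FALSE, nt)
  if (nt > 0) {
    flat <- matrix(es$data, nrow = nt * nc)   # (trial,channel) x sample
    starts <- seq(1, ns - wlen + 1, by = wstep)
    ptp <- rep(0, nt * nc)
    for (s in starts) {
      seg <- flat[, s:(s + wlen - 1), drop = FALSE]
      hi <- seg[cbind(seq_len(nrow(seg)), max.col(seg, ties.method = "first"))]
      lo <- -(-seg)[cbind(seq_len(nrow(seg)),
                          max.col(-seg, ties.method = "first"))]
      ptp <- pmax(ptp, hi - lo)
    }
    artifact <- apply(matrix(ptp > cfg$artifact_threshold_uv, nrow = nt), 1, any)
  }
  slow_prev <- !is.na(es$trials$prev_rt) & es$trials$prev_rt > cfg$prev_rt_max_ms
  keep <- !(artifact | slow_prev)
  message(sprintf(
    "reject_epochs: %d/%d removed (%d artifact > %g uV, %d preceding RT > %g ms)",
    sum(!keep), nt, sum(artifact), cfg$artifact_threshold_uv,
    sum(slow_prev & !artifact), cfg$prev_rt_max_ms))
  out <- subset_trials(es, keep)
  attr(out, "rejection") <- c(artifact = sum(artifact),
                              slow_prev = sum(slow_prev & !artifact),
                              retained = sum(keep))
  out
}

#' Cut epochs into the configured analysis windows
#'
#' Window bounds are half-open `[start, end)` ms, so a sample at exactly a
#' boundary belongs to the later window only. With the default
#' configuration this yields four 250-sample windows partitioning the
#' epoch. Windows that do not partition the epoch are accepted with a
#' warning.
#'
#' @param es an `epochset`.
#' @param cfg an `analysis_config`.
#' @return named list mapping window label to a trials x channels x samples
#'   array.
#' @export
window_epochs <- function(es, cfg = analysis_config()) {
  validate_epochset(es)
  t0 <- min(es$times); t1 <- max(es$times)
  out <- list()
  used <- rep(FALSE, length(es$times))
  for (w in names(cfg$windows)) {
    b <- cfg$windows[[w]]
    if (b[1] < t0 - 1e-9 || b[2] > t1 + 1000 / es$srate + 1e-9)
      stop("window '", w, "' [", b[1], ", ", b[2],
           ") lies outside the epoch (", t0, "..", t1, " ms)", call. = FALSE)
    idx <- which(es$times >= b[1] - 1e-9 & es$times < b[2] - 1e-9)
    used[idx] <- TRUE
    out[[w]] <- es$data[, , idx, drop = FALSE]
  }
  ns <- vapply(out, function(a) dim(a)[3], integer(1))
  if (!all(used) || length(unique(ns)) > 1)
    warning("configured windows do not partition the epoch into equal ",
            "segments (sample counts: ", paste(ns, collapse = ", "), ")",
            call. = FALSE)
  out
}

#' Compute the full spectrum set for one subject's epochs
#'
#' For every analysis window, channel and cue type: per-trial total power
#' spectra are averaged across trials (`total`); trials are averaged in the
#' time domain and transformed (`erp`); and the ERP spectrum is subtracted
#' (`erp_removed`). All three variants share one frequency axis.
#'
#' @param es an `epochset` (one subject; trials already selected/rejected).
#' @param cfg an `analysis_config`.
#' @param by_cue split trials by cue type (default) or pool all trials
#'   under cue type `"all"`.
#' @return a `spectrum_set`: list with `freqs`, `index` (data.frame with
#'   columns subject, window, channel, cue_type, variant, n_trials) and
#'   `power` (matrix, one row per index row).
#' @export
compute_spectrumset <- function(es, cfg = analysis_config(), by_cue = TRUE) {
  validate_epochset(es)
  if (nrow(es$trials) == 0) stop("no trials to analyze", call. = FALSE)
  subject <- as.character(unique(es$trials$subject))
  if (length(subject) != 1)
    stop("compute_spectrumset expects a single subject per epochset",
         call. = FALSE)
  wins <- window_epochs(es, cfg)
  groups <- if (by_cue) split(seq_len(nrow(es$trials)), es$trials$cue_type)
            else list(all = seq_len(nrow(es$trials)))
  freqs <- fft_band_freqs(es$srate, cfg$fft_len, c(cfg$freq_lo, cfg$freq_hi))
  idx <- list(); pw <- list(); r <- 0L
  for (w in names(wins)) {
    for (cue in names(groups)) {
      tr <- groups[[cue]]
      for (ch in seq_along(es$channels)) {
        segs <- matrix(wins[[w]][tr, ch, ], nrow = length(tr))
        per_trial <- fft_power_matrix(segs, es$srate, cfg$fft_len,
                                      c(cfg$freq_lo, cfg$freq_hi))$power
        tot <- colMeans(per_trial)
        erp <- drop(fft_power_matrix(matrix(colMeans(segs), nrow = 1),
                                     es$srate, cfg$fft_len,
                                     c(cfg$freq_lo, cfg$freq_hi))$power)
        rem <- tot - erp
        rem[rem < 0 & rem > -1e-12 * pmax(tot, .Machine$double.xmin)] <- 0
        if (any(rem < 0))
          stop("consistency error: ERP power exceeds mean trial power",
               call. = FALSE)
        for (v in c("total", "erp", "erp_removed")) {
          r <- r + 1L
          idx[[r]] <- data.frame(subject = subject, window = w,
                                 channel = es$channels[ch], cue_type = cue,
                                 variant = v, n_trials = length(tr),
                                 stringsAsFactors = FALSE)
          pw[[r]] <- switch(v, total = tot, erp = erp, erp_removed = rem)
        }
      }
    }
  }
  structure(list(freqs = freqs, index = do.call(rbind, idx),
                 power = do.call(rbind, pw)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bins (%.2f-%.2f Hz)\n",
              nrow(x$index), length(x$freqs), min(x$freqs), max(x$freqs)))
  cat("  windows:", paste(unique(x$index$window), collapse = ", "), "\n")
  cat("  channels:", length(unique(x$index$channel)),
      "| cue types:", paste(unique(x$index$cue_type), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a spectrum set to a long data.frame
#'
#' @param x a `spectrum_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per (spectrum, frequency bin).
#' @export
as.data.frame.spectrum_set <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  nb <- length(x$freqs)
  out <- x$index[rep(seq_len(nrow(x$index)), each = nb), , drop = FALSE]
  out$freq <- rep(x$freqs, nrow(x$index))
  out$power <- as.vector(t(x$power))
  rownames(out) <- NULL
  out
}
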