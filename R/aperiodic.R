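#' Fixed-mode spectral parameterization
#'
#' Decomposes a power spectrum into an aperiodic 1/f^x component plus up to
#' `max_n_peaks` Gaussian oscillatory peaks, fit in log10-power /
#' log10-frequency space. The model is
#' `log10 P(f) = b - x * log10(f) + sum_k h_k exp(-(f - c_k)^2 / (2 s_k^2))`
#' with offset `b`, positive exponent `x` (the log-log slope is `-x`), and
#' peaks parameterized by center (Hz), height (log10 power) and SD (Hz).
#'
#' Algorithm: (1) an initial least-squares line is refit robustly using only
#' points whose positive residual falls at or below a low percentile
#' (2.5%), so peaks do not drag the aperiodic estimate up; (2) the robust
#' line is subtracted to give the flattened spectrum; (3) peaks are located
#' iteratively at the flattened maximum and accepted while the height
#' exceeds `peak_threshold` times the SD of the current flattened spectrum;
#' each is fit by bounded least squares and subtracted; (4) peaks whose
#' center lies within one SD-bound of a band edge are discarded, and the
#' survivors are refit jointly; (5) the joint peak model is subtracted from
#' the original log spectrum and the aperiodic line refit on the
#' peak-removed spectrum; (6) R^2 is the squared Pearson correlation
#' between modeled and observed log10 power.
#'
#' @param ps a `power_spectrum`, or a list with `freqs` and `power`.
#' @param settings an `analysis_config` (fields `peak_width_limits`,
#'   `max_n_peaks`, `peak_threshold` are used).
#' @return an `aperiodic_fit`: list with `offset`, `exponent` (positive
#'   `x`; slope is `-exponent`), `peaks` (data.frame center/height/sd),
#'   `r2`, `fit_error` (mean absolute log10 residual) and `converged`.
#' @export
#' @examples
#' f <- (1:23) * 500 / 256
#' ps <- power_spectrum(f, 10^(1 - 1.5 * log10(f)))
#' fit <- fit_spectrum(ps)
#' c(fit$offset, fit$exponent)  # ~1, ~1.5
fit_spectrum <- function(ps, settings = analysis_config()) {
  freqs <- ps$freqs
  power <- ps$power
  if (!all(is.finite(power)))
    stop("input error: non-finite power values", call. = FALSE)
  usable <- power > 0
  if (any(!usable))
    warning(sum(!usable), " zero/negative power bin(s) excluded from fitting",
            call. = FALSE)
  freqs <- freqs[usable]; power <- power[usable]
  if (length(freqs) < 5) {
    warning("fewer than 5 usable bins; fit not attempted", call. = FALSE)
    return(structure(list(offset = NA_real_, exponent = NA_real_,
                          peaks = empty_peaks(), r2 = NA_real_,
                          fit_error = NA_real_, converged = FALSE),
                     class = "aperiodic_fit"))
  }
  logf <- log10(freqs)
  logp <- log10(power)
  sd_lo <- settings$peak_width_limits[1] / 2
  sd_hi <- settings$peak_width_limits[2] / 2

  ap <- robust_ap_fit(logf, logp)
  flat <- logp - (ap[1] - ap[2] * logf)

  ## iterative peak search on the flattened spectrum
  peaks <- list()
  resid <- flat
  for (k in seq_len(settings$max_n_peaks)) {
    i_max <- which.max(resid)
    height <- resid[i_max]
    ## 1e-6 log10 units: numerical floor so machine-precision residuals of
    ## an exactly representable aperiodic spectrum never count as peaks
    if (height <= settings$peak_threshold * stats::sd(resid) ||
        height < 1e-6) break
    g <- fit_single_gauss(freqs, resid, center0 = freqs[i_max],
                          height0 = height, sd0 = sd_lo,
                          sd_bounds = c(sd_lo, sd_hi),
                          band = range(freqs))
    if (is.null(g)) break
    peaks[[length(peaks) + 1]] <- g
    resid <- resid - gauss_curve(freqs, g)
  }
  ## edge-proximity rule: drop peaks whose center is within one SD of a band edge
  if (length(peaks)) {
    keep <- vapply(peaks, function(g)
      g[1] - min(freqs) >= g[3] && max(freqs) - g[1] >= g[3], logical(1))
    peaks <- peaks[keep]
  }
  ## joint refit of all surviving Gaussians on the flattened spectrum
  if (length(peaks))
    peaks <- fit_gauss_joint(freqs, flat, peaks, c(sd_lo, sd_hi), range(freqs))

  peak_model <- rep(0, length(freqs))
  for (g in peaks) peak_model <- peak_model + gauss_curve(freqs, g)

  ## final aperiodic fit on the peak-removed spectrum
  fin <- stats::lm.fit(cbind(1, logf), logp - peak_model)$coefficients
  offset <- unname(fin[1]); exponent <- unname(-fin[2])
  model <- offset - exponent * logf + peak_model
  r2 <- if (stats::sd(logp) == 0) 1 else suppressWarnings(stats::cor(model, logp)^2)
  if (!is.finite(r2)) r2 <- 0
  pk <- if (length(peaks)) {
    stats::setNames(as.data.frame(do.call(rbind, peaks)),
                    c("center", "height", "sd"))
  } else empty_peaks()
  structure(list(offset = offset, exponent = exponent, peaks = pk,
                 r2 = r2, fit_error = mean(abs(logp - model)),
                 converged = TRUE),
            class = "aperiodic_fit")
}

empty_peaks <- function()
  data.frame(center = numeric(0), height = numeric(0), sd = numeric(0))

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset %.4f, exponent %.4f (slope %.4f), R2 %.4f\n",
              x$offset, x$exponent, -x$exponent, x$r2))
  if (nrow(x$peaks))
    cat(sprintf("  %d peak(s): %s\n", nrow(x$peaks),
                paste(sprintf("%.1f Hz (h %.2f, sd %.2f)", x$peaks$center,
                              x$peaks$height, x$peaks$sd), collapse = "; ")))
  invisible(x)
}

## Robust aperiodic line: initial LS fit, then refit on the points whose
## clamped positive residual is at or below the 2.5th percentile (points on
## or under the line), so oscillatory peaks are ignored.
robust_ap_fit <- function(logf, logp, perc = 2.5) {
  co <- stats::lm.fit(cbind(1, logf), logp)$coefficients
  flat <- logp - (co[1] + co[2] * logf)
  flat[flat < 0] <- 0
  thr <- stats::quantile(flat, perc / 100, names = FALSE)
  mask <- flat <= thr
  if (sum(mask) >= 2)
    co <- stats::lm.fit(cbind(1, logf[mask]), logp[mask])$coefficients
  c(co[1], -co[2])   # (offset, exponent)
}

gauss_curve <- function(f, g) g[2] * exp(-(f - g[1])^2 / (2 * g[3]^2))

## Bounded least-squares fit of one Gaussian to a residual log spectrum.
## Analytic gradient; L-BFGS-B with one retry from the detected maximum.
fit_single_gauss <- function(freqs, y, center0, height0, sd0, sd_bounds, band) {
  obj <- function(p) {
    r <- y - gauss_curve(freqs, p)
    sum(r^2)
  }
  grd <- function(p) {
    e <- exp(-(freqs - p[1])^2 / (2 * p[3]^2))
    r <- y - p[2] * e
    dc <- p[2] * e * (freqs - p[1]) / p[3]^2
    dh <- e
    ds <- p[2] * e * (freqs - p[1])^2 / p[3]^3
    -2 * c(sum(r * dc), sum(r * dh), sum(r * ds))
  }
  lower <- c(band[1], 0, sd_bounds[1])
  upper <- c(band[2], Inf, sd_bounds[2])
  start <- pmin(pmax(c(center0, height0, sd0), lower), upper)
  fit <- tryCatch(
    stats::optim(start, obj, grd, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0)
    fit <- tryCatch(
      stats::optim(c(center0, max(height0, 1e-3), mean(sd_bounds)), obj, grd,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian peak fit failed twice; peak skipped", call. = FALSE)
    return(NULL)
  }
  fit$par
}

## Joint bounded refit of all peaks on the flattened spectrum.
fit_gauss_joint <- function(freqs, flat, peaks, sd_bounds, band) {
  p0 <- unlist(peaks)
  k <- length(peaks)
  model_of <- function(p) {
    m <- rep(0, length(freqs))
    for (i in seq_len(k)) m <- m + gauss_curve(freqs, p[(3 * i - 2):(3 * i)])
    m
  }
  obj <- function(p) sum((flat - model_of(p))^2)
  grd <- function(p) {
    r <- flat - model_of(p)
    g <- numeric(3 * k)
    for (i in seq_len(k)) {
      q <- p[(3 * i - 2):(3 * i)]
      e <- exp(-(freqs - q[1])^2 / (2 * q[3]^2))
      g[3 * i - 2] <- -2 * sum(r * q[2] * e * (freqs - q[1]) / q[3]^2)
      g[3 * i - 1] <- -2 * sum(r * e)
      g[3 * i]     <- -2 * sum(r * q[2] * e * (freqs - q[1])^2 / q[3]^3)
    }
    g
  }
  lower <- rep(c(band[1], 0, sd_bounds[1]), k)
  upper <- rep(c(band[2], Inf, sd_bounds[2]), k)
  fit <- tryCatch(
    stats::optim(pmin(pmax(p0, lower), upper), obj, grd, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(fit)) return(peaks)   # keep individual fits on failure
  lapply(seq_len(k), function(i) fit$par[(3 * i - 2):(3 * i)])
}

#' Reconstruct the aperiodic component in linear space
#'
#' Evaluates `10^(offset - exponent * log10(f))`, i.e. the fitted 1/f^x
#' background with the sign convention that `exponent` is positive and the
#' log-log slope is `-exponent`.
#'
#' @param fit an `aperiodic_fit` (peaks are ignored).
#' @param freqs frequencies (Hz), all > 0.
#' @return a `power_spectrum` holding the aperiodic curve.
#' @export
reconstruct_aperiodic <- function(fit, freqs) {
  if (any(freqs <= 0))
    stop("domain error: frequencies must be > 0", call. = FALSE)
  power_spectrum(freqs, 10^(fit$offset - fit$exponent * log10(freqs)),
                 variant = "total")
}

#' Fit every spectrum in a spectrum set
#'
#' Applies [fit_spectrum()] to each (subject, window, channel, cue type,
#' variant) spectrum and collects the aperiodic parameters into a slope
#' table. `slope` is `-exponent`, so steeper (more low-frequency-dominated)
#' spectra have more negative slope.
#'
#' @param ss a `spectrum_set`.
#' @param cfg an `analysis_config`.
#' @param variants which spectrum variants to fit (default `"total"` and
#'   `"erp_removed"`).
#' @return data.frame with columns subject, window, channel, cue_type,
#'   variant, slope, offset, exponent, r2, n_peaks, fit_error.
#' @export
fit_spectrumset <- function(ss, cfg = analysis_config(),
                            variants = c("total", "erp_removed")) {
  rows <- which(ss$index$variant %in% variants)
  out <- ss$index[rows, c("subject", "window", "channel", "cue_type",
                          "variant"), drop = FALSE]
  fits <- lapply(rows, function(r)
    fit_spectrum(list(freqs = ss$freqs, power = ss$power[r, ]), cfg))
  out$slope <- vapply(fits, function(f) -f$exponent, numeric(1))
  out$offset <- vapply(fits, `[[`, numeric(1), "offset")
  out$exponent <- vapply(fits, `[[`, numeric(1), "exponent")
  out$r2 <- vapply(fits, `[[`, numeric(1), "r2")
  out$n_peaks <- vapply(fits, function(f) nrow(f$peaks), integer(1))
  out$fit_error <- vapply(fits, `[[`, numeric(1), "fit_error")
  rownames(out) <- NULL
  out
}

#' Electrode fit-quality QC
#'
#' For each channel, each participant's mean model R^2 is computed per
#' (window x cue type) cell; the channel is excluded if the
#' across-participant median of those averages falls below `r2_threshold`
#' in ANY cell. An explicit channel list (by default the configured
#' `excluded_channels`, outermost parietal electrodes dropped to balance
#' cluster sizes) is excluded on top of the rule.
#'
#' @param st a slope table (from [fit_spectrumset()]); typically filtered
#'   to one variant before calling.
#' @param r2_threshold QC threshold on the median per-cell R^2.
#' @param exclude character vector of channels to exclude regardless of fit.
#' @return list with `retained`, `excluded_poor_fit`, `excluded_listed`.
#' @export
qc_electrodes <- function(st, r2_threshold = 0.90, exclude = character(0)) {
  if (!nrow(st)) stop("empty slope table", call. = FALSE)
  channels <- unique(st$channel)
  miss <- setdiff(exclude, channels)
  if (length(miss))
    stop("key error: channel(s) absent from slope table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ## per (channel, subject, window, cue_type): mean r2
  agg <- stats::aggregate(r2 ~ channel + subject + window + cue_type,
                          data = st, FUN = mean)
  ## median across subjects per (channel, window, cue_type) cell
  med <- stats::aggregate(r2 ~ channel + window + cue_type, data = agg,
                          FUN = stats::median)
  bad <- unique(med$channel[med$r2 < r2_threshold])
  listed <- setdiff(intersect(exclude, channels), bad)
  retained <- setdiff(channels, c(bad, listed))
  list(retained = retained, excluded_poor_fit = sort(bad),
       excluded_listed = sort(listed))
}
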