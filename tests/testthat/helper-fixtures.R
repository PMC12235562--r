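# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# Minimal valid epochset: deterministic low-amplitude signal unless a data
# array is supplied.
tiny_epochset <- function(n_trials = 4, channels = c("Fz", "Cz"),
                          srate = 500, data = NULL, trials = NULL) {
  times <- seq(-500, 1498, by = 1000 / srate)
  ns <- length(times)
  if (is.null(data)) {
    data <- array(0, dim = c(n_trials, length(channels), ns))
    for (tr in seq_len(n_trials))
      data[tr, , ] <- matrix(sin(2 * pi * 10 * times / 1000),
                             length(channels), ns, byrow = TRUE)
  }
  if (is.null(trials))
    trials <- trial_table(subject = "s01", age_group = "younger", age = 22,
                          context = "strategic", block = 1,
                          cue_type = "no_prediction",
                          congruency = rep(c("congruent", "incongruent"),
                                           length.out = n_trials),
                          rt = 600, accuracy = "correct", prev_rt = 600)
  epochset(data = data, times = times, srate = srate, channels = channels,
           trials = trials)
}

# Exactly representable aperiodic(+peaks) spectrum on the analysis bins.
analytic_spectrum <- function(offset = 1, exponent = 1.5,
                              peaks = NULL, srate = 500, fft_len = 256,
                              band = c(1.95, 44.92)) {
  f <- (1:(fft_len / 2)) * srate / fft_len
  f <- f[round(f, 2) >= band[1] & round(f, 2) <= band[2]]
  lp <- offset - exponent * log10(f)
  if (!is.null(peaks))
    for (i in seq_len(nrow(peaks)))
      lp <- lp + peaks$height[i] *
        exp(-(f - peaks$center[i])^2 / (2 * peaks$sd[i]^2))
  power_spectrum(f, 10^lp)
}

# Balanced long-format dataset for ANOVA tests: n subjects x within cells,
# optional between-group column, pure noise unless effects are injected.
null_anova_data <- function(n = 12, levels_win = c("w1", "w2"),
                            with_group = TRUE, sd = 1) {
  d <- expand.grid(subject = sprintf("s%02d", seq_len(n)),
                   win = levels_win, stringsAsFactors = FALSE)
  if (with_group)
    d$grp <- ifelse(match(d$subject, unique(d$subject)) <= n / 2,
                    "younger", "older")
  d$y <- stats::rnorm(nrow(d), sd = sd)
  d
}

# Brute-force Jaeckel dispersion minimizer over a beta grid, evaluated via
# the pairwise-difference identity D(b) = sqrt(12)/(2(n+1)) sum |e_i - e_j|
# (independent of the rank-based implementation path).
grid_rank_slope <- function(y, x, lo = -10, hi = 10, step = 1e-4) {
  n <- length(y)
  ij <- utils::combn(n, 2)
  dy <- y[ij[1, ]] - y[ij[2, ]]
  dx <- x[ij[1, ]] - x[ij[2, ]]
  bs <- seq(lo, hi, by = step)
  best <- Inf; bbest <- NA_real_
  for (s in seq(1, length(bs), by = 50000)) {
    idx <- s:min(s + 49999, length(bs))
    D <- colSums(abs(dy - outer(dx, bs[idx])))
    if (min(D) < best) {
      best <- min(D)
      bbest <- bs[idx][which.min(D)]
    }
  }
  bbest
}
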