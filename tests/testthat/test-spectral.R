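cfg <- analysis_config()

test_that("fft_power has the configured resolution and band", {
  seg <- sin(2 * pi * 10 * (0:249) / 500)
  ps <- fft_power(seg, 500, 256, c(cfg$freq_lo, cfg$freq_hi))
  expect_equal(diff(ps$freqs)[1], 500 / 256)      # 1.953125 Hz
  expect_equal(round(diff(ps$freqs)[1], 2), 1.95)
  ## retained bins are exactly k = 1..23
  expect_equal(ps$freqs, (1:23) * 500 / 256)
  expect_equal(round(max(ps$freqs), 2), 44.92)
})

test_that("a sinusoid at a bin frequency peaks at that bin", {
  f0 <- 20 * 500 / 256
  seg <- sin(2 * pi * f0 * (0:255) / 500)
  ps <- fft_power(seg, 500, 256, c(1.95, 44.92))
  expect_equal(ps$freqs[which.max(ps$power)], f0)
})

test_that("fft_power is scale-equivariant and refuses long segments", {
  seg <- stats::rnorm(250)
  p1 <- fft_power(seg, 500, 256, c(1.95, 44.92))$power
  p3 <- fft_power(3 * seg, 500, 256, c(1.95, 44.92))$power
  expect_equal(p3, 9 * p1, tolerance = 1e-12)
  expect_error(fft_power(stats::rnorm(300), 500, 256, c(1.95, 44.92)),
               "truncate")
})

test_that("full-band power obeys Parseval under the package convention", {
  set.seed(4)
  seg <- stats::rnorm(250)
  n_eff <- 250; fft_len <- 256
  X <- stats::fft(c(seg, rep(0, fft_len - n_eff)))
  ## DFT Parseval on the zero-padded segment
  expect_equal(sum(Mod(X)^2), fft_len * sum(seg^2), tolerance = 1e-10)
  ## and fft_power's retained bins are exactly |X_k|^2 * 2 / n_eff^2
  ps <- fft_power(seg, 500, fft_len, c(1.95, 44.92))
  expect_equal(ps$power, Mod(X[2:24])^2 * 2 / n_eff^2, tolerance = 1e-12)
})

test_that("window_epochs cuts four 250-sample half-open windows", {
  es <- tiny_epochset(n_trials = 2)
  wins <- window_epochs(es, cfg)
  expect_named(wins, c("pre_cue", "post_cue_1", "post_cue_2", "post_cue_3"))
  expect_true(all(vapply(wins, function(a) dim(a)[3], integer(1)) == 250))
  ## the sample at exactly 500 ms belongs to post_cue_2 only
  i500 <- which(es$times == 500)
  idx2 <- which(es$times >= 500 & es$times < 1000)
  expect_true(i500 %in% idx2)
  idx1 <- which(es$times >= 0 & es$times < 500)
  expect_false(i500 %in% idx1)
  ## out-of-epoch windows are a range error; non-partitioning ones warn
  expect_error(window_epochs(es, analysis_config(
    windows = list(pre_cue = c(-900, 0)))), "outside the epoch")
  expect_warning(window_epochs(es, analysis_config(
    windows = list(pre_cue = c(-500, 0), late = c(1000, 1400)))),
    "partition")
})

test_that("average_spectra is the per-bin arithmetic mean", {
  f <- (1:23) * 500 / 256
  s1 <- power_spectrum(f, rep(2, 23))
  s2 <- power_spectrum(f, rep(4, 23))
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$power, rep(3, 23))
  expect_equal(avg$n_trials, 2L)
  expect_equal(average_spectra(list(s1, s1))$power, s1$power)
  s3 <- power_spectrum(f + 1, rep(1, 23))
  expect_error(average_spectra(list(s1, s3)), "inconsistent")
})

test_that("trial-mean variance shrinks as 1/N for white noise", {
  set.seed(8)
  nreps <- 80
  one_bin_mean <- function(N) {
    segs <- matrix(stats::rnorm(N * 250), N)
    mean(apershift:::fft_power_matrix(segs, 500, 256,
                                      c(1.95, 44.92))$power[, 5])
  }
  v10 <- stats::var(replicate(nreps, one_bin_mean(10)))
  v80 <- stats::var(replicate(nreps, one_bin_mean(80)))
  expect_gt(v10 / v80, 8 / 2.5)   # ratio ~8, generous Monte-Carlo margin
  expect_lt(v10 / v80, 8 * 2.5)
})

test_that("erp_spectrum equals fft_power for a single trial and the total
           for identical trials", {
  seg <- sin(2 * pi * 7.8125 * (0:249) / 500)
  e1 <- erp_spectrum(matrix(seg, 1), 500, 256, c(1.95, 44.92))
  expect_equal(e1$power, fft_power(seg, 500, 256, c(1.95, 44.92))$power)
  trials <- matrix(rep(seg, 5), 5, byrow = TRUE)
  e5 <- erp_spectrum(trials, 500, 256, c(1.95, 44.92))
  tot <- average_spectra(apershift:::fft_power_matrix(
    trials, 500, 256, c(1.95, 44.92))$power, freqs = e5$freqs)
  expect_equal(e5$power, tot$power, tolerance = 1e-12)
})

test_that("ERP power vanishes as random-phase trials accumulate", {
  set.seed(9)
  make_erp_ratio <- function(N) {
    trials <- t(replicate(N, {
      ph <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * 10 * (0:249) / 500 + ph) + stats::rnorm(250, sd = 0.1)
    }))
    e <- erp_spectrum(trials, 500, 256, c(1.95, 44.92))
    tot <- colMeans(apershift:::fft_power_matrix(trials, 500, 256,
                                                 c(1.95, 44.92))$power)
    sum(e$power) / sum(tot)
  }
  r <- vapply(c(20, 200), make_erp_ratio, numeric(1))
  expect_lt(r[2], r[1])
  expect_lt(r[2], 0.05)
})

test_that("remove_erp_spectrum subtracts, clamps and detects mismatch", {
  f <- (1:23) * 500 / 256
  tot <- power_spectrum(f, rep(3, 23), variant = "total")
  erp <- power_spectrum(f, rep(1, 23), variant = "erp")
  rem <- remove_erp_spectrum(tot, erp)
  expect_equal(rem$power, rep(2, 23))
  expect_identical(rem$variant, "erp_removed")
  ## identical trials: residual collapses to ~0 (tiny negatives clamped)
  near <- power_spectrum(f, rep(3, 23) - 1e-15, variant = "erp")
  expect_true(all(remove_erp_spectrum(tot, near)$power >= 0))
  ## genuinely larger ERP power signals mismatched trial sets
  big <- power_spectrum(f, rep(3.5, 23), variant = "erp")
  expect_error(remove_erp_spectrum(tot, big), "consistency")
  ## frequency mismatch
  off <- power_spectrum(f + 1, rep(1, 23))
  expect_error(remove_erp_spectrum(tot, off), "frequency")
})

test_that("artifact rejection drops exactly the spiking trial", {
  es <- tiny_epochset(n_trials = 4)
  expect_message(clean <- reject_epochs(es, cfg), "0/4 removed")
  expect_equal(dim(clean$data)[1], 4)

  es$data[3, 2, 600] <- 300   # single 300-uV spike on one channel
  expect_message(clean <- reject_epochs(es, cfg), "1/4 removed")
  expect_equal(dim(clean$data)[1], 3)
  expect_equal(attr(clean, "rejection")[["artifact"]], 1)
})

test_that("epochs after a slow response are rejected, boundary exclusive", {
  es <- tiny_epochset(n_trials = 2)
  es$trials$prev_rt <- c(1300, 1500)
  clean <- suppressMessages(reject_epochs(es, cfg))
  expect_equal(nrow(clean$trials), 1)
  expect_equal(clean$trials$prev_rt, 1300)
  ## exactly 1400 ms is not "exceeded"
  es$trials$prev_rt <- c(1400, 1400.1)
  clean <- suppressMessages(reject_epochs(es, cfg))
  expect_equal(clean$trials$prev_rt, 1400)
})

test_that("artifact window longer than the epoch is a config error", {
  es <- tiny_epochset()
  expect_error(reject_epochs(es, analysis_config(artifact_window_ms = 3000)),
               "longer than the epoch")
})

test_that("Jensen inequality holds on a synthetic spectrum set", {
  tr <- sim_truth(seed = 21)
  des <- generate_design(design_spec(1, 1, 12), seed = 21)
  es <- synthesize_epochs(tr, des, cfg, channels = c("Fz", "Cz"))
  ss <- compute_spectrumset(es, cfg, by_cue = TRUE)
  expect_true(check_jensen(ss, rtol = 1e-12))
})
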