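test_that("the full task design has the published trial structure", {
  d <- generate_design(design_spec(), seed = 1)
  expect_equal(nrow(d), 1728)
  expect_equal(unname(table(d$context)["strategic"]), 864)
  expect_equal(unname(table(d$context)["affective"]), 864)
  expect_equal(length(unique(d$block)), 6)
  ## blocks alternate contexts
  ctx_by_block <- tapply(d$context, d$block, function(x) unique(x))
  expect_equal(as.vector(ctx_by_block),
               rep(c("strategic", "affective"), 3))
  ## strategic cues only in strategic blocks and vice versa
  expect_true(all(d$cue_type[d$context == "strategic"] %in%
                    c("predict_congruent", "no_prediction",
                      "predict_incongruent")))
  expect_true(all(d$cue_type[d$context == "affective"] %in%
                    c("positive", "neutral", "negative")))
})

test_that("congruency rates follow the per-cue probabilities", {
  ## 10,000 predictive trials: binomial oracle, 3 SE tolerance
  d <- generate_design(design_spec(n_strategic_blocks = 35,
                                   n_affective_blocks = 0,
                                   trials_per_block = 288), seed = 2)
  for (cue in c("predict_congruent", "no_prediction",
                "predict_incongruent")) {
    p_target <- c(predict_congruent = 0.75, no_prediction = 0.50,
                  predict_incongruent = 0.25)[[cue]]
    sub <- d[d$cue_type == cue, ]
    phat <- mean(sub$congruency == "congruent")
    se <- sqrt(p_target * (1 - p_target) / nrow(sub))
    expect_lt(abs(phat - p_target), 3 * se)
  }
})

test_that("invalid design probabilities raise a config error", {
  expect_error(design_spec(strategic_cue_probs = c(a = 0.5, b = 0.4)),
               "sum to 1")
})

test_that("spectral shaping recovers the injected exponent (no peaks)", {
  cfg <- analysis_config()
  tr <- sim_truth(x0 = 1.3, deltas = c(post_cue_1 = 0, post_cue_2 = 0,
                                       post_cue_3 = 0),
                  peaks = data.frame(center = numeric(0),
                                     height = numeric(0), sd = numeric(0)),
                  erp_gain = 0, seed = 5)
  des <- generate_design(design_spec(2, 0, 250), seed = 6)
  es <- synthesize_epochs(tr, des, cfg, channels = "Cz")
  wins <- window_epochs(es, cfg)
  ## per-bin mean log10 power across 500 trials regressed on log10 f
  segs <- matrix(wins$pre_cue[, 1, ], nrow = dim(wins$pre_cue)[1])
  pw <- apershift:::fft_power_matrix(segs, es$srate, cfg$fft_len,
                                     c(cfg$freq_lo, cfg$freq_hi))
  mlp <- colMeans(log10(pw$power))
  slope <- stats::coef(stats::lm(mlp ~ log10(pw$freqs)))[2]
  expect_lt(abs(unname(slope) + tr$x0), 0.05)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  cfg <- analysis_config()
  tr <- sim_truth(seed = 99)
  des <- generate_design(design_spec(1, 0, 5), seed = 99)
  es1 <- synthesize_epochs(tr, des, cfg, channels = "Cz")
  es2 <- synthesize_epochs(tr, des, cfg, channels = "Cz")
  expect_identical(es1$data, es2$data)
  b1 <- synthesize_behavior(tr, des)
  b2 <- synthesize_behavior(tr, des)
  expect_identical(b1, b2)
})

test_that("zero ERP gain leaves total and ERP-removed spectra in agreement", {
  cfg <- analysis_config()
  tr <- sim_truth(erp_gain = 0, seed = 12,
                  deltas = c(post_cue_1 = 0, post_cue_2 = 0, post_cue_3 = 0))
  des <- generate_design(design_spec(1, 0, 150), seed = 12)
  es <- synthesize_epochs(tr, des, cfg, channels = "Cz")
  ss <- compute_spectrumset(es, cfg, by_cue = FALSE)
  tot <- ss$power[ss$index$variant == "total" &
                    ss$index$window == "post_cue_1", ]
  rem <- ss$power[ss$index$variant == "erp_removed" &
                    ss$index$window == "post_cue_1", ]
  ## with random phases the ERP spectrum is O(1/N) of the total
  expect_lt(max(abs(rem - tot) / tot), 0.15)
  expect_lt(mean(abs(rem - tot) / tot), 0.05)
})

test_that("behavioral generator reproduces its cell structure", {
  tr <- sim_truth(seed = 31,
                  behavior = list(congruency_ms = 80, coupling_ms = 0,
                                  timeout_p = 0))
  des <- generate_design(design_spec(3, 3, 288), seed = 31)
  tt <- synthesize_behavior(tr, des)
  expect_true(all(tt$rt >= tr$behavior$rt_shift, na.rm = TRUE))
  corr <- tt$accuracy == "correct"
  eff <- mean(tt$rt[tt$congruency == "incongruent" & corr], na.rm = TRUE) -
    mean(tt$rt[tt$congruency == "congruent" & corr], na.rm = TRUE)
  ## 80-ms injected effect, ~1700 trials: recovered within 3 SE (~20 ms)
  se <- sqrt(stats::var(tt$rt, na.rm = TRUE) *
               (1 / sum(tt$congruency == "incongruent") +
                  1 / sum(tt$congruency == "congruent")))
  expect_lt(abs(eff - 80), 3 * se)
})

test_that("a zero congruency coefficient yields no congruency effect", {
  tr <- sim_truth(seed = 77, behavior = list(congruency_ms = 0,
                                             timeout_p = 0))
  des <- generate_design(design_spec(3, 3, 288), seed = 77)
  tt <- synthesize_behavior(tr, des)
  corr <- tt$accuracy == "correct"
  eff <- mean(tt$rt[tt$congruency == "incongruent" & corr]) -
    mean(tt$rt[tt$congruency == "congruent" & corr])
  se <- sqrt(stats::var(tt$rt, na.rm = TRUE) * 4 / nrow(tt))
  expect_lt(abs(eff), 3 * se)
})

test_that("negative RT shift is rejected", {
  expect_error(sim_truth(behavior = list(rt_shift = -5)), "config error")
})

test_that("truth_table exposes injected parameters and implied shifts", {
  truths <- simulate_cohort(n_younger = 2, n_older = 2, seed = 3)
  tt <- truth_table(truths)
  expect_equal(nrow(tt), 4)
  expect_equal(tt$true_shift_post_cue_1, -tt$delta_post_cue_1)
  expect_true(all(tt$x0 > 0))
})
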