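#' Task design specification
#'
#' Describes the cued-flanker block structure used by the generator:
#' alternating strategic and affective blocks. Within strategic blocks the
#' three predictive cue types are equiprobable and congruency is drawn per
#' cue type (75 / 50 / 25% congruent for predict-congruent / no-prediction /
#' predict-incongruent); within affective blocks the three valence cues are
#' equiprobable and congruency is 50%. The default specification yields
#' 3 + 3 blocks of 288 trials, 1728 trials in total.
#'
#' @param n_strategic_blocks,n_affective_blocks number of blocks per context.
#' @param trials_per_block trials per block.
#' @param strategic_cue_probs,affective_cue_probs cue-type probabilities
#'   within each block type (must sum to 1).
#' @param congruent_prob named vector: probability of a congruent flanker
#'   array given the cue type.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_strategic_blocks = 3, n_affective_blocks = 3,
                        trials_per_block = 288,
                        strategic_cue_probs = c(predict_congruent = 1/3,
                                                no_prediction = 1/3,
                                                predict_incongruent = 1/3),
                        affective_cue_probs = c(positive = 1/3,
                                                neutral = 1/3,
                                                negative = 1/3),
                        congruent_prob = c(predict_congruent = 0.75,
                                           no_prediction = 0.50,
                                           predict_incongruent = 0.25,
                                           positive = 0.50,
                                           neutral = 0.50,
                                           negative = 0.50)) {
  spec <- list(n_strategic_blocks = n_strategic_blocks,
               n_affective_blocks = n_affective_blocks,
               trials_per_block = trials_per_block,
               strategic_cue_probs = strategic_cue_probs,
               affective_cue_probs = affective_cue_probs,
               congruent_prob = congruent_prob)
  for (p in c("strategic_cue_probs", "affective_cue_probs")) {
    v <- spec[[p]]
    if (is.null(names(v)) || abs(sum(v) - 1) > 1e-9)
      stop("config error: ", p, " must be named and sum to 1", call. = FALSE)
  }
  if (any(spec$congruent_prob < 0 | spec$congruent_prob > 1))
    stop("config error: congruent_prob entries must lie in [0, 1]",
         call. = FALSE)
  structure(spec, class = "design_spec")
}

#' Generate a trial sequence from a design specification
#'
#' Blocks alternate between the strategic and affective contexts (starting
#' strategic) until both context's block counts are exhausted. Cue types are
#' drawn independently per trial with the block's cue probabilities and the
#' flanker congruency per the cue type's congruent probability.
#'
#' @param spec a `design_spec`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `trial`, `block`, `context`, `cue_type`,
#'   `congruency`.
#' @export
#' @examples
#' d <- generate_design(design_spec(), seed = 1)
#' nrow(d)             # 1728
#' table(d$context)    # 864 / 864
generate_design <- function(spec = design_spec(), seed = 1L) {
 with_seed(seed, {
  ctx_seq <- character(0)
  ns <- spec$n_strategic_blocks; na <- spec$n_affective_blocks
  while (ns > 0 || na > 0) {
    if (ns > 0) { ctx_seq <- c(ctx_seq, "strategic"); ns <- ns - 1 }
    if (na > 0) { ctx_seq <- c(ctx_seq, "affective"); na <- na - 1 }
  }
  rows <- lapply(seq_along(ctx_seq), function(b) {
    ctx <- ctx_seq[b]
    probs <- if (ctx == "strategic") spec$strategic_cue_probs
             else spec$affective_cue_probs
    cue <- sample(names(probs), spec$trials_per_block, replace = TRUE,
                  prob = probs)
    congr <- ifelse(stats::runif(spec$trials_per_block) <
                      spec$congruent_prob[cue],
                    "congruent", "incongruent")
    data.frame(block = b, context = ctx, cue_type = cue, congruency = congr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
 })
}

#' Phase-locked ERP template
#'
#' A damped oscillation confined to the interval 0..`duration_ms` after cue
#' onset (zero before the cue), with a smooth onset ramp: the generative
#' counterpart of a cue-evoked potential.
#'
#' @param times_ms per-sample latencies of the epoch (ms, cue onset at 0).
#' @param amplitude peak amplitude scale (uV).
#' @param freq_hz oscillation frequency (Hz).
#' @param decay_ms exponential decay time constant (ms).
#' @param duration_ms support of the waveform after cue onset (ms).
#' @return numeric vector of uV values aligned with `times_ms`.
#' @export
erp_template <- function(times_ms, amplitude = 5, freq_hz = 5,
                         decay_ms = 250, duration_ms = 800) {
  t <- times_ms / 1000
  w <- amplitude * sin(2 * pi * freq_hz * t) * exp(-times_ms / decay_ms) *
    (1 - exp(-times_ms / 20))
  w[times_ms < 0 | times_ms > duration_ms] <- 0
  w
}

#' Ground-truth parameters for one simulated subject
#'
#' Collects everything the generator needs and every value the recovery
#' tests compare against: the baseline aperiodic exponent `x0` and offset,
#' per-window exponent deltas (the injected counterpart of the cue-induced
#' shifts: a delta of +0.3 in a window makes the spectrum steeper there, so
#' the recovered slope shift is -0.3), oscillatory peaks, the ERP waveform
#' and gain, and the behavioral generator coefficients.
#'
#' @param subject subject id (string).
#' @param age_group `"younger"` or `"older"`.
#' @param age age in years.
#' @param x0 baseline aperiodic exponent (> 0).
#' @param offset aperiodic offset (log10 uV^2).
#' @param deltas named numeric: exponent delta per post-cue window.
#' @param peaks data.frame with columns `center` (Hz), `height` (log10
#'   power) and `sd` (Hz); may have zero rows.
#' @param erp_gain multiplier on the ERP template (0 disables the ERP).
#' @param erp_amplitude,erp_freq_hz template parameters, see
#'   [erp_template()].
#' @param behavior list of behavioral coefficients: `rt_shift` (ms, >= 0),
#'   `rt_base` (mean correct RT for a younger congruent strategic trial,
#'   ms), `congruency_ms`, `age_ms`, `context_ms` (additive RT effects),
#'   `coupling_ms` (ms of RT per unit of the subject's mean injected slope
#'   shift), `sd_log` (lognormal scale), `err_congruent`,
#'   `err_incongruent` (error probabilities), `timeout_p`.
#' @param seed integer seed used when this subject is synthesized.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(subject = "s01", age_group = "younger",
                      age = if (age_group == "younger") 22 else 71,
                      x0 = if (age_group == "younger") 1.4 else 1.1,
                      offset = x0,
                      deltas = c(post_cue_1 = 0.3, post_cue_2 = 0,
                                 post_cue_3 = -0.2),
                      peaks = data.frame(center = 10, height = 0.6, sd = 1.5),
                      erp_gain = 1, erp_amplitude = 5, erp_freq_hz = 5,
                      behavior = list(),
                      seed = 1L) {
  beh <- utils::modifyList(list(
    rt_shift = 150, rt_base = 520, congruency_ms = 80, age_ms = 60,
    context_ms = 10, coupling_ms = 200, sd_log = 0.25,
    err_congruent = 0.04, err_incongruent = 0.10, timeout_p = 0.005),
    behavior)
  if (x0 <= 0) stop("x0 must be > 0", call. = FALSE)
  if (beh$rt_shift < 0)
    stop("config error: negative RT shift", call. = FALSE)
  structure(list(subject = subject, age_group = age_group, age = age,
                 x0 = x0, offset = offset, deltas = deltas, peaks = peaks,
                 erp_gain = erp_gain, erp_amplitude = erp_amplitude,
                 erp_freq_hz = erp_freq_hz, behavior = beh,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

## Target log10 power of the synthetic background in window `win`.
truth_log_power <- function(truth, freqs, win, baseline = "pre_cue") {
  x <- truth$x0 + if (win == baseline) 0 else
    if (win %in% names(truth$deltas)) truth$deltas[[win]] else 0
  lp <- truth$offset - x * log10(freqs)
  if (nrow(truth$peaks))
    for (i in seq_len(nrow(truth$peaks)))
      lp <- lp + gauss_curve(freqs, unlist(truth$peaks[i, c("center", "height",
                                                            "sd")]))
  lp
}

## One colored-noise segment of n samples at srate whose expected
## periodogram (under the package's power convention) follows 10^log_p.
## Spectral shaping by inverse FFT with complex-Gaussian coefficients.
colored_segment <- function(n, srate, log_p_fun) {
  nf <- n %/% 2
  f <- (1:nf) * srate / n
  amp <- n * sqrt(10^log_p_fun(f) / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) /
    sqrt(2)
  if (n %% 2 == 0) z[nf] <- complex(real = stats::rnorm(1), imaginary = 0)
  spec <- c(0, amp * z)
  full <- c(spec, Conj(rev(spec[2:(if (n %% 2 == 0) nf else nf + 1)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Synthesize epoched EEG with known aperiodic ground truth
#'
#' Each trial is built window-by-window: every analysis window gets an
#' independent stationary colored-noise segment whose expected log10 power
#' follows `offset - (x0 + delta_w) * log10(f)` plus the truth's Gaussian
#' peaks (spectral shaping by inverse FFT with complex-Gaussian
#' coefficients, i.e. uniformly random phases). Segments are concatenated
#' in time order and the ERP waveform (times `erp_gain`) is added
#' identically to every trial, making it strictly phase-locked.
#'
#' @param truth a `sim_truth`.
#' @param design a trial design from [generate_design()] (one row per
#'   trial).
#' @param cfg an `analysis_config`; its windows define both synthesis and
#'   analysis segmentation.
#' @param channels channel labels to synthesize (independent noise per
#'   channel; identical ground truth).
#' @param srate sampling rate (Hz).
#' @return an `epochset` whose trial table carries the design columns
#'   (behavioral columns are `NA` until [synthesize_behavior()] fills
#'   them).
#' @export
synthesize_epochs <- function(truth, design, cfg = analysis_config(),
                              channels = c("Fz", "Cz", "Pz"), srate = 500) {
 with_seed(truth$seed, {
  wins <- cfg$windows[order(vapply(cfg$windows, `[`, numeric(1), 1))]
  step <- 1000 / srate
  times <- seq(wins[[1]][1], wins[[length(wins)]][2] - step, by = step)
  n_per_win <- vapply(wins, function(b) sum(times >= b[1] & times < b[2]),
                      integer(1))
  if (any(n_per_win <= 1))
    stop("dimension error: window/sample mismatch (a window holds <= 1 ",
         "sample at this srate)", call. = FALSE)
  nt <- nrow(design); nc <- length(channels); ns <- length(times)
  data <- array(0, dim = c(nt, nc, ns))
  erp <- truth$erp_gain *
    erp_template(times, amplitude = truth$erp_amplitude,
                 freq_hz = truth$erp_freq_hz)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      seg <- unlist(lapply(names(wins), function(w)
        colored_segment(n_per_win[[w]], srate,
                        function(f) truth_log_power(truth, f, w,
                                                    cfg$baseline_window))))
      data[tr, ch, ] <- seg + erp
    }
  }
  tt <- trial_table(subject = truth$subject, age_group = truth$age_group,
                    age = truth$age, context = design$context,
                    block = design$block, cue_type = design$cue_type,
                    congruency = design$congruency,
                    rt = NA_real_, accuracy = NA_character_,
                    prev_rt = NA_real_)
  epochset(data = data, times = times, srate = srate, channels = channels,
           trials = tt)
 })
}

#' Synthesize behavioral outcomes for a trial design
#'
#' Reaction times follow a shifted lognormal whose mean is
#' `rt_base + congruency_ms * [incongruent] + age_ms * [older] +
#' context_ms * [affective] + coupling_ms * mean injected slope shift`;
#' accuracy is Bernoulli per congruency; a small timeout probability yields
#' omissions (`rt = NA`). The coupling term ties a subject's injected
#' spectral shifts to their overall speed, giving the cohort a known
#' neuro-behavioral association for recovery tests (a more negative mean
#' shift, i.e. steeper post-cue spectra, speeds responses when
#' `coupling_ms > 0`).
#'
#' @param truth a `sim_truth`.
#' @param design trial design (or an `epochset` trial table) with
#'   `context`, `cue_type`, `congruency` columns.
#' @param seed optional seed; defaults to `truth$seed + 1` so EEG and
#'   behavior are independently reproducible.
#' @return a full trial table (see [trial_table()]).
#' @export
synthesize_behavior <- function(truth, design, seed = truth$seed + 1L) {
 with_seed(seed, {
  beh <- truth$behavior
  n <- nrow(design)
  mean_shift <- mean(-truth$deltas)   # slope shift = -exponent delta
  mu <- beh$rt_base +
    beh$congruency_ms * (design$congruency == "incongruent") +
    beh$age_ms * (truth$age_group == "older") +
    beh$context_ms * (design$context == "affective") +
    beh$coupling_ms * mean_shift
  scale_ms <- pmax(mu - beh$rt_shift, 1)
  rt <- beh$rt_shift +
    scale_ms * exp(stats::rnorm(n, -beh$sd_log^2 / 2, beh$sd_log))
  p_err <- ifelse(design$congruency == "incongruent",
                  beh$err_incongruent, beh$err_congruent)
  acc <- ifelse(stats::runif(n) < p_err, "incorrect", "correct")
  timeout <- stats::runif(n) < beh$timeout_p | rt > 1997
  acc[timeout] <- "timeout"
  rt[timeout] <- NA_real_
  trial_table(subject = truth$subject, age_group = truth$age_group,
              age = truth$age, context = design$context,
              block = design$block, cue_type = design$cue_type,
              congruency = design$congruency, rt = rt, accuracy = acc,
              prev_rt = c(NA_real_, rt[-n]))
 })
}

#' Build a cohort of simulated subjects
#'
#' Draws per-subject ground truth around the group-level defaults (baseline
#' exponent ~1.4 for younger, ~1.1 for older adults; biphasic exponent
#' deltas +0.3 / 0 / -0.2 across the post-cue windows; a 10-Hz alpha peak)
#' and returns one `sim_truth` per subject with a derived seed.
#'
#' @param n_younger,n_older group sizes.
#' @param delta_means named vector of mean exponent deltas per post window.
#' @param delta_sd between-subject SD of each delta.
#' @param x0_sd between-subject SD of the baseline exponent.
#' @param older_delta3_extra additional (more negative) exponent delta in
#'   the last window for older adults: the generative counterpart of the
#'   age-related counterclockwise rotation before the target.
#' @param behavior coefficients passed to every subject's [sim_truth()].
#' @param erp_gain ERP gain for every subject.
#' @param seed master seed; subject seeds are derived from it.
#' @return list of `sim_truth` objects.
#' @export
simulate_cohort <- function(n_younger = 21, n_older = 22,
                            delta_means = c(post_cue_1 = 0.3, post_cue_2 = 0,
                                            post_cue_3 = -0.2),
                            delta_sd = 0.1, x0_sd = 0.15,
                            older_delta3_extra = -0.15,
                            behavior = list(), erp_gain = 1, seed = 1L) {
 with_seed(seed, {
  n <- n_younger + n_older
  groups <- rep(c("younger", "older"), c(n_younger, n_older))
  lapply(seq_len(n), function(i) {
    grp <- groups[i]
    d <- delta_means + stats::rnorm(length(delta_means), 0, delta_sd)
    if (grp == "older" && "post_cue_3" %in% names(d))
      d[["post_cue_3"]] <- d[["post_cue_3"]] + older_delta3_extra
    sim_truth(
      subject = sprintf("s%02d", i), age_group = grp,
      age = stats::runif(1, if (grp == "younger") 18 else 65,
                         if (grp == "younger") 30 else 80),
      x0 = max(0.2, stats::rnorm(1, if (grp == "younger") 1.4 else 1.1,
                                 x0_sd)),
      deltas = d, behavior = behavior, erp_gain = erp_gain,
      seed = as.integer(seed + 1000L * i))
  })
 })
}

#' Flatten cohort ground truth to a table
#'
#' @param truths list of `sim_truth` objects.
#' @return data.frame with one row per subject: id, group, age, baseline
#'   exponent/offset, per-window exponent deltas and the implied true slope
#'   shifts (`-delta`), ERP gain and behavioral coefficients.
#' @export
truth_table <- function(truths) {
  do.call(rbind, lapply(truths, function(tr) {
    row <- data.frame(subject = tr$subject, age_group = tr$age_group,
                      age = tr$age, x0 = tr$x0, offset = tr$offset,
                      erp_gain = tr$erp_gain, seed = tr$seed,
                      stringsAsFactors = FALSE)
    for (w in names(tr$deltas)) {
      row[[paste0("delta_", w)]] <- tr$deltas[[w]]
      row[[paste0("true_shift_", w)]] <- -tr$deltas[[w]]
    }
    for (b in names(tr$behavior)) row[[b]] <- tr$behavior[[b]]
    row
  }))
}
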