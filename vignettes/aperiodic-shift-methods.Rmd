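---
title: "Methods: event-related shifts of the aperiodic EEG component"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related shifts of the aperiodic EEG component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apershift)
```

## The problem and the model

The broadband background of the EEG power spectrum follows an approximate
power law, \(P(f) \propto 1/f^{x}\). In log-log coordinates this background
is a line with slope \(-x\); its exponent is commonly read as a proxy for
the cortical excitation:inhibition (E:I) balance, with flatter spectra
(smaller \(x\)) indicating relatively more high-frequency power and a
higher E:I ratio. `apershift` quantifies how this aperiodic component
*changes within a trial* after an informative or affective cue, and how
those changes relate to subsequent behavior.

The full model of one spectrum in log space is

\[
\log_{10} P(f) \;=\; \beta \;-\; x \log_{10} f \;+\;
\sum_{k} h_k \exp\!\left(-\frac{(f - c_k)^2}{2 s_k^2}\right),
\]

an aperiodic line (offset \(\beta\), exponent \(x > 0\)) plus up to three
Gaussian oscillatory peaks (center \(c_k\) in Hz, height \(h_k\) in
log10-power units, SD \(s_k\) in Hz). Everywhere in the package the
reported `slope` equals \(-x\): *more negative slope = steeper spectrum =
relatively more inhibition*.

The pipeline is:

1. **Epoching and rejection** — cue-locked epochs (-500..1498 ms at
   500 Hz) are screened by a sliding peak-to-peak artifact criterion and a
   preceding-trial response-latency criterion (`reject_epochs()`).
2. **Windowed spectra** — each epoch is cut into four successive 500-ms
   windows (pre-cue baseline plus three post-cue windows); per-trial
   segments are zero-padded to 256 points and Fourier transformed
   (`window_epochs()`, `fft_power()`), giving 1.95-Hz resolution over the
   retained 1.95-44.92 Hz band (bins 1..23).
3. **ERP-spectrum removal** — the spectrum of the cross-trial time-domain
   average (the phase-locked ERP) is subtracted from the trial-averaged
   total spectrum per window/channel/cue type (`remove_erp_spectrum()`),
   isolating induced activity.
4. **Spectral parameterization** — each spectrum is decomposed into the
   aperiodic line plus peaks in fixed mode (`fit_spectrum()`); slope
   values are retained and screened by a model-\(R^2\) electrode QC
   (`qc_electrodes()`).
5. **Cue-induced shifts** — `Shift`\(_k\) = post-cue-\(k\) slope minus
   pre-cue slope (`compute_shifts()`); negative shifts are clockwise
   rotations (steepening, increased inhibition), positive shifts are
   counterclockwise (flattening, increased E:I ratio).
6. **Statistics** — sign-flip permutation mixed ANOVAs
   (`permutation_mixed_anova()`), planned paired/Welch comparisons, and
   rank-based regressions with Wilcoxon scores (`rank_fit()`) linking
   shifts, age and inverse-efficiency performance.

## Parameters that matter

All settings live in one `analysis_config()` object; the defaults are the
analysis configuration the package implements end to end.

| setting | default | unit | why |
|---|---|---|---|
| `windows` | four half-open 500-ms intervals | ms | partition the epoch cleanly on the 2-ms grid |
| `fft_len` | 256 | points | power-of-two padding of the 250-sample windows |
| `freq_lo`, `freq_hi` | 1.95, 44.92 | Hz | drop sub-2-cycle estimates and low-pass-contaminated bins; leaves bins 1..23 |
| `peak_width_limits` | 3-8 | Hz (full width) | plausible EEG oscillation widths; Gaussian SD bounds are half of these |
| `max_n_peaks` | 3 | — | parsimony with only 23 bins |
| `peak_threshold` | 2 | SD of flattened spectrum | peak acceptance threshold |
| `artifact_threshold_uv` | 200 | uV peak-to-peak | gross-artifact screen (600-ms windows, 100-ms steps) |
| `rt_min_ms`, `rt_max_ms` | 200, 1400 | ms | fast guesses and slow responses are discarded |
| `prev_rt_max_ms` | 1400 | ms | preceding-trial latency that contaminates the baseline |
| `n_permutations` | 10,000 | — | permutation ANOVA iterations |
| `qc_r2_threshold` | 0.90 | — | median per-cell model-\(R^2\) floor per electrode |

## Window conventions

The four windows are treated as half-open \([\text{start}, \text{end})\)
intervals in ms: \([-500, 0)\), \([0, 500)\), \([500, 1000)\) and
\([1000, 1500)\). On the 2-ms sample grid each window then holds exactly
250 samples and the sample at exactly 500 ms belongs to the second
post-cue window only. Descriptions of the pre-cue window as "-501 to
-1 ms" are equivalent to \([-500, 0)\) on this grid; the half-open
convention makes the equivalence explicit rather than leaving boundary
samples ambiguous.

## Spectral estimation choices

* **No taper.** Segments are zero-padded, not windowed. A taper would
  trade leakage for bandwidth; because every downstream quantity is a
  slope or offset in log-log space, the flat-top convention is kept and
  frozen in the tests.
* **Normalization.** One-sided power is \(|X_k|^2 \cdot 2 / n_\mathrm{eff}^2\)
  with \(n_\mathrm{eff} = 250\) the pre-padding length. Any fixed
  convention works (it moves \(\beta\), never \(x\)); this one makes a
  unit sinusoid at a bin frequency carry power ~0.5.
* **Band endpoints at print precision.** The 23rd bin lies at
  44.921875 Hz; analysis bands are conventionally quoted at 0.01-Hz
  precision, so bin membership is decided on frequencies rounded to two
  decimals. This retains exactly bins 1..23 for the default band.
* **ERP removal on matched trials.** The subtraction `total - erp` is only
  meaningful when both spectra come from the same trial set; then the
  difference is nonnegative by Jensen's inequality (mean of squared
  magnitudes \(\ge\) squared magnitude of the mean). Negative residuals
  beyond 1e-12 relative tolerance therefore raise a consistency error;
  tiny float negatives are clamped to zero, and bins that end up exactly
  zero are excluded from fitting with a warning.

## Parameterization algorithm

`fit_spectrum()` implements fixed-mode parameterization: (1) an initial
least-squares line in \((\log_{10} f, \log_{10} P)\) is refit using only
the points whose clamped positive residual is at or below the 2.5th
percentile, so oscillatory peaks cannot drag the line upward; (2) the
flattened residual spectrum is searched iteratively for maxima, accepted
as peaks while their height exceeds `peak_threshold` \(\times\) SD of the
current flattened spectrum (with a 1e-6 log-unit absolute floor so
machine-precision residuals of an exactly representable line never count
as peaks); each accepted peak is fit by bounded L-BFGS-B with analytic
gradients and subtracted; (3) peaks whose center lies within one fitted SD
of a band edge are discarded (edge artifacts of truncated Gaussians);
(4) survivors are refit jointly; (5) the joint peak model is subtracted
from the original log spectrum and the aperiodic line refit on the
peak-removed spectrum; (6) \(R^2\) is the squared Pearson correlation of
modeled and observed log power. A failed Gaussian fit is retried once from
the detected maximum and then skipped with a warning. Spectra with fewer
than five usable bins return `converged = FALSE` rather than a fit.

The "peak width limits = 3-8 Hz" are interpreted as full widths; Gaussian
SD bounds are half of them (1.5-4 Hz), and the search starts each peak at
the lower SD bound.

## The synthetic cohort

`simulate_cohort()` + `synthesize_epochs()` generate EEG whose ground
truth is recorded for recovery tests. Per 500-ms window, each trial
receives an independent stationary colored-noise segment built by inverse
FFT with complex-Gaussian coefficients whose expected log power follows
\(\beta - (x_0 + \Delta x_w)\log_{10} f\) plus the configured peaks; an
exponent delta \(\Delta x_w = +0.3\) makes that window steeper, so the
recovered slope shift is \(-0.3\). A damped-oscillation ERP template
(confined to 0-800 ms post-cue) is added identically to every trial,
making it strictly phase-locked — the generator-side oracle for the
ERP-removal stage. Behavior follows a shifted lognormal with additive
congruency, age-group and context terms, Bernoulli errors, rare timeouts,
and a linear coupling from each subject's injected mean slope shift to
their response speed, giving the cohort a known neuro-behavioral
association.

Default ground-truth values — baseline exponent ~1.4 (younger) / ~1.1
(older) with SD 0.15, biphasic deltas (+0.3, 0, -0.2) with SD 0.1, an
extra -0.15 on the last window's delta for older adults, a 10-Hz alpha
peak (height 0.6, SD 1.5 Hz), an 80-ms congruency effect and 4%/10%
error rates — are configurable placeholders chosen as physiologically
plausible magnitudes, not estimates of any particular dataset.

What the generator does **not** emulate: volume conduction and channel
covariance (channels are independent noise), ocular/muscle artifacts,
nonstationarity within a window, cross-window phase continuity (segments
are concatenated independently; an optional cross-fade defaults to 0 ms),
and 1/f "knees". Passing recovery tests therefore demonstrates
correctness of the estimators under the stated generative model, not
robustness to every property of real recordings.

## Statistical decisions

* **Permutation scheme.** Observed F statistics come from the classical
  split-plot decomposition (verified against `aov()` in the tests). For
  within-subject effects the null distribution flips the sign of each
  subject's effect contrasts; for effects involving the between factor it
  permutes group labels. Sign flips are drawn *independently* per subject
  (each flips with probability 1/2): this set of transformations is a
  group, making the test exact under symmetry of the subject contrasts.
  Flipping exactly half the subjects per iteration is available as
  `flip = "half"`, but it is not closed under composition and measured
  slightly anticonservative for within effects in null calibration, so it
  is not the default. The scheme is isolated in one place so alternatives
  can be swapped.
* **Shift sign.** Shifts are post-cue minus pre-cue slope; the initial
  post-cue steepening is thus a *negative* Shift1 and a later flattening a
  *positive* Shift3.
* **Shift2 defaults.** Shift2 is always computed and stored; analyses that
  exclude it (the ANOVA defaults in the CLI) do so by selection, and the
  regressions re-include it.
* **Error-rate denominator.** Timeouts are treated as omissions: they are
  discarded by trimming and never enter ERR's denominator, which is
  correct + incorrect responses only.
* **Boundary conventions.** Fast guesses use \(\le 200\) ms; the slow
  bound uses \(\ge 1400\) ms for current-trial trimming and a strict
  \(> 1400\) ms for the preceding-trial epoch rule ("exceeded").
* **Rank regression.** Jaeckel's dispersion with Wilcoxon scores is
  minimized by golden-section (one predictor) or Nelder-Mead from the
  least-squares start (the objective is convex and piecewise linear; a
  brute-force grid oracle in the tests confirms the optimum to 1e-3).
  The scale \(\hat\tau\) uses the Koul-Sievers-McKean pairwise-difference
  window estimator with the conventional bandwidth (delta = 0.8, or 0.95
  in small samples). The "\(R^2\) analog" reported for model comparisons
  is the proportional reduction in dispersion
  \(1 - D_\mathrm{model}/D_\mathrm{null}\), and is labeled as such.
* **Regressions on averaged data.** Neuro-behavioral models are intended
  for electrode-averaged (or cluster-averaged) values; per-electrode fits
  are for mapping, not inference.

## Problem sizes in the tests and acceptance script

The bundled experiments are sized to give stable Monte-Carlo estimates at
desk scale: exponent recovery uses a 5-point exponent grid with 100
replicates at noise SD 0.05; ANOVA calibration uses 500 null datasets of
20 subjects with 1,000 sign flips each (the acceptance script uses 400
datasets with 500 flips); biphasic recovery uses 100 cohorts of 40
subjects with 12 trials per subject on one channel (30 cohorts in the
script); the rank-regression oracle uses 50 random n = 7 datasets against
a 1e-4 grid and 500 null replications of the dispersion-reduction test.
Larger designs change none of the logic — only runtime.

## Known limitations

With 23 frequency bins the parameterization cannot distinguish more than
a few overlapping peaks, and peaks near the band edges are deliberately
discarded. The permutation ANOVA requires a balanced design (every
subject in every within cell). The ERP-removal identity holds exactly
only when total and ERP spectra come from identical trial sets, which the
pipeline enforces. The generator's defaults encode plausible magnitudes,
so recovery results quantify estimator behavior under those conditions
rather than reproducing any specific empirical dataset.
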