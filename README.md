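# apershift

Event-related analysis of the **aperiodic (1/f^x) component** of epoched
EEG: how the broadband background of the power spectrum — a line with
slope −x in log-log space, commonly read as a proxy for cortical
excitation:inhibition (E:I) balance — *shifts within a trial* after a
cue, and how those shifts relate to behavior.

The package is written for EEG researchers who want a tested, scriptable
version of this pipeline:

1. **Epoching & rejection** — cue-locked epochs (−500..1498 ms at
   500 Hz), peak-to-peak artifact screening (200 µV in sliding 600-ms
   windows), exclusion of epochs following slow (>1400 ms) responses.
2. **Windowed spectra** — four successive 500-ms windows (pre-cue
   baseline + three post-cue), zero-padded 256-point FFTs, 1.95-Hz
   resolution over 1.95–44.92 Hz (bins 1..23).
3. **ERP-spectrum removal** — the spectrum of the cross-trial time-domain
   average (the phase-locked ERP) is subtracted from the trial-averaged
   total spectrum, isolating induced activity.
4. **Spectral parameterization** — fixed-mode decomposition of each
   spectrum into `log10 P(f) = β − x·log10 f + Σ Gaussians` (offset β,
   exponent x, ≤3 peaks of 3–8 Hz width, 2-SD threshold), with model-R²
   electrode QC.
5. **Cue-induced shifts** — `Shift_k = slope(post-cue-k) − slope(pre-cue)`
   per subject/channel/cue type; negative = steepening (more inhibition),
   positive = flattening (higher E:I ratio).
6. **Statistics** — mixed ANOVAs with sign-flip permutation p-values,
   planned paired/Welch comparisons with Cohen's d, Cousineau–Morey
   within-subject SEs, Spearman correlations, and rank-based (Wilcoxon
   score / Jaeckel dispersion) regressions with dispersion-reduction model
   comparison and a regress-out workflow.

A **synthetic-data generator** produces cohorts with recorded ground
truth — per-window exponent deltas, oscillatory peaks, a phase-locked ERP
template, and behavior coupled to the injected shifts — so every stage is
covered by parameter-recovery tests.

## Worked example

Simulate a small cohort with the generator's default biphasic ground
truth (exponent deltas +0.3 / 0 / −0.2 across the post-cue windows, an
extra age-related flattening in the last window), run the full pipeline,
and test the Time-Window effect:

```r
library(apershift)
cfg <- analysis_config()

truths <- simulate_cohort(n_younger = 6, n_older = 6, seed = 42)
tab <- cohort_tables(truths, cfg, dspec = design_spec(1, 1, 24),
                     channels = c("Fz", "Cz", "Pz"))

round(tapply(tab$shifts$value, tab$shifts[c("shift", "age_group")], mean), 3)
#>         age_group
#> shift     older younger
#>   Shift1 -0.269  -0.291
#>   Shift2  0.009  -0.050
#>   Shift3  0.337   0.136

sh <- tab$shifts[tab$shifts$shift %in% c("Shift1", "Shift3"), ]
permutation_mixed_anova(sh, "value", "subject",
                        within = "shift", between = "age_group",
                        n_perm = 2000, seed = 42)
#>            effect      F df1 df2      p   pes
#> 1       age_group   5.39   1  10 0.0400 0.350
#> 2           shift 146.74   1  10 0.0015 0.936
#> 3 age_group:shift   3.86   1  10 0.0890 0.278
```

Reading the output: the recovered shifts mirror the injected ground truth
— an initial *negative* shift (post-cue steepening, Shift1 ≈ −0.28, i.e.
a clockwise rotation toward inhibition) that reverses into a *positive*
shift before the imperative stimulus (Shift3 > 0, counterclockwise,
toward excitation), more strongly in the older group (0.337 vs 0.136, the
injected age effect). The permutation ANOVA flags the Time-Window effect
(F(1,10) = 146.7, permutation p ≈ 0.0015, ηp² = 0.94) and the Age-Group
effect (p = 0.04) at these small-sample sizes.

A command-line wrapper over the same functions ships in
`inst/cli/apershift.R`:

```sh
Rscript inst/cli/apershift.R run-all --out demo --seed 4
Rscript inst/cli/apershift.R simulate --out sim --seed 4
Rscript inst/cli/apershift.R fit --in sim/s01.h5 --out slopes_s01.tsv
```

## Documentation

The methods vignette (`vignettes/aperiodic-shift-methods.Rmd`) documents
the model and its assumptions, every tunable parameter with units and
defaults, the synthesis model and what it deliberately does not emulate,
numerical conventions (window half-openness, FFT normalization, band
endpoints at print precision, peak-fit bounds and edge rules), the
permutation scheme, and known limitations.
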