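# glmspectrum

Spectrum estimation for continuous electrophysiological recordings (EEG,
MEG, LFP — any regularly sampled time series) in which the averaging step of
the classical time-averaged (Welch) periodogram is replaced by a
mass-univariate general linear model. Instead of averaging the sliding-window
short-time Fourier spectra, `glmspectrum` fits, per frequency bin and
channel,

```
S_y(f, k) = X(k) B(f) + e(f)
```

over the K window segments, where X is a design matrix of condition
indicators, dynamic covariates and confound regressors. This keeps the
classical estimator as the simplest special case (a single constant
regressor reproduces the Welch average exactly) while adding, in one step:

- **contrast spectra** — copes `c'B̂(f)`, their squared standard errors
  (varcopes `[c'(X'X)⁺c]·σ̂²(f)`) and t-spectra `cope/√varcope`;
- **adaptive confound regression** — non-zero-mean artefact regressors
  (bad-segment counts, EOG traces) soak up artefact variance so condition
  estimates approach the artefact-free spectrum;
- **effect sizes** — Cohen's f² from nested-model R² differences, per
  frequency and channel;
- **model-projected spectra** — the fitted spectrum at a covariate's
  observed extremes, for visualisation;
- **multilevel group analysis** — stacked first-level cope-spectra fitted
  with a second, between-subject GLM (fixed effects);
- **non-parametric inference** — cluster-based permutation tests over the
  frequency × channel grid (sign-flip / row-shuffle column permutation,
  max cluster-mass null, add-one p-values).

Estimation uses the Moore–Penrose pseudo-inverse throughout, so
rank-deficient designs return the minimum-Euclidean-norm solution instead of
failing, and `design_diagnostics()` (correlations, singular values, VIFs)
makes collinearity visible before fitting.

The package is aimed at researchers who currently report Welch spectra and
condition differences computed from them, and want covariate/confound
modelling and defensible group-level statistics without changing their
spectral front end.

## Worked example

Simulate a two-minute recording alternating between two conditions every
10 s — a 1/f background plus a 9 Hz oscillation that is twice as strong in
the second ("eyes-closed"-like) condition, with artefact bursts and a blink
confound — then fit the six-contrast first-level model:

```r
library(glmspectrum)

sim <- simulate_recording(recording_spec(duration = 120, block_len = 10,
                                         seed = 1))
st  <- compute_stft(sim$ts, stft_config(nperseg = 500, noverlap = 250,
                                        freq_range = c(1, 45)))
fl  <- first_level_design(st$segments, sim$truth$condition,
                          confounds = list(bad_segments = sim$truth$artefact,
                                           eog = abs(sim$truth$eog)))
fit <- fit_glm(st, fl$design, fl$contrasts)
fit
#> <glms_fit> P=5 regressors, 89 freqs, 1 channel(s), dof=115
#>   contrasts: mean, open, closed, open>closed, linear_trend, bad_segments, eog

ib <- which.min(abs(st$freqs - 9))          # the 9 Hz bin
round(fit$copes[c("open", "closed", "open>closed"), ib, 1], 2)
#>        open      closed open>closed
#>       96.19      201.17     -104.98
round(fit$tstats["open>closed", ib, 1], 2)
#> [1] -7.56
```

The `open` and `closed` copes are the per-condition magnitude spectra at
9 Hz: the oscillation is about twice as large in the second condition, as
injected. The differential cope is negative (open minus closed) and its
t-spectrum value of −7.56 far exceeds the usual cluster-forming threshold
(`critical_t(205, 0.001)` = 3.34), the classic alpha-reactivity pattern.
First-level t-values are descriptive only; inference belongs at the group
level:

```r
g   <- simulate_group(12, recording_spec(duration = 60, block_len = 10),
                      group_effect = 1.5, seed = 2)
gd  <- stack_first_level(g$results, "open>closed")
gdes <- group_design_from_table(g$truth, "group")
gcs <- make_contrasts(list(group_weighted_mean_contrast(c(12, 12)),
                           c(1, -1)), c("grand_mean", "g1>g2"))
res <- cluster_permutation_test(gd, gdes, gcs, "g1>g2",
                                permutation_config(nperms = 1000, seed = 3))
res
#> <glms_cluster_result> contrast 'g1>g2', threshold t = 3.792 (dof 22), 1000 permutation(s)
#>   cluster 1: 11 points, 6.5-11.5 Hz, mass 71.19, p = 0.001998 *
```

The permutation test localises the injected group difference to a cluster
around the oscillation frequency.

See `vignettes/glm-spectrum-methods.Rmd` for the model, its assumptions, all
tunable parameters and the package's numerical choices, and
`inst/cli/glmspectrum.R` for a shell front end
(`simulate` / `first-level` / `group`).

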