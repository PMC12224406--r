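---
title: "The GLM-spectrum: model, estimation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GLM-spectrum: model, estimation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmspectrum)
```

## The model

The classical time-averaged (Welch) periodogram estimates a spectrum by
splitting a recording into overlapping, tapered windows, Fourier-transforming
each window, and averaging the per-window spectra. `glmspectrum` replaces
that final averaging step with a mass-univariate general linear model. For a
chosen spectral quantity $S_y(f, k)$ — the magnitude, power or log-power of
the short-time Fourier transform at frequency $f$ in segment $k$ — we fit,
independently for every frequency bin and channel,

$$ S_y(f, k) = X(k)\,B(f) + e(f), $$

where $X$ is a $K \times P$ design matrix over the $K$ segments and $B(f)$
are the regression parameters ("beta-spectra"). A single constant regressor
makes the fitted beta-spectrum *exactly* the time-averaged spectrum, so the
classical estimator is the simplest special case; richer designs add
condition indicators, dynamic covariates and confounds on top of it without
changing the estimator's baseline behaviour. The test suite checks this
equivalence to machine precision.

Regressor semantics matter and are explicit in the package:

* **constant** — a column of ones; models the mean (or the intercept when
  non-zero-mean confounds are present).
* **categorical** — $\{0,1\}$ condition indicators (one column per
  condition, no global intercept); a signed $\pm 1$ coding is accepted for
  differential regressors.
* **parametric (demeaned / z-scored)** — dynamic covariates modelling
  variation *around* the mean. Demeaning does not change the slope
  interpretation; it keeps the constant regressor interpretable as a mean.
  The z-transform uses the sample standard deviation (denominator $K - 1$).
* **confound (non-zero mean)** — artefact regressors carried raw, so the
  condition regressors act as intercepts and the confound's share of the
  mean is regressed out. The amount of denoising adapts to how predictive
  the confound actually is in each dataset.

Sample-level covariates (artefact indicators, EOG traces) are prepared like
the data itself: segmented identically and summed within each window
(`aggregate_to_segments()`); overlapping windows intentionally double-count
shared samples.

## Estimation

Parameters are estimated with the Moore–Penrose pseudo-inverse,
$\hat B(f) = X^{+} S_y(f)$, computed once per design and reused across all
frequency-by-channel targets. For a full-column-rank design this equals
ordinary least squares; under exact multicollinearity it returns the
minimum-Euclidean-norm solution, and the associated contrast variances are
inflated accordingly, so partially collinear designs degrade gracefully
instead of failing. `design_diagnostics()` reports column correlations, the
singular-value spectrum, and variance inflation factors so degenerate
designs are visible before fitting; the VIF auxiliary regressions include an
intercept, which keeps $\mathrm{VIF} \ge 1$ for any design, including
indicator-only ones.

Contrasts are $P \times N_c$ weight matrices. For contrast $c$:

$$ \mathrm{cope}(f) = c^\top \hat B(f), \qquad
   \mathrm{varcope}(f) = \left[c^\top (X^\top X)^{+} c\right]\,
   \hat\sigma^2(f), \qquad
   t(f) = \mathrm{cope}(f)/\sqrt{\mathrm{varcope}(f)}. $$

Two numerical choices are worth stating. First, the residual variance is
normalised by the residual degrees of freedom,
$\hat\sigma^2(f) = \mathrm{RSS}(f) / (K - \mathrm{rank}(X))$, so that the
contrast $t$-statistics reduce exactly to the classical one-sample and
pooled-variance independent-samples $t$-tests for the corresponding designs
— a property the test suite verifies against textbook formulas on thousands
of random instances. Second, only the diagonal of
$C^\top (X^\top X)^{+} C$ is ever needed, so it is accumulated directly as
$\sum_i [(X^\top X)^{+} c]_i\, c_i$ per contrast without materialising the
full $N_c \times N_c$ product; the tests confirm the shortcut equals the
full-product diagonal to $10^{-12}$.

Degenerate bins are flagged rather than thrown: an exactly-fitted bin has
$t = 0$ when its cope is also zero and a signed infinity otherwise, and a
saturated design ($\mathrm{dof} = 0$) still returns betas while marking
inference unavailable. $R^2$ always uses the mean-centred total sum of
squares — including for constant-free designs — so values are comparable
across models. Cohen's $f^2$ effect sizes compare the full model to a
reduced model per frequency and channel; for `"conditions"` the reduced
model pools all condition indicators into one shared mean column, measuring
what separate condition means add. Negative floating-point residue is
clipped at zero.

Model-projected spectra evaluate the fit at a covariate's observed extremes,
$\max(R_v)\hat B_{rv}(f) + \mathrm{cope}_{\text{mean}}(f)$, purely as a
visualisation of the spectral range a covariate spans; they carry no
inferential weight.

## The spectral front end

`compute_stft()` uses a periodic (not symmetric) Hann taper — the standard
choice for averaged overlapping spectra — or a rectangular window. The
frequency axis is one-sided with no amplitude doubling, and power is
normalised by the window length $N$; Welch-convention normalisation by the
window energy $\sum w^2$ is available as an opt-in flag
(`window_energy_scaling`). Trailing samples that do not fill a complete
window are dropped. Log-power clips power at $10^{-300}$ before the log so
silent bins produce a large negative number rather than $-\infty$ inside the
GLM. Frequency-range restriction is inclusive at both endpoints and applied
after the FFT. The magnitude spectrum is the default dependent variable: it
is close to Gaussian in practice and robust to the outliers that raw power's
positive skew amplifies.

## Group level

The group model is a fixed-effects multilevel analysis: one chosen
first-level cope-spectrum is stacked across datasets
(`stack_first_level()`, validating identical frequency grids and channel
counts) and a second GLM is fitted over subjects with the same machinery,
$\mathrm{dof} = N - \mathrm{rank}(X_{\text{group}})$. Carrying only copes
forward means every dataset contributes equally; varcope carry-forward and
mixed-effects estimation are deliberately out of scope. Between-subject
covariates are z-scored across subjects by default so group indicator
columns model group means, and the participant-weighted mean contrast
$[n_1/N, n_2/N, 0, \dots]$ recovers the grand mean exactly. Subjects with
missing channels are rejected rather than imputed.

## Permutation inference

Group contrasts are tested non-parametrically. Only the design columns with
non-zero weight in the tested contrast are manipulated (Draper–Stoneman
column permutation): independent $\pm 1$ sign flips per row for categorical
regressors, one shared row shuffle for parametric ones; all other columns
are left bit-identical. Draper–Stoneman can behave erratically in very small
samples, so the package warns below $N = 12$.

Clusters are formed on the frequency $\times$ channel grid from points
exceeding a two-tailed Student-$t$ threshold (default forming
$p = 0.001$; at the headline group scale, $t(205) = 3.34$). Frequency bins
are adjacent when consecutive; channels are adjacent per a user-supplied
symmetric, irreflexive 0/1 matrix; there is no diagonal coupling. Clusters
smaller than `extent_threshold + 1` points are discarded (default: at least
2 adjacent points). The cluster statistic is the **mass** — the sum of
member $t$ values — which subsumes extent and is the common default. Each
permutation contributes the maximum $|$mass$|$ over both tails to a single
null distribution, controlling the two-tailed family-wise error once, and
cluster p-values use the add-one rule $p = (1 + b)/(1 + m)$ so the identity
permutation is always counted and $p = 0$ is impossible. The default
permutation count is 2500; everything is bit-reproducible from the seed.

### Calibration study design

The acceptance study verifies family-wise error calibration with 400
independent null cohorts of $N = 20$ subjects of white-noise cope-spectra on
a $16 \times 3$ grid, 500 permutations each at $\alpha = 0.05$. This study
uses a liberal cluster-forming threshold ($p = 0.05$) rather than the
analysis default of $0.001$: under a pure null on a small grid, a $0.001$
threshold almost never yields any suprathreshold cluster, so the empirical
rejection rate would sit near zero and say nothing about the correctness of
the max-statistic machinery. At $p = 0.05$ observed clusters occur in a
meaningful fraction of repeats and the empirical family-wise error rate is
expected to match the nominal level — which is what the suite checks against
the exact binomial acceptance band.

## The synthetic generator

`simulate_recording()` produces the data structure the model assumes:

* a **1/f background** made by frequency-domain shaping of white noise, so
  the log-log power slope is controlled exactly (default exponent 1, typical
  of broadband electrophysiological spectra);
* a **narrowband oscillation** (default 9 Hz, 1 Hz bandwidth) built from
  band-filtered noise rather than a pure sinusoid, so spectra have realistic
  width;
* **alternating condition blocks** (default 16 one-minute blocks at 250 Hz,
  mirroring an alternating eyes-open/eyes-closed protocol) scaling the
  oscillation amplitude by per-condition multipliers (default 1 and 2 — the
  closed-eyes-like condition has the stronger alpha);
* a **linear amplitude drift** (default $\pm 5\%$ over the recording) for
  time-on-task effects;
* **artefact bursts** (default 1/min, 1 s, $8\times$ background amplitude)
  of injected broadband noise with a per-sample indicator returned;
* an **EOG-like blink trace** (default 12 blinks/min, 0.3 s Gaussian
  kernels) whose kernel multiplies the oscillation envelope through a signed
  coupling coefficient, negative by default so blink-rich segments have
  suppressed alpha.

All randomness flows through one seeded generator; per-subject seeds in
`simulate_group()` derive deterministically from the master seed. The ground
truth (condition labels, artefact indicator, EOG trace, true envelope) is
returned for recovery testing.

What the generator does *not* emulate: volume conduction and realistic
sensor geometry, non-Gaussian heavy-tailed artefacts, temporal
autocorrelation structure beyond what windowing induces, and non-stationary
oscillation frequency. Passing recovery tests on this generator therefore
demonstrates the statistical machinery is correct under its own assumptions,
not that real EEG meets those assumptions. In particular, first-level
residuals of real recordings are autocorrelated, which is why the package
computes no first-level p-values: first-level results are descriptive, and
inference happens at the group level where subjects are exchangeable.

## Design choices that were genuinely open

* **Segment covariate sampling.** The linear-trend covariate is sampled at
  segment centres before z-scoring (segment starts would work equally; the
  centre is the less biased representative of a window).
* **Condition labels for boundary segments** are taken from the sample at
  the window centre.
* **Serialisation format.** First-level and group results are written as a
  single JSON document with explicit array dimensions — human-readable,
  dependency-light and diff-friendly; this file is the unit the group level
  consumes.
* **Rank tolerance** follows the standard SVD machine-precision rule
  $\max(K, P)\,\varepsilon\,s_{\max}$ everywhere (rank reporting and
  pseudo-inversion), so the two cannot disagree.
* **Segment starts are 1-based**, following R indexing conventions.

## Problem sizes used by the tests

The suite exercises full-scale parameters where they are cheap (the
$t(205)$ threshold, 2 s / 250 Hz spectral resolution, 1000-instance t-test
equivalences) and deliberately compact simulations elsewhere: 120 s
recordings over 40 seeds for condition-effect recovery, 90 s recordings over
20 seeds for the confound-denoising check, and the 400-repeat calibration
study described above. These sizes give Monte-Carlo error well inside the
asserted bounds while keeping the whole suite fast enough to run routinely.

## Known limitations

* No first-level inferential statistics (autocorrelated residuals).
* Fixed-effects group model only; no FLAME-style mixed effects or
  varcope/t carry-forward.
* Real-valued spectra only; the complex spectrum is rejected at the fit
  boundary.
* OLS only — no robust, regularised or Bayesian fitting.
* Draper–Stoneman permutation only; Manly / Freedman–Lane variants are not
  implemented.

## A compact worked example

```{r example, eval = FALSE}
sim <- simulate_recording(recording_spec(duration = 120, block_len = 10,
                                         seed = 1))
st <- compute_stft(sim$ts, stft_config(nperseg = 500, noverlap = 250,
                                       freq_range = c(1, 45)))
fl <- first_level_design(st$segments, sim$truth$condition,
                         confounds = list(bad_segments = sim$truth$artefact,
                                          eog = abs(sim$truth$eog)))
fit <- fit_glm(st, fl$design, fl$contrasts)
fit$copes["open>closed", which.min(abs(st$freqs - 9)), 1]  # alpha reactivity
```
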