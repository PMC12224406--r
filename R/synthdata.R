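# Synthetic recordings with the statistical structure the spectrum GLM is
# designed for: a 1/f-sloped background, a narrowband alpha-like oscillation
# whose amplitude alternates between two conditions, a slow linear amplitude
# drift, intermittent high-variance artefact bursts, and an EOG-like blink
# trace negatively coupled to the oscillation amplitude. All ground-truth
# quantities are returned so recovery can be tested end to end.

#' Recording specification for the synthetic generator
#'
#' Defaults describe an alternating eyes-open / eyes-closed style resting
#' recording: 16 one-minute blocks at 250 Hz, a 9 Hz oscillation twice as
#' strong in the second (eyes-closed-like) condition, a mild amplitude drift,
#' roughly one artefact burst and a dozen blinks per minute, and a negative
#' blink-to-oscillation coupling.
#'
#' @param duration Recording length in seconds; must be a whole multiple of
#'   `block_len`.
#' @param fs Sampling rate in Hz.
#' @param nchan Channel count.
#' @param slope Exponent of the 1/f-type background: power falls off as
#'   `f^-slope` on log-log axes.
#' @param background_amp Background noise standard deviation.
#' @param osc_freq Oscillation centre frequency in Hz.
#' @param osc_bw Oscillation bandwidth (Gaussian sd of the spectral mask) in
#'   Hz; the carrier is narrowband-filtered noise, not a pure sinusoid.
#' @param osc_amp Base oscillation amplitude.
#' @param topography Per-channel oscillation weights (default all ones).
#' @param block_len Condition block length in seconds; conditions alternate
#'   block by block.
#' @param cond_multipliers Oscillation amplitude multiplier per condition
#'   (length 2).
#' @param cond_names Condition labels.
#' @param trend Fractional linear amplitude drift over the recording
#'   (0.1 = +/-5 percent around the middle).
#' @param artefact_rate Artefact bursts per minute.
#' @param artefact_duration Burst duration in seconds.
#' @param artefact_amp Burst noise amplitude as a multiple of
#'   `background_amp`.
#' @param blink_rate Blinks per minute.
#' @param blink_width Blink kernel width (seconds).
#' @param eog_coupling Signed coefficient linking the blink kernel to a
#'   transient change of oscillation amplitude (default negative: blinks
#'   suppress the oscillation).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return Object of class `glms_recording_spec`.
#' @export
recording_spec <- function(duration = 960, fs = 250, nchan = 1,
                           slope = 1, background_amp = 1,
                           osc_freq = 9, osc_bw = 1, osc_amp = 1,
                           topography = NULL,
                           block_len = 60, cond_multipliers = c(1, 2),
                           cond_names = c("open", "closed"),
                           trend = 0.1,
                           artefact_rate = 1, artefact_duration = 1,
                           artefact_amp = 8,
                           blink_rate = 12, blink_width = 0.3,
                           eog_coupling = -0.3,
                           seed = 1) {
  if (is.null(topography)) topography <- rep(1, nchan)
  if (length(topography) != nchan) {
    .stop_validation("'topography' must have one weight per channel")
  }
  if (length(cond_multipliers) != 2 || length(cond_names) != 2) {
    .stop_validation("exactly two alternating conditions are supported")
  }
  if (abs(duration / block_len - round(duration / block_len)) > 1e-9) {
    .stop_validation("'block_len' must divide 'duration' exactly")
  }
  rates <- c(slope = slope, background_amp = background_amp, osc_bw = osc_bw,
             osc_amp = osc_amp, artefact_rate = artefact_rate,
             artefact_duration = artefact_duration, artefact_amp = artefact_amp,
             blink_rate = blink_rate, blink_width = blink_width,
             cond_multipliers)
  if (any(rates < 0)) .stop_validation("rates and amplitudes must be non-negative")
  structure(list(duration = duration, fs = fs, nchan = nchan, slope = slope,
                 background_amp = background_amp, osc_freq = osc_freq,
                 osc_bw = osc_bw, osc_amp = osc_amp, topography = topography,
                 block_len = block_len, cond_multipliers = cond_multipliers,
                 cond_names = cond_names, trend = trend,
                 artefact_rate = artefact_rate,
                 artefact_duration = artefact_duration,
                 artefact_amp = artefact_amp, blink_rate = blink_rate,
                 blink_width = blink_width, eog_coupling = eog_coupling,
                 seed = seed),
            class = "glms_recording_spec")
}

# Gaussian white noise shaped in the frequency domain to a target log-log
# power slope (power ~ f^-slope), unit output sd. Frequencies below 0.5 Hz
# keep the 0.5 Hz gain so the DC region does not blow up.
.shaped_noise <- function(n, fs, slope) {
  x <- stats::rnorm(n)
  if (slope == 0) return(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  gain <- pmax(f_fold, 0.5)^(-slope / 2)
  y <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Narrowband carrier: white noise through a Gaussian spectral mask centred on
# f0 with sd bw, unit output sd.
.narrowband_noise <- function(n, fs, f0, bw) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  mask <- exp(-0.5 * ((f_fold - f0) / bw)^2)
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate a multichannel recording
#'
#' Generates `background + topography * carrier * envelope + artefacts`
#' where the envelope is
#' `osc_amp * condition_multiplier * (1 + trend drift) * (1 + coupling * blink kernel)`
#' (clipped at zero), the background is 1/f-shaped noise, the carrier is
#' narrowband-filtered noise, artefact bursts inject amplified white noise in
#' marked windows, and blink events build an EOG-like confound trace.
#'
#' @param spec A `glms_recording_spec`.
#' @return List with `ts` (a `glms_ts`) and `truth` (class
#'   `glms_ground_truth`): per-sample `condition` (integer) and
#'   `condition_labels`, `artefact` indicator, `eog` trace, `envelope`
#'   (per-sample true oscillation amplitude), and the `spec`.
#' @examples
#' sim <- simulate_recording(recording_spec(duration = 20, block_len = 10, seed = 7))
#' sim$ts
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "glms_recording_spec"))
  withr::with_seed(spec$seed, {
    n <- round(spec$duration * spec$fs)
    tt <- (seq_len(n) - 1) / spec$fs

    cond <- (floor(tt / spec$block_len) %% 2L) + 1L

    eog <- numeric(n)
    n_blinks <- stats::rpois(1, spec$blink_rate * spec$duration / 60)
    if (n_blinks > 0) {
      centres <- sort(stats::runif(n_blinks, 0, spec$duration))
      half <- 3 * spec$blink_width / 2
      for (cn in centres) {
        i0 <- max(1L, floor((cn - half) * spec$fs) + 1L)
        i1 <- min(n, ceiling((cn + half) * spec$fs))
        if (i1 < i0) next
        ti <- tt[i0:i1]
        eog[i0:i1] <- eog[i0:i1] + exp(-0.5 * ((ti - cn) / (spec$blink_width / 2))^2)
      }
    }

    envelope <- spec$osc_amp * spec$cond_multipliers[cond] *
      (1 + spec$trend * (tt / spec$duration - 0.5)) *
      (1 + spec$eog_coupling * eog)
    envelope <- pmax(envelope, 0)

    artefact <- integer(n)
    n_bursts <- stats::rpois(1, spec$artefact_rate * spec$duration / 60)
    if (n_bursts > 0) {
      starts <- stats::runif(n_bursts, 0,
                             max(spec$duration - spec$artefact_duration, 0))
      for (s in starts) {
        i0 <- floor(s * spec$fs) + 1L
        i1 <- min(n, i0 + round(spec$artefact_duration * spec$fs) - 1L)
        artefact[i0:i1] <- 1L
      }
    }

    carrier <- .narrowband_noise(n, spec$fs, spec$osc_freq, spec$osc_bw)
    osc <- carrier * envelope

    data <- matrix(0, n, spec$nchan)
    for (ch in seq_len(spec$nchan)) {
      bg <- spec$background_amp * .shaped_noise(n, spec$fs, spec$slope)
      data[, ch] <- bg + spec$topography[ch] * osc
      n_art <- sum(artefact)
      if (n_art > 0) {
        data[artefact == 1L, ch] <- data[artefact == 1L, ch] +
          spec$artefact_amp * spec$background_amp * stats::rnorm(n_art)
      }
    }

    ts <- time_series(data, spec$fs)
    truth <- structure(list(condition = cond,
                            condition_labels = spec$cond_names,
                            artefact = artefact, eog = eog,
                            envelope = envelope, spec = spec),
                       class = "glms_ground_truth")
    list(ts = ts, truth = truth)
  })
}

#' Standard first-level design for a synthetic recording
#'
#' Builds the condition + trend + confound design mirroring the generator's
#' structure: one `{0,1}` indicator per condition (segment condition taken at
#' the window centre), a z-scored linear trend sampled at segment centres,
#' and one non-zero-mean confound per supplied sample-level trace (summed
#' within each window). Contrasts: a proportion-weighted overall mean, one
#' selector per condition, the condition difference (first minus second),
#' and a selector per covariate.
#'
#' @param segments `glms_segments` (e.g. `stft$segments`).
#' @param condition Per-sample integer condition labels (1 or 2).
#' @param condition_names Length-2 labels.
#' @param confounds Named list of per-sample confound traces; each is summed
#'   within segments and entered raw (non-zero mean).
#' @param trend Include the z-scored linear trend covariate (default `TRUE`).
#' @return List with `design` and `contrasts`.
#' @export
first_level_design <- function(segments, condition,
                               condition_names = c("open", "closed"),
                               confounds = list(), trend = TRUE) {
  stopifnot(inherits(segments, "glms_segments"))
  if (length(condition) != segments$n_samples) {
    .stop_alignment("'condition' must have one label per sample")
  }
  centres <- segments$starts + segments$nperseg %/% 2L
  seg_cond <- condition[centres]
  regs <- list(
    finalize_regressor(as.numeric(seg_cond == 1L), "categorical", condition_names[1]),
    finalize_regressor(as.numeric(seg_cond == 2L), "categorical", condition_names[2])
  )
  if (trend) {
    regs <- c(regs, list(finalize_regressor(centres, "parametric_zscore", "linear_trend")))
  }
  for (nm in names(confounds)) {
    v <- aggregate_to_segments(confounds[[nm]], segments)
    regs <- c(regs, list(finalize_regressor(v, "confound_nonzero_mean", nm)))
  }
  dm <- assemble_design(regs)
  P <- ncol(dm$X)
  wlist <- list(mean_contrast_weights(dm, condition_names),
                selector_contrast_weights(dm, condition_names[1]),
                selector_contrast_weights(dm, condition_names[2]),
                diff_contrast_weights(dm, condition_names[1], condition_names[2]))
  cnames <- c("mean", condition_names,
              paste0(condition_names[1], ">", condition_names[2]))
  for (nm in setdiff(colnames(dm$X), condition_names)) {
    wlist <- c(wlist, list(selector_contrast_weights(dm, nm)))
    cnames <- c(cnames, nm)
  }
  list(design = dm, contrasts = make_contrasts(wlist, cnames))
}

#' Simulate a two-group cohort and fit all first levels
#'
#' Draws per-subject oscillation amplitudes `osc_amp ~ base + N(0, sd)` with
#' the second group shifted by `group_effect`, simulates each recording from
#' a per-subject seed derived deterministically from `seed`, and runs every
#' subject through the shared STFT + design + GLM recipe.
#'
#' @param n_per_group Subjects per group (>= 2 each).
#' @param base_spec A `glms_recording_spec` shared by all subjects (its
#'   `osc_amp` is the group-1 mean; its seed is ignored).
#' @param group_effect Shift of the oscillation amplitude in group 2.
#' @param between_subject_sd Between-subject sd of the oscillation amplitude.
#' @param seed Master seed.
#' @param stft_cfg STFT settings for the first level (default: 2 s windows,
#'   50 percent overlap, Hann, magnitude, 1-45 Hz).
#' @return List with `results` (list of `glms_fit`), `truth` (data frame:
#'   subject, group, osc_amp, seed) and `contrast_names`.
#' @export
simulate_group <- function(n_per_group, base_spec, group_effect = 0,
                           between_subject_sd = 0.1, seed = 1,
                           stft_cfg = NULL) {
  if (n_per_group < 2) .stop_validation("'n_per_group' must be at least 2")
  n <- 2L * as.integer(n_per_group)
  if (is.null(stft_cfg)) {
    stft_cfg <- stft_config(nperseg = 2 * base_spec$fs,
                            noverlap = base_spec$fs,
                            window = "hann", mode = "magnitude",
                            freq_range = c(1, 45))
  }
  seeds <- .derive_seeds(seed, n + 1L)
  amps <- withr::with_seed(seeds[n + 1L], {
    base_spec$osc_amp + stats::rnorm(n, 0, between_subject_sd) +
      rep(c(0, group_effect), each = n_per_group)
  })
  amps <- pmax(amps, 0.01)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- base_spec
    spec_i$osc_amp <- amps[i]
    spec_i$seed <- seeds[i]
    sim <- simulate_recording(spec_i)
    st <- compute_stft(sim$ts, stft_cfg)
    fl <- first_level_design(st$segments, sim$truth$condition,
                             condition_names = base_spec$cond_names,
                             confounds = list(bad_segments = sim$truth$artefact,
                                              eog = abs(sim$truth$eog)))
    results[[i]] <- fit_glm(st, fl$design, fl$contrasts, keep_residuals = FALSE)
  }
  truth <- data.frame(subject = paste0("subj", seq_len(n)),
                      group = rep(c(1L, 2L), each = n_per_group),
                      osc_amp = amps, seed = seeds[seq_len(n)])
  list(results = results, truth = truth,
       contrast_names = results[[1]]$contrasts$names)
}

#' Simulate a null group dataset of white-noise copes
#'
#' Convenience generator for permutation calibration studies: N subjects of
#' IID Gaussian cope-spectra with no structure.
#'
#' @param n_subjects Subject count.
#' @param n_freqs,n_channels Grid size.
#' @param sd Between-subject noise sd.
#' @param seed RNG seed.
#' @return A `glms_group_dataset`.
#' @export
simulate_null_copes <- function(n_subjects, n_freqs, n_channels = 1,
                                sd = 1, seed = 1) {
  data <- withr::with_seed(seed, {
    array(stats::rnorm(n_subjects * n_freqs * n_channels, 0, sd),
          dim = c(n_subjects, n_freqs, n_channels))
  })
  group_dataset(data, freqs = seq_len(n_freqs), source_contrast = "null")
}
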