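# Short-time Fourier transform and the time-averaged (Welch) spectrum.
#
# The sliding-window spectrum computed here is the dependent variable of the
# first-level GLM: values[k, f, c] holds the spectrum of segment k at
# frequency bin f for channel c.

#' Continuous multichannel time series
#'
#' Light container for a regularly sampled recording. A vector is treated as a
#' single channel.
#'
#' @param data Numeric vector or samples-by-channels matrix; all values must
#'   be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channel_names Optional character labels, one per channel.
#' @return An object of class `glms_ts` with elements `data` (matrix), `fs`
#'   and `channel_names`.
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * (0:999) / 250), fs = 250)
#' @export
time_series <- function(data, fs, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1) .stop_data("time series must contain at least one sample")
  if (!all(is.finite(data))) .stop_data("time series contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    .stop_config("'fs' must be a single positive number")
  }
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(colnames(data))) colnames(data)
      else paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data)) {
    .stop_validation("'channel_names' length does not match the channel count")
  }
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "glms_ts")
}

#' @export
print.glms_ts <- function(x, ...) {
  cat(sprintf("<glms_ts> %d samples x %d channel(s) @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' STFT configuration
#'
#' Window, overlap, taper and output-mode settings for [compute_stft()].
#'
#' @param nperseg Segment (window) length in samples.
#' @param noverlap Overlap between consecutive segments in samples;
#'   `0 <= noverlap < nperseg`.
#' @param window Taper: `"hann"` (periodic) or `"rectangular"`.
#' @param mode Output transform: `"magnitude"` (|Y|, the default dependent
#'   variable of the GLM-spectrum), `"power"` (|Y|^2 / N), `"log_power"`
#'   (natural log of power, floored at `log_floor`), or `"complex"`.
#' @param freq_range Optional `c(f_lo, f_hi)` in Hz; bins with
#'   `f_lo <= f <= f_hi` are retained (inclusive at both ends).
#' @param window_energy_scaling If `TRUE`, power is normalised by the window
#'   energy `sum(w^2)` (the Welch convention) instead of by `N`.
#' @param detrend If `TRUE`, the mean of each segment is removed before
#'   tapering.
#' @param log_floor Lower clip applied to power before taking logs, guarding
#'   against `-Inf` at exactly-zero bins.
#' @return An object of class `glms_stft_config`.
#' @export
stft_config <- function(nperseg, noverlap,
                        window = c("hann", "rectangular"),
                        mode = c("magnitude", "power", "log_power", "complex"),
                        freq_range = NULL,
                        window_energy_scaling = FALSE,
                        detrend = FALSE,
                        log_floor = 1e-300) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  nperseg <- as.integer(nperseg)
  noverlap <- as.integer(noverlap)
  if (nperseg < 2) .stop_config("'nperseg' must be at least 2")
  if (noverlap < 0 || noverlap >= nperseg) {
    .stop_config("'noverlap' must satisfy 0 <= noverlap < nperseg")
  }
  if (!is.null(freq_range)) {
    if (length(freq_range) != 2 || freq_range[1] >= freq_range[2]) {
      .stop_config("'freq_range' must be c(f_lo, f_hi) with f_lo < f_hi")
    }
  }
  structure(list(nperseg = nperseg, noverlap = noverlap, window = window,
                 mode = mode, freq_range = freq_range,
                 window_energy_scaling = isTRUE(window_energy_scaling),
                 detrend = isTRUE(detrend), log_floor = log_floor),
            class = "glms_stft_config")
}

#' Sliding-window segmentation
#'
#' Splits `n_samples` samples into overlapping windows of `nperseg` samples
#' with hop `nperseg - noverlap`. Trailing samples that do not fill a complete
#' window are dropped. Start indices are 1-based; segment k covers samples
#' `start[k] .. start[k] + nperseg - 1`.
#'
#' @param n_samples Total sample count, or a `glms_ts` object.
#' @param nperseg Window length in samples.
#' @param noverlap Overlap in samples.
#' @return An object of class `glms_segments`: list with `starts` (integer
#'   vector), `nperseg`, `noverlap`, `n_samples` and `K`.
#' @examples
#' segment_signal(10, nperseg = 4, noverlap = 2)$starts  # 1 3 5 7
#' @export
segment_signal <- function(n_samples, nperseg, noverlap) {
  if (inherits(n_samples, "glms_ts")) n_samples <- nrow(n_samples$data)
  n_samples <- as.integer(n_samples)
  nperseg <- as.integer(nperseg)
  noverlap <- as.integer(noverlap)
  if (noverlap >= nperseg || noverlap < 0) {
    .stop_config("'noverlap' must satisfy 0 <= noverlap < nperseg")
  }
  if (nperseg > n_samples) {
    .stop_data(sprintf(
      "empty segmentation: nperseg (%d) exceeds the %d available samples",
      nperseg, n_samples))
  }
  hop <- nperseg - noverlap
  K <- (n_samples - nperseg) %/% hop + 1L
  starts <- 1L + hop * (seq_len(K) - 1L)
  structure(list(starts = starts, nperseg = nperseg, noverlap = noverlap,
                 n_samples = n_samples, K = K),
            class = "glms_segments")
}

#' Taper weights
#'
#' @param window `"hann"` for the periodic Hann taper
#'   `w(n) = 0.5 * (1 - cos(2 * pi * n / N))`, `n = 0..N-1`, or
#'   `"rectangular"` for all ones.
#' @param nperseg Window length N (>= 2).
#' @return Numeric vector of `nperseg` non-negative weights.
#' @export
make_window <- function(window, nperseg) {
  nperseg <- as.integer(nperseg)
  if (nperseg < 2) .stop_config("'nperseg' must be at least 2")
  switch(window,
    rectangular = rep(1, nperseg),
    hann = 0.5 * (1 - cos(2 * pi * (seq_len(nperseg) - 1) / nperseg)),
    .stop_config(sprintf("unknown window type '%s'", window))
  )
}

#' Short-time Fourier transform
#'
#' Computes the tapered DFT of each sliding-window segment of each channel and
#' applies the configured output transform. The frequency axis is one-sided
#' (0 to fs/2); no one-sided amplitude doubling is applied, and power is
#' normalised by the segment length N (or by the window energy when
#' `window_energy_scaling` is set).
#'
#' @param ts A `glms_ts` time series.
#' @param config A `glms_stft_config`.
#' @return An object of class `glms_stft`: `values` (K segments x F
#'   frequencies x C channels array, complex only in `"complex"` mode),
#'   `freqs` (Hz), `segments` (the `glms_segments` used), `config`, `fs`,
#'   `channel_names` and `mode`.
#' @examples
#' ts <- time_series(rnorm(1000), fs = 250)
#' st <- compute_stft(ts, stft_config(250, 125))
#' dim(st$values)
#' @export
compute_stft <- function(ts, config) {
  stopifnot(inherits(ts, "glms_ts"), inherits(config, "glms_stft_config"))
  if (!all(is.finite(ts$data))) .stop_data("time series contains non-finite values")
  seg <- segment_signal(nrow(ts$data), config$nperseg, config$noverlap)
  N <- config$nperseg
  K <- seg$K
  C <- ncol(ts$data)
  w <- make_window(config$window, N)
  nfreq <- N %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1) * ts$fs / N

  sample_idx <- outer(0:(N - 1L), seg$starts, "+")  # N x K
  complex_mode <- identical(config$mode, "complex")
  vals <- if (complex_mode) array(complex(real = 0), dim = c(K, nfreq, C))
          else array(0, dim = c(K, nfreq, C))
  for (ch in seq_len(C)) {
    segs <- matrix(ts$data[, ch][sample_idx], nrow = N, ncol = K)
    if (config$detrend) segs <- sweep(segs, 2, colMeans(segs))
    Y <- stats::mvfft(segs * w)[seq_len(nfreq), , drop = FALSE]  # F x K
    vals[, , ch] <- switch(config$mode,
      complex   = t(Y),
      magnitude = t(Mod(Y)),
      power     = t(.stft_power(Y, N, w, config$window_energy_scaling)),
      log_power = t(log(pmax(.stft_power(Y, N, w, config$window_energy_scaling),
                             config$log_floor)))
    )
  }

  if (!is.null(config$freq_range)) {
    keep <- freqs >= config$freq_range[1] & freqs <= config$freq_range[2]
    if (!any(keep)) .stop_config("'freq_range' retains no frequency bins")
    freqs <- freqs[keep]
    vals <- vals[, keep, , drop = FALSE]
  }

  structure(list(values = vals, freqs = freqs, segments = seg,
                 config = config, fs = ts$fs,
                 channel_names = ts$channel_names, mode = config$mode),
            class = "glms_stft")
}

.stft_power <- function(Y, N, w, window_energy_scaling) {
  denom <- if (window_energy_scaling) sum(w^2) else N
  Mod(Y)^2 / denom
}

#' Wrap an existing spectral array as an STFT object
#'
#' Builds a `glms_stft` from a pre-computed real-valued array, so data coming
#' from other estimators (or simulations working directly at the segment
#' level) can flow through the same GLM machinery.
#'
#' @param values K x F x C numeric array (a K x F matrix is promoted to one
#'   channel).
#' @param freqs Frequency axis of length F.
#' @param mode Label for the spectral quantity stored (default
#'   `"magnitude"`).
#' @param channel_names Optional channel labels.
#' @return A `glms_stft`.
#' @export
stft_object <- function(values, freqs, mode = "magnitude",
                        channel_names = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3) .stop_validation("'values' must be K x F x C")
  if (dim(values)[2] != length(freqs)) {
    .stop_alignment("'freqs' length does not match dim(values)[2]")
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(values)[3]))
  structure(list(values = values, freqs = as.numeric(freqs), segments = NULL,
                 config = NULL, fs = NA_real_, channel_names = channel_names,
                 mode = mode),
            class = "glms_stft")
}

#' @export
print.glms_stft <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<glms_stft> %d segments x %d freqs x %d channel(s), mode '%s'\n",
              d[1], d[2], d[3], x$mode))
  cat(sprintf("  freqs: %g .. %g Hz\n", min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Time-averaged (Welch) spectrum
#'
#' Arithmetic mean of the time-varying spectrum over segments. With a Hann
#' taper and overlapping segments in `"power"` mode this is Welch's
#' periodogram; fitting a single constant regressor with [fit_glm()] gives
#' the identical estimate.
#'
#' @param stft A real-mode `glms_stft`.
#' @return Object of class `glms_spectrum`: `values` (F x C matrix) and
#'   `freqs`.
#' @export
welch_spectrum <- function(stft) {
  stopifnot(inherits(stft, "glms_stft"))
  if (identical(stft$mode, "complex")) {
    .stop_config("welch_spectrum() requires a real-valued STFT mode")
  }
  if (dim(stft$values)[1] == 0) .stop_data("empty segmentation: no segments to average")
  avg <- apply(stft$values, c(2, 3), mean)
  avg <- matrix(avg, nrow = length(stft$freqs),
                dimnames = list(NULL, stft$channel_names))
  structure(list(values = avg, freqs = stft$freqs, mode = stft$mode),
            class = "glms_spectrum")
}
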