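#' Segment a recording into fixed-length epochs
#'
#' Cuts a continuous multi-channel recording into non-overlapping,
#' consecutive epochs; remainder samples at the end are dropped.
#'
#' @param recording A `session_recording` (see [simulate_session()]) or a
#'   channels x samples matrix with attribute/argument `fs`.
#' @param length_s Epoch length in seconds (default 2 s).
#' @param fs Sampling rate (Hz); taken from the recording when omitted.
#' @return Object of class `epoch_set`: `data` (samples x channels x
#'   n_epochs array), `fs`, `length_s`.
#' @export
epoch <- function(recording, length_s = 2, fs = NULL) {
  if (inherits(recording, "session_recording")) {
    if (is.null(fs)) fs <- recording$fs
    x <- recording$data
  } else {
    x <- recording
    if (is.null(fs)) fs <- attr(recording, "fs")
  }
  if (is.null(fs)) stop("sampling rate `fs` is required")
  nsamp <- as.integer(round(length_s * fs))
  nchan <- nrow(x)
  n_ep <- floor(ncol(x) / nsamp)
  if (n_ep < 1) stop("recording shorter than one epoch")
  arr <- aperm(array(x[, seq_len(n_ep * nsamp), drop = FALSE],
                     c(nchan, nsamp, n_ep)), c(2, 1, 3))
  structure(list(data = arr, fs = fs, length_s = length_s,
                 n_epochs = n_ep, n_channels = nchan),
            class = "epoch_set")
}

# Complex Fourier coefficients of every epoch after windowing and
# zero-padding: returns list(coefs = nfreq x nchan x n_epochs, freqs).
epoch_fourier <- function(epochs, window = "hanning", pad_to_s = 4) {
  nsamp <- dim(epochs$data)[1]
  nchan <- dim(epochs$data)[2]
  n_ep <- dim(epochs$data)[3]
  npad <- max(nsamp, as.integer(round(pad_to_s * epochs$fs)))
  win <- switch(window,
                hanning = 0.5 - 0.5 * cos(2 * pi * seq_len(nsamp) / (nsamp + 1)),
                none = rep(1, nsamp),
                stop("unknown window: ", window))
  nfreq <- npad %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1L) * epochs$fs / npad
  # FFT all epochs/channels at once
  buf <- matrix(0, npad, nchan * n_ep)
  buf[seq_len(nsamp), ] <- matrix(epochs$data, nsamp, nchan * n_ep) * win
  X <- stats::mvfft(buf)[seq_len(nfreq), , drop = FALSE]
  list(coefs = array(X, c(nfreq, nchan, n_ep)), freqs = freqs, npad = npad)
}

#' Averaged windowed FFT power spectrum
#'
#' Computes the per-epoch, Hanning-windowed, zero-padded FFT power spectrum
#' and averages it over epochs. At the defaults (2-s epochs, 250 Hz,
#' padding to 4 s) the frequency resolution is 0.25 Hz.
#'
#' @param epochs An [epoch()] set.
#' @param window `"hanning"` (default) or `"none"`.
#' @param pad_to_s Zero-pad each epoch to this many seconds before the FFT.
#' @return Object of class `power_spectrum`: `freqs` (Hz), `power`
#'   (channels x frequencies, T^2), `n_epochs`, `window`, `pad_to_s`.
#' @export
epoch_spectrum <- function(epochs, window = "hanning", pad_to_s = 4) {
  ef <- epoch_fourier(epochs, window, pad_to_s)
  spectrum_from_fourier(ef, epochs, window, pad_to_s)
}

# Average power spectrum from precomputed epoch Fourier coefficients.
spectrum_from_fourier <- function(ef, epochs, window = "hanning",
                                  pad_to_s = 4) {
  d <- dim(ef$coefs)
  a2 <- abs(ef$coefs)^2
  dim(a2) <- c(d[1] * d[2], d[3])
  pw <- matrix(rowMeans(a2), d[1], d[2])          # nfreq x nchan
  structure(list(freqs = ef$freqs, power = t(pw),
                 n_epochs = epochs$n_epochs, window = window,
                 pad_to_s = pad_to_s, fs = epochs$fs),
            class = "power_spectrum")
}

#' Individual alpha frequency from a power spectrum
#'
#' Finds the frequency of the power maximum within a closed band of the
#' channel-subset-averaged spectrum. Ties are broken toward the lowest
#' frequency. When the in-band spectrum is monotone (no interior local
#' maximum), the band-edge argmax is still returned, flagged by a warning
#' and the `flat_peak` attribute.
#'
#' @param spectrum A [epoch_spectrum()] result.
#' @param band Closed search band in Hz (default the alpha band, 8-12 Hz).
#' @param channels Integer channel subset to average (default: all).
#' @return IAF in Hz, with attribute `flat_peak`.
#' @export
detect_iaf <- function(spectrum, band = c(8, 12), channels = NULL) {
  if (band[1] < min(spectrum$freqs) || band[2] > max(spectrum$freqs))
    stop("band must lie within the spectrum's frequency range")
  if (is.null(channels)) channels <- seq_len(nrow(spectrum$power))
  avg <- colMeans(spectrum$power[channels, , drop = FALSE])
  sel <- which(spectrum$freqs >= band[1] - 1e-9 & spectrum$freqs <= band[2] + 1e-9)
  pin <- avg[sel]
  k <- which.max(pin)          # first maximum = lowest frequency on ties
  interior <- k > 1 && k < length(pin)
  if (!interior) {
    flat <- all(diff(pin) <= 0) || all(diff(pin) >= 0)
    if (flat) warning("no interior spectral maximum in band; returning band-edge argmax")
  }
  structure(spectrum$freqs[sel[k]], flat_peak = !interior)
}

#' Round the alpha peak to the stimulation frequency
#'
#' The tACS frequency is the integer nearest the identified alpha peak;
#' half-way ties round up.
#'
#' @param iaf Alpha peak frequency (Hz), positive.
#' @return Integer stimulation frequency (Hz).
#' @export
stimulation_frequency <- function(iaf) {
  if (any(iaf <= 0)) stop("iaf must be positive")
  as.integer(floor(iaf + 0.5))
}

#' Frequency-precision predictor from the baseline spectrum
#'
#' Extracts the dominant frequency `df` (in-band argmax of the all-channel
#' average spectrum of the baseline block) and the signed frequency
#' mismatch `sf - df` between the pre-determined stimulation frequency and
#' the baseline alpha peak.
#'
#' @param sf Integer stimulation frequency (Hz).
#' @param baseline_spectrum [epoch_spectrum()] of the pre-stimulation block.
#' @param band Dominant-frequency search band (Hz).
#' @param abs_mismatch Return `|sf - df|` instead of the signed mismatch.
#' @return List of class `frequency_predictors`: `iaf` (alias of `df`),
#'   `sf`, `df`, `mismatch`.
#' @export
frequency_mismatch <- function(sf, baseline_spectrum, band = c(8, 12),
                               abs_mismatch = FALSE) {
  df <- as.numeric(detect_iaf(baseline_spectrum, band = band))
  mm <- sf - df
  if (abs_mismatch) mm <- abs(mm)
  structure(list(iaf = df, sf = as.integer(sf), df = df, mismatch = mm),
            class = "frequency_predictors")
}

#' Posterior channel subset of a sensor array
#'
#' Returns the indices of the posterior third of the array (most negative
#' y coordinates), mirroring the fixed posterior sensor selection used for
#' alpha-peak detection.
#'
#' @param sensors A [sensor_array()].
#' @param fraction Fraction of sensors to keep (default 1/3).
#' @return Integer vector of channel indices.
#' @export
posterior_channels <- function(sensors, fraction = 1 / 3) {
  n <- nrow(sensors$positions)
  k <- max(1L, round(n * fraction))
  order(sensors$positions[, 2])[seq_len(k)]
}

#' Zero-phase band-pass filter for continuous recordings
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase shift). Off by default in the pipeline: the generator
#' produces band-limited content, so the filter mainly matters when
#' feeding in externally generated recordings.
#'
#' @param recording A `session_recording` (or channels x samples matrix
#'   with `fs` supplied).
#' @param low,high Band edges (Hz).
#' @param fs Sampling rate, taken from the recording when omitted.
#' @param order Butterworth order.
#' @return The recording with filtered data.
#' @export
bandpass_filter <- function(recording, low = 1, high = 40, fs = NULL,
                            order = 4) {
  is_rec <- inherits(recording, "session_recording")
  x <- if (is_rec) recording$data else recording
  if (is.null(fs)) fs <- if (is_rec) recording$fs else attr(recording, "fs")
  if (is.null(fs)) stop("sampling rate `fs` is required")
  if (low <= 0 || high >= fs / 2 || high <= low)
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  if (is_rec) {
    recording$data <- x
    recording
  } else x
}

#' Export a power spectrum as TSV
#'
#' Long-format table (frequency, channel, power).
#'
#' @param spectrum A [epoch_spectrum()] result.
#' @param path Output file path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  df <- data.frame(
    frequency = rep(spectrum$freqs, each = nrow(spectrum$power)),
    channel = rep(seq_len(nrow(spectrum$power)), length(spectrum$freqs)),
    power = as.vector(spectrum$power))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
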