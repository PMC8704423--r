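# Welch segment-averaged (cross-)spectrum. One-sided; `y = x` gives the PSD.
# Segments use a Hamming window with the given fractional overlap.
welch_spectrum <- function(x, y = x, fs, nperseg = 1024, overlap = 0.5) {
  n <- min(length(x), length(y))
  if (length(x) != length(y))
    warning("length mismatch; truncating to ", n, " samples")
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (n < nperseg) {
    nperseg <- 2^floor(log2(n))
    warning("signal shorter than segment; nperseg shrunk to ", nperseg)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  acc <- complex(real = numeric(nperseg), imaginary = numeric(nperseg))
  for (s in starts) {
    seg_x <- stats::fft(w * x[s:(s + nperseg - 1)])
    seg_y <- stats::fft(w * y[s:(s + nperseg - 1)])
    acc <- acc + Conj(seg_x) * seg_y
  }
  sxy <- acc / (length(starts) * fs * sum(w^2))
  half <- seq_len(floor(nperseg / 2) + 1)
  sxy <- sxy[half]
  sxy[-c(1, length(half))] <- 2 * sxy[-c(1, length(half))]
  list(freq_hz = (half - 1) * fs / nperseg, s = sxy)
}

#' Normalized Welch power spectral density of FFRs
#'
#' Welch PSDs (1024-point Hamming segments, 50% overlap by default) are
#' computed per tone, averaged across tones, converted to dB and normalized
#' so the maximum is exactly 0 dB. Because the FFR is dominated by F0
#' energy this effectively normalizes the F0 peak, making the roll-off of
#' the higher harmonics directly comparable between recording levels.
#'
#' @param ffrs A single waveform, an `ffr_waveform`, or a list of them
#'   (one per tone; averaged before normalization).
#' @param fs Sampling rate (taken from `ffr_waveform` input if absent).
#' @param channel Channel label for `ffr_waveform` input.
#' @param nperseg,overlap Welch parameters.
#' @return data.frame `freq_hz`, `psd_db` (max exactly 0 dB).
#' @export
welch_psd_norm <- function(ffrs, fs = NULL, channel = NULL,
                           nperseg = 1024, overlap = 0.5) {
  xs <- as_waveform_list(ffrs, channel)
  if (is.null(fs)) fs <- attr(xs, "fs")
  if (is.null(fs)) stop("fs must be given for plain numeric input")
  if (all(vapply(xs, function(x) all(x == 0), logical(1))))
    stop("all-zero signal; PSD normalization undefined")
  ps <- lapply(xs, function(x)
    welch_spectrum(x, x, fs, nperseg, overlap))
  pavg <- Reduce(`+`, lapply(ps, function(p) Re(p$s))) / length(ps)
  db <- 10 * log10(pmax(pavg, .Machine$double.xmin))
  data.frame(freq_hz = ps[[1]]$freq_hz, psd_db = db - max(db))
}

#' Cross-spectral density magnitude between two FFRs
#'
#' Welch cross-spectra (50% overlapping Hamming segments) are computed per
#' tone and their magnitudes averaged, quantifying shared spectral power
#' between recording levels irrespective of latency differences. This is a
#' power-coherence measure, not a measure of phase-locking.
#'
#' @param ffrs_a,ffrs_b Waveform(s) as in [welch_psd_norm()]; paired by
#'   position (tone).
#' @param fs Sampling rate.
#' @param channel_a,channel_b Channel labels for `ffr_waveform` input.
#' @param nperseg,overlap Welch parameters.
#' @return data.frame `freq_hz`, `cpsd` (magnitude).
#' @export
cross_spectral_density <- function(ffrs_a, ffrs_b, fs = NULL,
                                   channel_a = NULL, channel_b = NULL,
                                   nperseg = 1024, overlap = 0.5) {
  xa <- as_waveform_list(ffrs_a, channel_a)
  xb <- as_waveform_list(ffrs_b, channel_b)
  if (length(xa) != length(xb)) stop("tone lists differ in length")
  if (is.null(fs)) fs <- attr(xa, "fs")
  if (is.null(fs)) stop("fs must be given for plain numeric input")
  cs <- mapply(function(a, b) {
    sp <- welch_spectrum(a, b, fs, nperseg, overlap)
    Mod(sp$s)
  }, xa, xb, SIMPLIFY = FALSE)
  f <- welch_spectrum(xa[[1]], xa[[1]], fs, nperseg, overlap)$freq_hz
  data.frame(freq_hz = f, cpsd = Reduce(`+`, cs) / length(cs))
}

# normalize input forms: numeric vector, ffr_waveform, or list of either
as_waveform_list <- function(ffrs, channel = NULL) {
  fs <- NULL
  if (inherits(ffrs, "ffr_waveform")) {
    fs <- ffrs$fs; ffrs <- list(ffrs)
  } else if (is.numeric(ffrs)) ffrs <- list(ffrs)
  xs <- lapply(ffrs, function(f) {
    if (inherits(f, "ffr_waveform")) {
      fs <<- f$fs
      ffr_channel(f, channel)
    } else as.numeric(f)
  })
  attr(xs, "fs") <- fs
  xs
}

#' Continuous wavelet transform with a Morse wavelet
#'
#' Analytic generalized Morse wavelet (default gamma = 3, beta = 20)
#' evaluated in the frequency domain at the requested peak frequencies.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate.
#' @param freqs Peak frequencies, Hz.
#' @param gamma,beta Morse shape parameters.
#' @return Complex matrix, `length(freqs)` x `length(x)`.
#' @export
morse_cwt <- function(x, fs, freqs, gamma = 3, beta = 20) {
  n <- length(x)
  X <- stats::fft(x)
  fbin <- (seq_len(n) - 1) / n * fs
  out <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    ratio <- fbin / f
    H <- numeric(n)
    pos <- fbin > 0 & fbin <= fs / 2
    H[pos] <- 2 * ratio[pos]^beta *
      exp(-(beta / gamma) * (ratio[pos]^gamma - 1))
    out[i, ] <- stats::fft(X * H, inverse = TRUE) / n
  }
  out
}

#' Frequency-wise cross-correlation latency between scalp and cortical FFRs
#'
#' Both FFRs are decomposed with the Morse continuous wavelet transform;
#' at each frequency the real-valued band signals are cross-correlated
#' (normalized/Pearson form) over lags within `max_lag_ms`, and the lag of
#' the maximum absolute correlation is reported. Positive latencies mean
#' the cortical FFR lags the scalp FFR. Lags of one period or more at that
#' frequency are flagged as period-ambiguous. The Welch cross-spectral
#' magnitude at each frequency is attached for joint spectrotemporal
#' reading.
#'
#' @param ffr_scalp,ffr_cortex Equal-rate waveforms (vectors or
#'   `ffr_waveform`s).
#' @param fs Sampling rate.
#' @param freqs Analysis frequencies (default 70-250 Hz in 2 Hz steps).
#' @param max_lag_ms Lag search bound (default 30 ms, covering all
#'   plausible scalp-cortex latency differences).
#' @param gamma,beta Morse parameters.
#' @return A `latency_by_frequency` data.frame: `freq_hz`, `lag_ms`, `r`,
#'   `ambiguous`, `cpsd`.
#' @export
wavelet_xcorr_latency <- function(ffr_scalp, ffr_cortex, fs = NULL,
                                  freqs = seq(70, 250, by = 2),
                                  max_lag_ms = 30, gamma = 3, beta = 20) {
  if (length(freqs) == 0) stop("empty frequency grid")
  xs <- as_waveform_list(ffr_scalp); xc <- as_waveform_list(ffr_cortex)
  if (is.null(fs)) fs <- attr(xs, "fs")
  if (is.null(fs)) stop("fs must be given for plain numeric input")
  a <- xs[[1]]; b <- xc[[1]]
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  Wa <- morse_cwt(a, fs, freqs, gamma, beta)
  Wb <- morse_cwt(b, fs, freqs, gamma, beta)
  res <- t(vapply(seq_along(freqs), function(i) {
    xc_ <- xcorr_lag(Re(Wa[i, ]), Re(Wb[i, ]), fs, max_lag_ms)
    c(xc_$lag_ms, xc_$r)
  }, numeric(2)))
  sp <- welch_spectrum(a, b, fs, nperseg = min(1024, 2^floor(log2(n))))
  cpsd <- stats::approx(sp$freq_hz, Mod(sp$s), xout = freqs, rule = 2)$y
  out <- data.frame(freq_hz = freqs, lag_ms = res[, 1], r = res[, 2],
                    ambiguous = abs(res[, 1]) >= 1000 / freqs,
                    cpsd = cpsd)
  class(out) <- c("latency_by_frequency", "data.frame")
  out
}
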