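#' Fundamental-frequency contour for a Mandarin tone
#'
#' Returns the ground-truth F0 trajectory used to synthesize the vowel /yi/
#' carrying one of the four Mandarin lexical tones: T1 (high-level, 129 Hz),
#' T2 (low-rising, 109 to 133 Hz), T3 (low-dipping, 89 to 111 Hz) and T4
#' (high-falling, 140 to 92 Hz).
#'
#' Only the endpoints/extrema of the natural productions are documented, so
#' the trajectory shapes are modelled: T1 is constant; T2 and T4 are
#' raised-cosine ramps (zero slope at onset and offset, mimicking the
#' flattening of natural F0 movements at voicing boundaries); T3 is a
#' piecewise-cosine dip that starts at 105 Hz, reaches its 89 Hz minimum at
#' 60% of the vowel duration and rises to 111 Hz at offset.
#'
#' @param tone_id One of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @param n_samples Number of contour samples.
#' @param fs Sampling rate in Hz (only used to label the time axis).
#' @return Numeric vector of length `n_samples`, instantaneous F0 in Hz.
#' @examples
#' f0 <- make_f0_contour("T2", 1000, 4000)
#' range(f0)  # 109 133
#' @export
make_f0_contour <- function(tone_id, n_samples, fs) {
  if (length(tone_id) != 1L || !tone_id %in% c("T1", "T2", "T3", "T4"))
    stop("unknown tone_id: ", paste(tone_id, collapse = ","),
         " (expected one of T1, T2, T3, T4)")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  u <- if (n_samples == 1L) 0 else seq(0, 1, length.out = n_samples)
  # raised-cosine ramp from a to b over u in [0, 1]
  ramp <- function(a, b) a + (b - a) * (1 - cos(pi * u)) / 2
  f0 <- switch(tone_id,
    T1 = rep(129, n_samples),
    T2 = ramp(109, 133),
    T4 = ramp(140, 92),
    T3 = {
      brk <- 0.6
      out <- numeric(n_samples)
      lo <- u <= brk
      out[lo]  <- 89 + (105 - 89) * (1 + cos(pi * u[lo] / brk)) / 2
      out[!lo] <- 89 + (111 - 89) * (1 - cos(pi * (u[!lo] - brk) / (1 - brk))) / 2
      out
    })
  f0
}

# fixed two-resonance /i/-like spectral envelope; gain at frequency f (Hz).
# Lorentzian peaks near 300 Hz (F1) and 2200 Hz (F2); the analyses downstream
# only require F0 and harmonics to be present with a speech-like tilt.
vowel_envelope_gain <- function(freq_hz) {
  res <- function(f, fc, bw) 1 / (1 + ((f - fc) / bw)^2)
  res(freq_hz, 300, 200) + 0.35 * res(freq_hz, 2200, 400)
}

#' Synthesize a Mandarin tone stimulus
#'
#' Generates the vowel stimulus as a harmonic source following the tone's F0
#' contour, spectrally shaped by a fixed two-resonance /i/-like envelope, and
#' peak-normalized. Deterministic for fixed inputs.
#'
#' @param tone_id One of `"T1"`..`"T4"`.
#' @param fs Sampling rate, samples/s (default 48000).
#' @param duration_s Duration in seconds (default 0.25).
#' @param n_harmonics Number of harmonics of the (time-varying) F0 to sum;
#'   harmonics above Nyquist are dropped automatically.
#' @return A `tone_stimulus` object: list with `tone_id`, `waveform`
#'   (peak-normalized, `abs(x) <= 1`), `fs`, `duration_s` and `f0_contour`
#'   (per-sample ground-truth F0, Hz).
#' @examples
#' st <- synthesize_tone("T1")
#' length(st$waveform)  # 12000
#' @export
synthesize_tone <- function(tone_id, fs = 48000, duration_s = 0.25,
                            n_harmonics = 20) {
  if (fs < 8000) stop("fs must be >= 8000")
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- round(fs * duration_s)
  f0 <- make_f0_contour(tone_id, n, fs)
  phase <- 2 * pi * cumsum(f0) / fs
  x <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    fk <- k * f0
    if (all(fk >= fs / 2)) break
    amp <- (1 / k) * vowel_envelope_gain(fk)
    amp[fk >= fs / 2] <- 0
    x <- x + amp * sin(k * phase)
  }
  # 5 ms raised-cosine onset/offset gate to avoid spectral splatter
  x <- x * cos_gate(n, fs, ramp_s = 0.005)
  x <- 0.95 * x / max(abs(x))
  structure(list(tone_id = tone_id, waveform = x, fs = fs,
                 duration_s = n / fs, f0_contour = f0),
            class = "tone_stimulus")
}

# raised-cosine on/off gate
cos_gate <- function(n, fs, ramp_s = 0.005) {
  nr <- min(round(ramp_s * fs), floor(n / 2))
  g <- rep(1, n)
  if (nr > 0) {
    r <- (1 - cos(pi * seq(0, 1, length.out = nr))) / 2
    g[seq_len(nr)] <- r
    g[(n - nr + 1):n] <- rev(r)
  }
  g
}

#' @export
print.tone_stimulus <- function(x, ...) {
  cat(sprintf("<tone_stimulus %s: %.0f ms @ %g Hz, F0 %.0f-%.0f Hz>\n",
              x$tone_id, 1000 * x$duration_s, x$fs,
              min(x$f0_contour), max(x$f0_contour)))
  invisible(x)
}

#' Synthesize all four Mandarin tone stimuli
#'
#' @inheritParams synthesize_tone
#' @return Named list of [synthesize_tone()] results for T1..T4.
#' @export
synthesize_tone_set <- function(fs = 48000, duration_s = 0.25) {
  ids <- c("T1", "T2", "T3", "T4")
  stats::setNames(lapply(ids, synthesize_tone, fs = fs,
                         duration_s = duration_s), ids)
}
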