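#' Inter-trial phase coherence spectrogram
#'
#' Decomposes every trial with complex Gaussian-envelope wavelets
#' (by default 130 frequencies spanning 70-200 Hz with equal temporal
#' widths, i.e. a fixed wavelet duration across frequency), normalizes each
#' time-frequency coefficient to a unit vector, averages the unit vectors
#' across trials and takes the magnitude of the resultant. Values are in
#' `[0, 1]`: 0 = no phase-locking, 1 = perfect phase-locking across trials.
#' ITPC is by construction invariant to per-trial amplitude scaling.
#'
#' @param epochs An `epoched_recording`.
#' @param channel Channel label (default first channel).
#' @param tone Optional tone label to restrict trials.
#' @param freqs Analysis frequencies, Hz (default `seq(70, 200,
#'   length.out = 130)`).
#' @param width `"fixed"` (equal absolute temporal width across frequency,
#'   default) or `"cycles"` (constant-cycles Morlet).
#' @param sigma_t_s Wavelet temporal SD in seconds when `width = "fixed"`.
#' @param cycles Number of cycles when `width = "cycles"`.
#' @return An `itpc_spectrogram`: `values` (freq x time), `freqs_hz`,
#'   `times_ms`, `n_trials`.
#' @export
itpc <- function(epochs, channel = NULL, tone = NULL,
                 freqs = seq(70, 200, length.out = 130),
                 width = c("fixed", "cycles"),
                 sigma_t_s = 0.015, cycles = 7) {
  width <- match.arg(width)
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stop("analysis frequency at/above Nyquist")
  ch <- if (is.null(channel)) 1L
        else match(channel, epochs$channel_meta$label)
  keep <- if (is.null(tone)) rep(TRUE, dim(epochs$data)[1])
          else epochs$tone_id == tone
  if (sum(keep) < 2) stop("need at least 2 trials")
  M <- epochs$data[keep, ch, , drop = FALSE]
  dim(M) <- c(sum(keep), dim(epochs$data)[3])
  X <- t(M)                                        # samples x trials
  n <- nrow(X); n_tr <- ncol(X)
  Fx <- stats::mvfft(X)
  fbin <- (seq_len(n) - 1) / n * fs                # FFT bin frequencies
  vals <- matrix(0, length(freqs), n)
  eps <- .Machine$double.eps^0.5
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    st <- if (width == "fixed") sigma_t_s else cycles / (2 * pi * f)
    H <- exp(-2 * pi^2 * st^2 * (fbin - f)^2)      # one-sided (analytic)
    H[fbin > fs / 2] <- 0
    C <- stats::mvfft(Fx * H, inverse = TRUE) / n  # samples x trials, complex
    mag <- Mod(C)
    U <- C / mag
    U[mag < eps] <- 0                              # excluded, not NaN
    nvalid <- rowSums(mag >= eps)
    res <- Mod(rowSums(U))
    vals[i, ] <- ifelse(nvalid > 0, res / pmax(nvalid, 1), 0)
  }
  vals <- pmin(pmax(vals, 0), 1)     # guard rounding at the boundaries
  structure(list(values = vals, freqs_hz = freqs,
                 times_ms = epochs$t0_ms + 1000 * (seq_len(n) - 1) / fs,
                 n_trials = n_tr),
            class = "itpc_spectrogram")
}

#' @export
print.itpc_spectrogram <- function(x, ...) {
  cat(sprintf("<itpc_spectrogram: %d freqs (%.0f-%.0f Hz) x %d times, n=%d trials>\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_ms), x$n_trials))
  invisible(x)
}

#' ITPC sampled along the stimulus F0 trajectory
#'
#' Reads the spectrogram at the frequency bin nearest the stimulus F0 at
#' every time point, yielding the phase-locking strength along the pitch
#' contour. Contour frequencies outside the spectrogram grid are clamped to
#' the nearest edge with a warning.
#'
#' @param itpc_spec An `itpc_spectrogram`.
#' @param f0_hz Ground-truth F0 contour values.
#' @param f0_times_ms Times of the contour samples, ms re: stimulus onset.
#' @return data.frame with `time_ms`, `freq_hz` (grid frequency used) and
#'   `itpc`; one row per spectrogram time bin inside the contour span.
#' @export
itpc_at_f0 <- function(itpc_spec, f0_hz, f0_times_ms = NULL) {
  if (length(f0_hz) == 0) stop("empty F0 contour")
  if (is.null(f0_times_ms))
    f0_times_ms <- seq(0, max(itpc_spec$times_ms),
                       length.out = length(f0_hz))
  tsel <- itpc_spec$times_ms >= min(f0_times_ms) &
          itpc_spec$times_ms <= max(f0_times_ms)
  tt <- itpc_spec$times_ms[tsel]
  f_at_t <- stats::approx(f0_times_ms, f0_hz, xout = tt, rule = 2)$y
  rng <- range(itpc_spec$freqs_hz)
  if (any(f_at_t < rng[1] | f_at_t > rng[2])) {
    warning("F0 contour exits the frequency grid; clamped")
    f_at_t <- pmin(pmax(f_at_t, rng[1]), rng[2])
  }
  fi <- vapply(f_at_t, function(f) which.min(abs(itpc_spec$freqs_hz - f)),
               integer(1))
  data.frame(time_ms = tt, freq_hz = itpc_spec$freqs_hz[fi],
             itpc = itpc_spec$values[cbind(fi, which(tsel))])
}
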