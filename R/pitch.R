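#' Sliding-window autocorrelation pitch tracking
#'
#' Per window, computes the normalized autocorrelation over the lags that
#' correspond to the F0 search range; the F0 estimate is `fs / best_lag`
#' and the pitch strength is the maximum correlation coefficient (floored
#' at 0 for reporting). Windows whose strength falls below
#' `unvoiced_threshold` are flagged unvoiced and excluded from summaries.
#'
#' @param waveform Numeric vector (stimulus or averaged FFR).
#' @param fs Sampling rate, Hz.
#' @param window_ms Analysis window (default 40 ms; must hold >= 2 periods
#'   of the lowest search F0).
#' @param step_ms Hop between window starts (default 10 ms).
#' @param f0_range Search range in Hz (default 80-180).
#' @param unvoiced_threshold Strength below which a window is unvoiced
#'   (default 0.3).
#' @param interpolate If TRUE, parabolic interpolation around the best lag
#'   (never moves the estimate by more than one lag step). Off by default
#'   to keep estimates grid-exact.
#' @return A `pitch_track` data.frame: `time_ms` (window centre), `f0_hz`,
#'   `strength`, `voiced`; attributes store the parameters.
#' @export
track_pitch <- function(waveform, fs, window_ms = 40, step_ms = 10,
                        f0_range = c(80, 180), unvoiced_threshold = 0.3,
                        interpolate = FALSE) {
  n <- length(waveform)
  win <- round(window_ms / 1000 * fs)
  if (win > n) stop("window longer than waveform")
  step <- max(1L, round(step_ms / 1000 * fs))
  lag_min <- max(1L, floor(fs / f0_range[2]))
  lag_max <- ceiling(fs / f0_range[1])
  if (win < 2 * lag_max)
    stop("window must hold at least 2 periods of the lowest search F0")
  starts <- seq(1L, n - win + 1L, by = step)
  lags <- lag_min:lag_max
  res <- vapply(starts, function(s) {
    x <- waveform[s:(s + win - 1L)]
    r <- vapply(lags, function(l) {
      a <- x[1:(win - l)]; b <- x[(1 + l):win]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den == 0) 0 else sum(a * b) / den
    }, numeric(1))
    bi <- which.max(r)
    lag_best <- lags[bi]
    if (interpolate && bi > 1 && bi < length(lags)) {
      y1 <- r[bi - 1]; y2 <- r[bi]; y3 <- r[bi + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        delta <- 0.5 * (y1 - y3) / den
        lag_best <- lag_best + max(-1, min(1, delta))
      }
    }
    c(fs / lag_best, max(r[bi], 0))
  }, numeric(2))
  out <- data.frame(time_ms = 1000 * (starts - 1 + win / 2) / fs,
                    f0_hz = res[1, ], strength = res[2, ])
  out$voiced <- out$strength >= unvoiced_threshold
  attr(out, "params") <- list(window_ms = window_ms, step_ms = step_ms,
                              f0_range = f0_range,
                              unvoiced_threshold = unvoiced_threshold,
                              fs = fs)
  class(out) <- c("pitch_track", "data.frame")
  out
}

#' Correlation between two pitch tracks
#'
#' Pearson correlation of the F0 estimates over the windows voiced in both
#' tracks (used e.g. to compare hemispheres or recording levels).
#'
#' @param track_a,track_b `pitch_track`s on identical time grids.
#' @return Pearson r.
#' @export
track_correlation <- function(track_a, track_b) {
  if (nrow(track_a) != nrow(track_b) ||
      any(abs(track_a$time_ms - track_b$time_ms) > 1e-6))
    stop("tracks must share the same time grid")
  v <- track_a$voiced & track_b$voiced
  if (sum(v) < 3) stop("fewer than 3 shared voiced windows")
  a <- track_a$f0_hz[v]; b <- track_b$f0_hz[v]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance track; correlation undefined")
  stats::cor(a, b)
}

#' Pitch track of a tone stimulus
#'
#' Convenience wrapper running [track_pitch()] on a `tone_stimulus` or
#' `ffr_waveform` (first/selected channel).
#'
#' @param x A `tone_stimulus` or `ffr_waveform`.
#' @param channel Channel label for `ffr_waveform` input.
#' @param ... Passed to [track_pitch()].
#' @return A `pitch_track`.
#' @export
pitch_track_of <- function(x, channel = NULL, ...) {
  if (inherits(x, "tone_stimulus"))
    track_pitch(x$waveform, x$fs, ...)
  else if (inherits(x, "ffr_waveform"))
    track_pitch(ffr_channel(x, channel), x$fs, ...)
  else stop("unsupported input")
}
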