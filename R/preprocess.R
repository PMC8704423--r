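#' Remove power-line interference by sinusoidal regression
#'
#' Fits least-squares sine and cosine regressors at the line frequency and
#' its harmonics to every trial/channel and subtracts the fit. Non-line
#' content is untouched (the regressors are narrowband and orthogonal to
#' broadband signal in expectation).
#'
#' @param epochs An `epoched_recording`.
#' @param line_freq_hz Line fundamental (default 60 Hz).
#' @param n_harmonics Number of harmonics (including the fundamental) to
#'   regress out. Harmonics at or above Nyquist are skipped with a warning.
#' @return The cleaned `epoched_recording`.
#' @export
remove_line_noise <- function(epochs, line_freq_hz = 60, n_harmonics = 3) {
  fs <- epochs$fs
  if (line_freq_hz >= fs / 2) stop("line_freq_hz must be below Nyquist")
  n <- dim(epochs$data)[3]
  t <- (seq_len(n) - 1) / fs
  freqs <- line_freq_hz * seq_len(n_harmonics)
  bad <- freqs >= fs / 2
  if (any(bad)) {
    warning("skipping line harmonics at/above Nyquist: ",
            paste(freqs[bad], collapse = ", "), " Hz")
    freqs <- freqs[!bad]
  }
  if (length(freqs) == 0) return(epochs)
  X <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))))
  XtXi <- solve(crossprod(X))
  d <- dim(epochs$data)
  # samples x (trials*channels) matrix view for one shot regression
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  M <- M - X %*% (XtXi %*% crossprod(X, M))
  epochs$data <- aperm(array(M, dim = c(n, d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Zero-phase Butterworth filtering of epochs
#'
#' Third-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the group delay is ~0 and peak latencies are
#' preserved.
#'
#' @param epochs An `epoched_recording`.
#' @param band `c(low, high)` in Hz; use `NA` for one side to get a pure
#'   high- or low-pass.
#' @param order Filter order (default 3).
#' @return Filtered `epoched_recording`.
#' @export
filter_epochs <- function(epochs, band, order = 3) {
  fs <- epochs$fs
  lo <- band[1]; hi <- band[2]
  if (!is.na(lo) && !is.na(hi) && lo >= hi)
    stop("band edges inverted: ", lo, " >= ", hi)
  nyq <- fs / 2
  bf <- if (is.na(lo)) signal::butter(order, hi / nyq, "low")
        else if (is.na(hi) || hi >= nyq)
          signal::butter(order, lo / nyq, "high")
        else signal::butter(order, c(lo, hi) / nyq, "pass")
  d <- dim(epochs$data)
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  for (j in seq_len(ncol(M)))
    M[, j] <- signal::filtfilt(bf, M[, j])
  epochs$data <- aperm(array(M, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Drops every trial whose peak absolute amplitude over the analyzed
#' channels exceeds the threshold (evaluated per raw epoch, before any
#' averaging).
#'
#' @param epochs An `epoched_recording`.
#' @param threshold_uv Rejection threshold in uV (e.g. 75 for human sEEG,
#'   35 for human scalp EEG, 250 for animal recordings).
#' @param channels Optional channel labels to restrict the scan.
#' @return List with `epochs` (retained trials), `n_rejected`, `per_tone`
#'   (named rejection counts) and `kept` (logical index over input trials).
#' @export
reject_artifacts <- function(epochs, threshold_uv, channels = NULL) {
  stopifnot(threshold_uv > 0)
  sel <- if (is.null(channels)) seq_len(dim(epochs$data)[2])
         else which(epochs$channel_meta$label %in% channels)
  peak <- apply(abs(epochs$data[, sel, , drop = FALSE]), 1, max)
  kept <- peak <= threshold_uv
  if (!any(kept))
    stop("all trials rejected at threshold ", threshold_uv, " uV")
  per_tone <- tapply(!kept, epochs$tone_id, sum)
  out <- epochs
  out$data <- epochs$data[kept, , , drop = FALSE]
  out$polarity <- epochs$polarity[kept]
  out$tone_id <- epochs$tone_id[kept]
  list(epochs = out, n_rejected = sum(!kept),
       per_tone = per_tone, kept = kept)
}

#' Polarity-balanced FFR averaging
#'
#' For each tone, averages the condensation-trial mean and the
#' rarefaction-trial mean with equal weight (regardless of trial counts),
#' so any component that flips sign with stimulus polarity — stimulus
#' artifact, cochlear-microphonic-like contamination — cancels.
#'
#' @param epochs An `epoched_recording`.
#' @return Named list (by tone) of `ffr_waveform` objects, each holding a
#'   channels x samples matrix of the averaged FFR.
#' @export
average_polarities <- function(epochs) {
  tones <- unique(epochs$tone_id)
  out <- list()
  for (tn in tones) {
    idx <- epochs$tone_id == tn
    pol <- epochs$polarity[idx]
    dat <- epochs$data[idx, , , drop = FALSE]
    pols <- unique(pol)
    if (length(pols) < 2) {
      warning("tone ", tn, ": only one polarity present; plain mean used")
      avg <- apply(dat, c(2, 3), mean)
    } else {
      m1 <- apply(dat[pol == pols[1], , , drop = FALSE], c(2, 3), mean)
      m2 <- apply(dat[pol == pols[2], , , drop = FALSE], c(2, 3), mean)
      avg <- (m1 + m2) / 2
    }
    out[[tn]] <- ffr_waveform(avg, fs = epochs$fs, t0_ms = epochs$t0_ms,
                              tone_id = tn,
                              channels = epochs$channel_meta$label,
                              n_trials = sum(idx))
  }
  out
}

#' Averaged FFR waveform container
#'
#' @param samples channels x samples numeric matrix (uV); a plain vector is
#'   treated as a single channel.
#' @param fs,t0_ms Sampling rate and epoch start (ms, <= 0).
#' @param tone_id Tone label.
#' @param channels Channel labels.
#' @param n_trials Number of trials averaged.
#' @return `ffr_waveform` object.
#' @export
ffr_waveform <- function(samples, fs, t0_ms, tone_id = NA_character_,
                         channels = NULL, n_trials = NA_integer_) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  stopifnot(all(is.finite(samples)), t0_ms <= 0)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(samples)))
  structure(list(samples = samples, fs = fs, t0_ms = t0_ms,
                 tone_id = tone_id, channels = channels,
                 n_trials = n_trials), class = "ffr_waveform")
}

#' @export
print.ffr_waveform <- function(x, ...) {
  cat(sprintf("<ffr_waveform %s: %d channel(s) x %d samples @ %g Hz (n=%s trials)>\n",
              x$tone_id, nrow(x$samples), ncol(x$samples), x$fs, x$n_trials))
  invisible(x)
}

#' Extract one channel of an averaged FFR as a vector
#' @param ffr An `ffr_waveform`.
#' @param channel Channel label (default: first channel).
#' @return Numeric vector.
#' @export
ffr_channel <- function(ffr, channel = NULL) {
  i <- if (is.null(channel)) 1L else match(channel, ffr$channels)
  if (is.na(i)) stop("unknown channel: ", channel)
  ffr$samples[i, ]
}

#' FFR signal-to-noise ratio and bootstrap significance
#'
#' SNR is the RMS of the averaged (polarity-balanced) FFR inside the
#' response window divided by the RMS inside the prestimulus baseline
#' window. Significance comes from a trial bootstrap of the paired t
#' statistic between the per-trial response-window and baseline-window RMS
#' values: trials are resampled with replacement, the studentized paired
#' difference recomputed, and the p-value is the fraction of resamples
#' whose t statistic is at or beyond the null (<= 0). The studentized
#' statistic is approximately pivotal, so the p-value is close to uniform
#' under a pure-noise null.
#'
#' @param epochs An `epoched_recording` (one tone, or pooled).
#' @param channel Channel label to analyze (default first channel).
#' @param response_window_ms,baseline_window_ms Disjoint windows, ms; the
#'   baseline must end at or before 0 ms.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return List (`snr_report`): `snr`, `p_value`, `n_boot`, window RMS
#'   values.
#' @export
ffr_snr_and_significance <- function(epochs, channel = NULL,
                                     response_window_ms = c(0, 250),
                                     baseline_window_ms = c(-25, 0),
                                     n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100 for a stable p-value")
  if (baseline_window_ms[2] > 0) stop("baseline window must end at <= 0 ms")
  if (!(response_window_ms[1] >= baseline_window_ms[2] ||
        baseline_window_ms[1] >= response_window_ms[2]))
    stop("response and baseline windows must be disjoint")
  ch <- if (is.null(channel)) 1L
        else match(channel, epochs$channel_meta$label)
  t_ms <- epoch_times_ms(epochs)
  ir <- t_ms >= response_window_ms[1] & t_ms < response_window_ms[2]
  ib <- t_ms >= baseline_window_ms[1] & t_ms < baseline_window_ms[2]
  if (!any(ir) || !any(ib)) stop("empty analysis window")
  x <- epochs$data[, ch, ]                      # trials x samples
  avg <- polarity_balanced_mean(x, epochs$polarity)
  snr <- rms(avg[ir]) / rms(avg[ib])
  # per-trial paired window-RMS differences, then a t-statistic bootstrap
  d <- apply(x[, ir, drop = FALSE], 1, rms) -
       apply(x[, ib, drop = FALSE], 1, rms)
  n_tr <- length(d)
  tstat <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(0)
    mean(v) / (s / sqrt(length(v)))
  }
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(b)
    tstat(d[sample.int(n_tr, n_tr, replace = TRUE)]), numeric(1))
  p <- (1 + sum(stat <= 0)) / (n_boot + 1)
  structure(list(snr = snr, p_value = p, n_boot = n_boot,
                 rms_response = rms(avg[ir]), rms_baseline = rms(avg[ib])),
            class = "snr_report")
}

# equal-weight mean of the per-polarity means (falls back to plain mean
# when only one polarity is present in the resample)
polarity_balanced_mean <- function(x, polarity) {
  pols <- unique(polarity)
  if (length(pols) < 2) return(colMeans(x))
  (colMeans(x[polarity == pols[1], , drop = FALSE]) +
   colMeans(x[polarity == pols[2], , drop = FALSE])) / 2
}

#' Paired comparison by sign-flip permutation
#'
#' Tests the null of no paired difference with a sign-flip permutation of
#' the Wilcoxon signed-rank statistic (default) or the paired t statistic.
#' Enumerates all 2^n sign patterns when n <= 12, otherwise samples.
#'
#' @param metric_a,metric_b Equal-length paired samples (n >= 5).
#' @param n_perm Number of random sign flips when not exhaustive.
#' @param seed Integer seed.
#' @param statistic `"signed_rank"` or `"t"`.
#' @return List: two-sided `p_value`, observed `statistic`, `exhaustive`.
#' @export
compare_paired <- function(metric_a, metric_b, n_perm = 10000, seed = 1,
                           statistic = c("signed_rank", "t")) {
  statistic <- match.arg(statistic)
  stopifnot(length(metric_a) == length(metric_b))
  n <- length(metric_a)
  if (n < 5) stop("need at least 5 pairs")
  d <- metric_a - metric_b
  stat_fun <- if (statistic == "signed_rank") {
    function(d) {
      nz <- d != 0
      if (!any(nz)) return(0)
      sum(sign(d[nz]) * rank(abs(d[nz])))
    }
  } else {
    function(d) if (stats::sd(d) == 0) 0 else
      mean(d) / (stats::sd(d) / sqrt(length(d)))
  }
  obs <- stat_fun(d)
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- apply(signs, 1, function(s) stat_fun(d * s))
    p <- mean(abs(null) >= abs(obs) - 1e-12)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i)
      stat_fun(d * sample(c(-1, 1), n, replace = TRUE)), numeric(1))
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
    exhaustive <- FALSE
  }
  list(p_value = p, statistic = obs, exhaustive = exhaustive)
}
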