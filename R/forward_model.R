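#' Frequency-dependent phase-locking gain of a generator
#'
#' Models the decline of phase-locking with stimulus frequency for the two
#' FFR generators. Gain is 1 up to the source's knee frequency and rolls off
#' log-linearly (fixed dB/octave) above it; the cortical source rolls off
#' faster than the subcortical source, so at matched frequency above both
#' knees the cortical gain is always lower.
#'
#' @param freq_hz Frequency (vectorized), Hz; must be > 0.
#' @param source `"subcortical"` or `"cortical"`.
#' @param knee_hz Knee frequency; defaults 150 Hz (subcortical) / 90 Hz
#'   (cortical).
#' @param slope_db_oct Roll-off slope above the knee in dB/octave; defaults
#'   6 (subcortical) / 18 (cortical).
#' @return Gain in `[0, 1]`, same length as `freq_hz`.
#' @export
phase_locking_gain <- function(freq_hz,
                               source = c("subcortical", "cortical"),
                               knee_hz = NULL, slope_db_oct = NULL) {
  source <- match.arg(source)
  if (any(freq_hz <= 0)) stop("freq_hz must be > 0")
  if (is.null(knee_hz))
    knee_hz <- if (source == "subcortical") 150 else 90
  if (is.null(slope_db_oct))
    slope_db_oct <- if (source == "subcortical") 6 else 18
  g <- rep(1, length(freq_hz))
  hi <- freq_hz > knee_hz
  g[hi] <- 10^(-slope_db_oct * log2(freq_hz[hi] / knee_hz) / 20)
  g
}

#' Default recording montage
#'
#' Two scalp channels, one cortical-surface channel and a laminar probe with
#' `n_laminar` contacts at uniform `spacing_um` starting at `depth0_um`.
#'
#' @param n_laminar Number of laminar contacts (default 16).
#' @param spacing_um Contact spacing in micrometres (default 100).
#' @param depth0_um Depth of the most superficial contact (default 100).
#' @return data.frame with columns `label`, `kind` (one of `"scalp"`,
#'   `"cortical_surface"`, `"laminar"`) and `depth_um` (NA off the probe).
#' @export
default_montage <- function(n_laminar = 16, spacing_um = 100,
                            depth0_um = 100) {
  depths <- depth0_um + spacing_um * (seq_len(n_laminar) - 1)
  data.frame(
    label = c("Cz", "T4", "Surf1", sprintf("L%02d", seq_len(n_laminar))),
    kind = c("scalp", "scalp", "cortical_surface", rep("laminar", n_laminar)),
    depth_um = c(NA, NA, NA, depths),
    stringsAsFactors = FALSE)
}

#' Two-source forward model configuration
#'
#' Parameterizes the generative model behind [simulate_ffr_dataset()]: a
#' subcortical generator (short latency, shallow phase-locking roll-off,
#' spatially flat volume conduction) and a cortical generator (longer
#' latency, steep roll-off, laminar depth profile with a current sink around
#' the granular/thalamorecipient depth), mixed into the montage, plus 1/f
#' noise, power-line harmonics and a polarity-flipping stimulus-artifact
#' term (a cochlear-microphonic-like contaminant that polarity averaging
#' must cancel).
#'
#' @param fs Recording sampling rate, Hz.
#' @param epoch_ms Epoch window relative to stimulus onset, ms
#'   (`epoch_ms[1]` must be <= 0 so a prestimulus baseline exists).
#' @param subcortical_latency_ms,cortical_latency_ms Generator latencies.
#' @param knee_hz Named vector: phase-locking knee per source.
#' @param rolloff_slope_db_oct Named vector: roll-off slope per source.
#' @param granular_depth_um Depth of the laminar sink (thalamorecipient
#'   layer analogue).
#' @param laminar_sd_um Spatial SD of the laminar sink profile.
#' @param montage Channel metadata, see [default_montage()].
#' @param mixing Optional channels x 2 matrix of source->channel weights
#'   (columns `subcortical`, `cortical`); built from the montage by default.
#' @param signal_rms_uv Per-source response RMS at unit mixing weight, uV.
#' @param onset_amp Amplitude of the onset transient relative to the
#'   sustained response RMS, per source.
#' @param cortical_env_amp Amplitude of the cortical envelope-following
#'   (sustained) component relative to its phase-locked response RMS; the
#'   subcortical generator has none.
#' @param artifact_rms_uv RMS of the polarity-flipping stimulus artifact at
#'   unit artifact weight (applied to scalp channels).
#' @param noise_rms_uv RMS of the additive 1/f noise per channel/trial.
#' @param noise_exponent Spectral exponent of the 1/f noise.
#' @param line_freq_hz Power-line fundamental, Hz.
#' @param line_amp_uv Amplitudes (uV) of line fundamental and harmonics.
#' @param n_trials Trials per polarity per tone.
#' @param seed Integer seed; identical seed implies identical dataset.
#' @return A `ffr_forward_config` list.
#' @export
forward_model_config <- function(fs = 8000,
                                 epoch_ms = c(-50, 300),
                                 subcortical_latency_ms = 3,
                                 cortical_latency_ms = 15,
                                 knee_hz = c(subcortical = 150, cortical = 90),
                                 rolloff_slope_db_oct = c(subcortical = 6,
                                                          cortical = 18),
                                 granular_depth_um = 900,
                                 laminar_sd_um = 200,
                                 montage = default_montage(),
                                 mixing = NULL,
                                 signal_rms_uv = 1,
                                 onset_amp = c(subcortical = 1, cortical = 3),
                                 cortical_env_amp = 1.5,
                                 artifact_rms_uv = 0.2,
                                 noise_rms_uv = 2,
                                 noise_exponent = 1,
                                 line_freq_hz = 60,
                                 line_amp_uv = c(0.5, 0.25, 0.125),
                                 n_trials = 20,
                                 seed = 1) {
  stopifnot(cortical_latency_ms > subcortical_latency_ms,
            epoch_ms[1] <= 0, epoch_ms[2] > epoch_ms[1], n_trials >= 1)
  if (nrow(montage) < 1) stop("montage must contain at least one channel")
  if (is.null(mixing)) mixing <- default_mixing(montage, granular_depth_um,
                                                laminar_sd_um)
  stopifnot(nrow(mixing) == nrow(montage), all(is.finite(mixing)))
  structure(list(
    fs = fs, epoch_ms = epoch_ms,
    subcortical_latency_ms = subcortical_latency_ms,
    cortical_latency_ms = cortical_latency_ms,
    knee_hz = knee_hz, rolloff_slope_db_oct = rolloff_slope_db_oct,
    granular_depth_um = granular_depth_um, laminar_sd_um = laminar_sd_um,
    montage = montage, mixing = mixing,
    signal_rms_uv = signal_rms_uv, onset_amp = onset_amp,
    cortical_env_amp = cortical_env_amp,
    artifact_rms_uv = artifact_rms_uv,
    noise_rms_uv = noise_rms_uv, noise_exponent = noise_exponent,
    line_freq_hz = line_freq_hz, line_amp_uv = line_amp_uv,
    n_trials = n_trials, seed = seed), class = "ffr_forward_config")
}

# default source->channel mixing: scalp dominated by the volume-conducted
# subcortical source; cortical surface by the cortical source; laminar
# contacts carry a flat subcortical term plus a negative-Gaussian cortical
# depth profile (LFP trough at the granular depth => CSD sink there).
default_mixing <- function(montage, granular_depth_um, laminar_sd_um = 200) {
  n <- nrow(montage)
  mix <- matrix(0, n, 2, dimnames = list(montage$label,
                                         c("subcortical", "cortical")))
  for (i in seq_len(n)) {
    mix[i, ] <- switch(montage$kind[i],
      scalp = c(1.0, 0.35),
      cortical_surface = c(0.2, 1.0),
      laminar = {
        d <- montage$depth_um[i]
        prof <- -1.5 * exp(-(d - granular_depth_um)^2 / (2 * laminar_sd_um^2))
        c(0.3, prof)
      },
      stop("unknown channel kind: ", montage$kind[i]))
  }
  mix
}

# deterministic per-source response to one stimulus at the recording rate:
# harmonic stack following the F0 contour with frequency-dependent
# phase-locking gain, gated, RMS-normalized, plus a Gaussian onset transient.
# Returns a full-epoch vector (latency applied).
source_epoch_response <- function(stim, config, source) {
  fs <- config$fs
  n_epoch <- round(diff(config$epoch_ms) / 1000 * fs)
  t_ms <- config$epoch_ms[1] + 1000 * (seq_len(n_epoch) - 1) / fs
  n_resp <- round(stim$duration_s * fs)
  f0 <- stats::approx(seq_along(stim$f0_contour) / stim$fs,
                      stim$f0_contour,
                      xout = (seq_len(n_resp) - 1) / fs, rule = 2)$y
  knee <- config$knee_hz[[source]]
  slope <- config$rolloff_slope_db_oct[[source]]
  phase <- 2 * pi * cumsum(f0) / fs
  x <- numeric(n_resp)
  k_max <- max(1, floor((fs / 2 - 1) / max(f0)))
  for (k in seq_len(k_max)) {
    g <- phase_locking_gain(k * f0, source, knee_hz = knee,
                            slope_db_oct = slope)
    x <- x + (1 / k) * g * sin(k * phase)
  }
  x <- x * cos_gate(n_resp, fs, 0.005)
  x <- x / stats::sd(x)
  if (source == "cortical" && config$cortical_env_amp > 0) {
    # sustained envelope-following component: cortex tracks the stimulus
    # envelope (sustained potential) on top of its phase-locked response
    env <- cos_gate(n_resp, fs, 0.03)
    x <- x + config$cortical_env_amp * env / stats::sd(env)
    x <- x / stats::sd(x)
  }
  latency_ms <- if (source == "subcortical") config$subcortical_latency_ms
                else config$cortical_latency_ms
  # onset transient: Gaussian bump (SD 2 ms) peaking 4 ms after response onset
  trans <- config$onset_amp[[source]] *
    exp(-(t_ms - latency_ms - 4)^2 / (2 * 2^2))
  out <- numeric(n_epoch)
  i0 <- which.min(abs(t_ms - latency_ms))
  idx <- i0:min(n_epoch, i0 + n_resp - 1)
  out[idx] <- x[seq_along(idx)]
  (out + trans) * config$signal_rms_uv
}

# 1/f^a noise with unit RMS via spectral shaping of white Gaussian noise
one_over_f_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # two-sided frequency index
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a multi-level epoched FFR dataset
#'
#' Draws trial-level responses to each stimulus from the two-source forward
#' model: per trial, the latency-shifted, roll-off-filtered harmonic
#' responses of the subcortical and cortical generators are mixed into every
#' channel through the configured weights; scalp channels additionally carry
#' a stimulus artifact whose sign follows stimulus polarity; 1/f noise and
#' power-line harmonics are added. The neural response itself is
#' polarity-invariant (it follows the F0 periodicity, not the signed
#' waveform).
#'
#' @param config A [forward_model_config()].
#' @param stimuli List of [synthesize_tone()] objects (typically
#'   [synthesize_tone_set()]).
#' @return An `epoched_recording`: list with `data` (trials x channels x
#'   samples array, uV), `fs`, `t0_ms`, `channel_meta`, `polarity`
#'   (`"condensation"`/`"rarefaction"` per trial) and `tone_id` per trial.
#' @export
simulate_ffr_dataset <- function(config, stimuli) {
  stopifnot(inherits(config, "ffr_forward_config"), length(stimuli) >= 1)
  set.seed(config$seed)
  fs <- config$fs
  n_epoch <- round(diff(config$epoch_ms) / 1000 * fs)
  t_s <- (seq_len(n_epoch) - 1) / fs
  n_ch <- nrow(config$montage)
  tones <- names(stimuli)
  if (is.null(tones)) tones <- vapply(stimuli, `[[`, "", "tone_id")

  # per tone: n_ch x n_samples clean response, and resampled artifact
  clean <- list(); artifact <- list()
  onset_i <- which.min(abs(config$epoch_ms[1] + 1000 * t_s))
  for (tn in tones) {
    st <- stimuli[[tn]]
    sub <- source_epoch_response(st, config, "subcortical")
    ctx <- source_epoch_response(st, config, "cortical")
    clean[[tn]] <- config$mixing[, "subcortical"] %o% sub +
                   config$mixing[, "cortical"] %o% ctx
    wav <- stats::approx(seq_along(st$waveform) / st$fs, st$waveform,
                         xout = (seq_len(n_epoch) - onset_i) / fs,
                         rule = 2, yleft = 0, yright = 0)$y
    artifact[[tn]] <- config$artifact_rms_uv * wav / max(stats::sd(wav), 1e-12)
  }
  art_w <- ifelse(config$montage$kind == "scalp", 1, 0)

  pol_levels <- c("condensation", "rarefaction")
  n_trials_tot <- length(tones) * 2L * config$n_trials
  data <- array(0, dim = c(n_trials_tot, n_ch, n_epoch))
  tone_id <- character(n_trials_tot)
  polarity <- character(n_trials_tot)
  i <- 0L
  for (tn in tones) for (pol in pol_levels) for (r in seq_len(config$n_trials)) {
    i <- i + 1L
    sgn <- if (pol == "condensation") 1 else -1
    tr <- clean[[tn]]
    tr <- tr + (art_w * sgn) %o% artifact[[tn]]
    if (config$noise_rms_uv > 0) {
      noise <- vapply(seq_len(n_ch), function(ch)
        config$noise_rms_uv * one_over_f_noise(n_epoch, config$noise_exponent),
        numeric(n_epoch))
      tr <- tr + t(noise)
    }
    if (length(config$line_amp_uv) > 0 && any(config$line_amp_uv > 0)) {
      for (h in seq_along(config$line_amp_uv)) {
        fh <- h * config$line_freq_hz
        if (fh >= fs / 2) next
        ph <- stats::runif(n_ch, 0, 2 * pi)
        tr <- tr + config$line_amp_uv[h] *
          sin(outer(ph, 2 * pi * fh * t_s, `+`))
      }
    }
    data[i, , ] <- tr
    tone_id[i] <- tn
    polarity[i] <- pol
  }
  epoched_recording(data, fs = fs, t0_ms = config$epoch_ms[1],
                    channel_meta = config$montage,
                    polarity = polarity, tone_id = tone_id)
}

#' Construct an epoched multichannel recording
#'
#' @param data trials x channels x samples array (uV).
#' @param fs Sampling rate, Hz.
#' @param t0_ms Epoch start relative to stimulus onset (must be <= 0).
#' @param channel_meta data.frame with `label`, `kind`, `depth_um`.
#' @param polarity Character per trial.
#' @param tone_id Character per trial.
#' @return An `epoched_recording` object.
#' @export
epoched_recording <- function(data, fs, t0_ms, channel_meta,
                              polarity, tone_id) {
  stopifnot(length(dim(data)) == 3, t0_ms <= 0,
            dim(data)[1] == length(polarity),
            dim(data)[1] == length(tone_id),
            dim(data)[2] == nrow(channel_meta))
  for (tn in unique(tone_id)) {
    cnt <- table(factor(polarity[tone_id == tn],
                        levels = unique(polarity)))
    if (length(cnt) == 2 && abs(cnt[1] - cnt[2]) > 1)
      warning("unbalanced polarity counts for ", tn, ": ",
              paste(cnt, collapse = "/"))
  }
  lam <- channel_meta$depth_um[channel_meta$kind == "laminar"]
  if (length(lam) > 1 && any(diff(lam) <= 0))
    stop("laminar channel depths must be strictly increasing")
  structure(list(data = data, fs = fs, t0_ms = t0_ms,
                 channel_meta = channel_meta,
                 polarity = polarity, tone_id = tone_id),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording: %d trials x %d channels x %d samples @ %g Hz, t0 %g ms>\n",
    d[1], d[2], d[3], x$fs, x$t0_ms))
  cat("  tones:", paste(unique(x$tone_id), collapse = " "),
      "| kinds:", paste(unique(x$channel_meta$kind), collapse = " "), "\n")
  invisible(x)
}

#' Epoch time axis in milliseconds
#' @param epochs An `epoched_recording` (or any object with `fs`, `t0_ms`
#'   and a sample count in its third data dimension).
#' @return Numeric vector of per-sample times, ms relative to stimulus onset.
#' @export
epoch_times_ms <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$t0_ms + 1000 * (seq_len(n) - 1) / epochs$fs
}

#' Select channels by label or kind
#' @param epochs An `epoched_recording`.
#' @param label,kind Select by exact label(s) or by channel kind.
#' @return An `epoched_recording` restricted to the matching channels.
#' @export
select_channels <- function(epochs, label = NULL, kind = NULL) {
  keep <- rep(TRUE, nrow(epochs$channel_meta))
  if (!is.null(label)) keep <- keep & epochs$channel_meta$label %in% label
  if (!is.null(kind)) keep <- keep & epochs$channel_meta$kind %in% kind
  if (!any(keep)) stop("no channels match the selection")
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$channel_meta <- epochs$channel_meta[keep, , drop = FALSE]
  epochs
}

# stimulus feature at the recording rate for cross-correlation analyses
#' Stimulus feature resampled to a recording rate
#'
#' @param stim A `tone_stimulus`.
#' @param fs_out Target sampling rate.
#' @param type `"envelope"` (rectified + 50 Hz low-pass, default) or
#'   `"waveform"`.
#' @return Numeric vector at `fs_out`.
#' @export
stimulus_feature <- function(stim, fs_out, type = c("envelope", "waveform")) {
  type <- match.arg(type)
  x <- stats::approx(seq_along(stim$waveform) / stim$fs, stim$waveform,
                     xout = seq(1 / fs_out, stim$duration_s, by = 1 / fs_out),
                     rule = 2)$y
  if (type == "waveform") return(x)
  bf <- signal::butter(4, min(50 / (fs_out / 2), 0.99), "low")
  as.numeric(signal::filtfilt(bf, abs(x)))
}
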