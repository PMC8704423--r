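# shared fixtures, built once per test run and cached

.fix <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fix)) assign(key, builder(), envir = .fix)
  get(key, envir = .fix)
}

tone_set <- function() cached("tones", synthesize_tone_set)

# near-noiseless simulation: clean averaged FFRs for ICA/CSD/spectral tests
clean_sim <- function() cached("clean_sim", function() {
  cfg <- forward_model_config(n_trials = 1, noise_rms_uv = 0.1, seed = 5)
  rec <- remove_line_noise(simulate_ffr_dataset(cfg, tone_set()))
  list(config = cfg, rec = rec, ffrs = average_polarities(rec))
})

# ground-truth source waveforms concatenated over the four tones
source_truth <- function(cfg) {
  list(sub = unlist(lapply(tone_set(), function(s)
         ffrtools:::source_epoch_response(s, cfg, "subcortical"))),
       ctx = unlist(lapply(tone_set(), function(s)
         ffrtools:::source_epoch_response(s, cfg, "cortical"))))
}

# single-channel pure-noise epochs (null data for significance tests)
noise_epochs <- function(n_trials = 24, fs = 2000, t0_ms = -25,
                         dur_ms = 125) {
  n <- round(dur_ms / 1000 * fs)
  dat <- array(stats::rnorm(n_trials * n), dim = c(n_trials, 1, n))
  epoched_recording(dat, fs, t0_ms,
                    data.frame(label = "Cz", kind = "scalp",
                               depth_um = NA),
                    polarity = rep(c("condensation", "rarefaction"),
                                   length.out = n_trials),
                    tone_id = rep("T1", n_trials))
}

# two independent non-Gaussian sources mixed into n_ch channels
two_source_mixture <- function(seed, n = 4000, n_ch = 6, noise = 0.01) {
  set.seed(seed)
  s1 <- sign(stats::rnorm(n)) * stats::rexp(n)
  s2 <- as.numeric(signal::filtfilt(signal::butter(2, 0.15),
                                    sign(stats::rnorm(n)) * stats::rexp(n)))
  S <- rbind(s1 / stats::sd(s1), s2 / stats::sd(s2))
  A <- matrix(stats::rnorm(2 * n_ch), n_ch, 2)
  list(X = A %*% S + noise * matrix(stats::rnorm(n_ch * n), n_ch),
       S = S, A = A)
}

# noiseless pitch tracks of the four stimuli, one per tone, replicated
noiseless_tracks <- function(n_per_tone = 3) {
  tones <- tone_set()
  tracks <- list(); labs <- character(0)
  for (tn in names(tones)) {
    tr <- track_pitch(tones[[tn]]$waveform, tones[[tn]]$fs)
    for (i in seq_len(n_per_tone)) {
      tracks[[length(tracks) + 1L]] <- tr
      labs <- c(labs, tn)
    }
  }
  list(tracks = tracks, labels = labs)
}
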