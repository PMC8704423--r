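test_that("pseudo-trial construction honors k at both extremes", {
  cfg <- forward_model_config(n_trials = 6, seed = 13,
                              montage = default_montage(0)[1, , drop = FALSE])
  rec <- simulate_ffr_dataset(cfg, tone_set()["T1"])
  p1 <- make_averaged_trials(rec, 1, seed = 1)
  expect_equal(nrow(p1$x), 12)
  expect_true(all(apply(p1$x, 1, function(r)
    any(apply(rec$data[, 1, ], 1, function(tr) isTRUE(all.equal(tr, r)))))))
  pall <- make_averaged_trials(rec, 12, seed = 1)
  expect_equal(nrow(pall$x), 1)
  expect_equal(pall$x[1, ], colMeans(rec$data[, 1, ]))
  expect_error(make_averaged_trials(rec, 13, seed = 1,
                                    min_pseudo_trials = 1), "pseudo-trials")
})

test_that("pseudo-trial SNR grows like sqrt(k)", {
  cfg <- forward_model_config(n_trials = 32, seed = 17,
                              montage = default_montage(0)[1, , drop = FALSE])
  rec <- simulate_ffr_dataset(cfg, tone_set()["T1"])
  clean_cfg <- forward_model_config(n_trials = 1, noise_rms_uv = 0,
                                    line_amp_uv = 0, artifact_rms_uv = 0,
                                    seed = 17,
                                    montage = default_montage(0)[1, , drop = FALSE])
  truth <- average_polarities(
    simulate_ffr_dataset(clean_cfg, tone_set()["T1"]))$T1
  tv <- ffr_channel(truth)
  noise_rms_at_k <- function(k) {
    p <- make_averaged_trials(rec, k, seed = 3)
    mean(apply(p$x, 1, function(r) sqrt(mean((r - tv)^2))))
  }
  ks <- c(1, 4, 16)
  nr <- vapply(ks, noise_rms_at_k, numeric(1))
  # residual noise should shrink ~ 1/sqrt(k): fit log-log slope ~ -0.5
  slope <- stats::coef(stats::lm(log(nr) ~ log(ks)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("HMM training log-likelihood is nondecreasing", {
  nt <- noiseless_tracks(4)
  set.seed(8)
  feats <- lapply(nt$tracks[nt$labels == "T2"], function(tr) {
    f <- ffrtools:::track_features(tr)
    f + matrix(rnorm(length(f), sd = 2), nrow(f))
  })
  m <- fit_lr_hmm(feats, n_states = 4, n_iter = 15)
  expect_true(all(diff(m$loglik_trace) > -1e-6))
})

test_that("noiseless tracks decode perfectly; shuffled labels fall to chance", {
  nt <- noiseless_tracks(3)
  cm <- decode_confusion(nt$tracks, nt$labels)
  expect_equal(unname(diag(as.matrix(cm))), rep(1, 4))
  expect_equal(unname(rowSums(as.matrix(cm))), rep(1, 4))
  # label permutation: accuracy compatible with 4-class chance
  cfg <- forward_model_config(n_trials = 16, seed = 23,
                              montage = default_montage(0)[1, , drop = FALSE])
  rec <- simulate_ffr_dataset(cfg, tone_set())
  pseudo <- make_averaged_trials(rec, 4, seed = 23)
  tracks <- pseudo_trial_tracks(pseudo)
  set.seed(99)
  shuffled <- sample(attr(tracks, "tone_id"))
  cm_sh <- decode_confusion(tracks, shuffled, cv = "kfold", fold_seed = 2)
  acc <- decoding_accuracy(cm_sh)
  n_tracks <- length(tracks)
  ci <- stats::binom.test(round(acc * n_tracks), n_tracks,
                          0.25)$conf.int
  expect_true(acc >= 0 && acc <= 1)
  expect_lt(acc, 0.55)          # far from genuine decoding performance
  expect_gte(0.25, ci[1] - 0.25)  # chance inside/near the binomial CI
})

test_that("row normalization and tie handling hold for any input", {
  nt <- noiseless_tracks(3)
  cm <- decode_confusion(nt$tracks, nt$labels, cv = "none")
  expect_true(all(abs(rowSums(as.matrix(cm)) - 1) < 1e-9))
  expect_true(all(as.matrix(cm) >= 0 & as.matrix(cm) <= 1))
})

test_that("a degraded tone is decoded less accurately than a clean one", {
  # emulate lost pitch tracking at high F0: measured T4 tracks collapse
  # onto a level contour indistinguishable from T1, while T2 stays faithful
  set.seed(41)
  tones <- tone_set()
  fake_track <- function(tn, flatten = 0, sd_noise = 1) {
    tr <- pitch_track_of(tones[[tn]])
    tr$f0_hz <- (1 - flatten) * tr$f0_hz + flatten * 129 +
      rnorm(nrow(tr), sd = sd_noise)
    tr
  }
  tracks <- c(lapply(1:10, function(i) fake_track("T1")),
              lapply(1:10, function(i) fake_track("T2")),
              lapply(1:10, function(i) fake_track("T3")),
              lapply(1:10, function(i) fake_track("T4", flatten = 1)))
  labels <- rep(c("T1", "T2", "T3", "T4"), each = 10)
  cm <- decode_confusion(tracks, labels, cv = "kfold", fold_seed = 5)
  expect_gt(cm["T2", "T2"], cm["T4", "T4"])
})

test_that("decoding accuracy is nondecreasing in averaging size", {
  cfg <- forward_model_config(n_trials = 32, seed = 29,
                              montage = default_montage(0)[1, , drop = FALSE])
  rec <- simulate_ffr_dataset(cfg, tone_set())
  acc_at_k <- function(k) {
    pseudo <- make_averaged_trials(rec, k, seed = 11)
    tracks <- pseudo_trial_tracks(pseudo)
    decoding_accuracy(decode_confusion(tracks, attr(tracks, "tone_id"),
                                       cv = "kfold", fold_seed = 3))
  }
  accs <- vapply(c(2, 8, 16), acc_at_k, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
  expect_gt(accs[3], 0.25)
})
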