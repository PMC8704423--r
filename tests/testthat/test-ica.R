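test_that("Infomax blindly recovers independent sources up to sign/order", {
  mx <- two_source_mixture(1)
  dec <- fit_ica(mx$X, var_threshold = 0.999, seed = 1)
  expect_equal(dec$n_components, 2L)
  cc <- abs(stats::cor(t(dec$activations), t(mx$S)))
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  # same seed, same decomposition
  dec2 <- fit_ica(mx$X, var_threshold = 0.999, seed = 1)
  expect_identical(dec$unmixing, dec2$unmixing)
})

test_that("a rank-1 mixture is explained entirely by its first component", {
  set.seed(2)
  s <- as.numeric(signal::filtfilt(signal::butter(2, 0.2), stats::rnorm(3000)))
  X <- c(1, -2, 0.5, 3) %o% s
  dec <- suppressWarnings(fit_ica(X, var_threshold = 0.99, seed = 1))
  for (e in 1:4)
    expect_equal(pvaf(dec, 1, e), 100, tolerance = 1e-6)
})

test_that("back-projection reconstructs the retained subspace", {
  mx <- two_source_mixture(5, noise = 0.05)
  dec <- fit_ica(mx$X, var_threshold = 0.95, seed = 3)
  recon <- ica_backproject(dec)
  # oracle: projection of the centred data onto the retained PCA subspace
  xc <- dec$data
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  V <- eg$vectors[, seq_len(dec$n_components), drop = FALSE]
  proj <- V %*% crossprod(V, xc)
  rel <- sqrt(mean((recon - proj)^2)) / sqrt(mean(proj^2))
  expect_lt(rel, 1e-6)
  # joint PVAF of all components ~ 100% of the retained subspace signal
  tot_resid <- xc - recon
  expect_gt(100 * (1 - sum(apply(tot_resid, 1, stats::var)) /
                     sum(apply(xc, 1, stats::var))),
            95)
})

test_that("PVAF bounds, errors, and orthogonal components behave", {
  mx <- two_source_mixture(7)
  dec <- fit_ica(mx$X, var_threshold = 0.999, seed = 2)
  expect_error(pvaf(dec, 1, 99), "electrode")
  expect_error(pvaf(dec, 99, 1), "component")
  # a channel dominated by source 1 gets ~0 PVAF from the other component
  w <- abs(stats::cor(t(dec$activations), t(mx$S)))
  c1 <- which.max(w[, 1])
  A1 <- mx$A
  ch_dom <- which.max(abs(A1[, 1]) / (abs(A1[, 2]) + 1e-9))
  other <- setdiff(1:2, c1)
  expect_lt(pvaf(dec, other, ch_dom), 25)
  expect_gt(pvaf(dec, c1, ch_dom), 75)
})

test_that("component latency and power coherence track the stimulus", {
  st <- tone_set()$T2
  fs <- 8000
  wav <- stimulus_feature(st, fs, "waveform")
  d <- round(0.0034 * fs)             # 3.4 ms
  act <- c(rep(0, d), wav[1:(length(wav) - d)])
  cl <- component_latency(act, wav, fs)
  expect_lte(abs(cl$lag_ms - 3.4), 0.5)
  expect_true(cl$reliable)
  set.seed(8)
  cl_noise <- component_latency(stats::rnorm(length(wav)), wav, fs)
  expect_false(cl_noise$reliable)
  # activation == stimulus: coherence spectrum equals the stimulus PSD
  co <- component_power_coherence(wav, wav, fs)
  ps <- ffrtools:::welch_spectrum(wav, wav, fs,
                                  nperseg = 2^floor(log2(length(wav))))
  expect_equal(co$coherence, Mod(ps$s), tolerance = 1e-10)
  # independent activation: near-floor coherence at the F0 peak
  peak_bin <- which.min(abs(co$freq_hz - 120))
  floor_vals <- replicate(5, {
    co_n <- component_power_coherence(stats::rnorm(length(wav)) *
                                        stats::sd(wav), wav, fs)
    co_n$coherence[peak_bin]
  })
  expect_lt(mean(floor_vals), 0.05 * co$coherence[peak_bin])
})

test_that("source labeling is correct and invariant to sign and order", {
  sim <- clean_sim()
  rec <- sim$rec
  dec <- fit_ica(ica_input_from_ffrs(sim$ffrs), var_threshold = 0.96,
                 seed = 5)
  truth <- source_truth(sim$config)
  r_sub <- apply(dec$activations, 1, stats::cor, y = truth$sub)
  r_ctx <- apply(dec$activations, 1, stats::cor, y = truth$ctx)
  onset <- which.min(abs(epoch_times_ms(rec)))
  n_tone <- dim(rec$data)[3]
  feat <- stimulus_feature(tone_set()$T4, rec$fs, "waveform")
  lats <- vapply(seq_len(dec$n_components), function(j)
    component_latency(dec$activations[j, (3 * n_tone + onset):(4 * n_tone)],
                      feat, rec$fs)$lag_ms, numeric(1))
  intra <- which(rec$channel_meta$kind != "scalp")
  tab <- classify_components(dec, lats, intracranial = intra)
  i_sub <- which.max(abs(r_sub)); i_ctx <- which.max(abs(r_ctx))
  expect_equal(tab$label[i_sub], "putative_subcortical")
  expect_equal(tab$label[i_ctx], "putative_cortical")
  # flipping signs and swapping order leaves labels unchanged
  flip <- dec
  flip$spatial_weights <- -flip$spatial_weights[, rev(seq_len(dec$n_components))]
  flip$activations <- -flip$activations[rev(seq_len(dec$n_components)), ,
                                        drop = FALSE]
  flip$total_pvaf <- rev(dec$total_pvaf)
  tab_f <- classify_components(flip, rev(lats), intracranial = intra)
  expect_equal(tab_f$label, rev(tab$label))
})
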