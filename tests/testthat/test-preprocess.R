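make_epochs <- function(signals, fs = 1000, t0_ms = -25,
                        polarity = NULL, tone_id = NULL) {
  n_tr <- length(signals)
  n <- length(signals[[1]])
  dat <- array(0, dim = c(n_tr, 1, n))
  for (i in seq_len(n_tr)) dat[i, 1, ] <- signals[[i]]
  epoched_recording(dat, fs, t0_ms,
                    data.frame(label = "Cz", kind = "scalp", depth_um = NA),
                    polarity = polarity %||%
                      rep(c("condensation", "rarefaction"),
                          length.out = n_tr),
                    tone_id = tone_id %||% rep("T1", n_tr))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

band_power <- function(x, fs, f0, bw = 2) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n
  fr <- (seq_len(n) - 1) / n * fs
  sum(X[fr >= f0 - bw & fr <= f0 + bw])
}

test_that("line-noise regression removes 60 Hz harmonics, keeps the rest", {
  fs <- 1000; t <- (0:999) / fs
  pure <- sin(2 * pi * 60 * t + 0.7)
  ep <- make_epochs(list(pure, pure))
  out <- remove_line_noise(ep, 60, 1)
  red_db <- 10 * log10(band_power(ep$data[1, 1, ], fs, 60) /
                       max(band_power(out$data[1, 1, ], fs, 60), 1e-30))
  expect_gt(red_db, 20)
  # composite 60+120+180 all attenuated
  comp <- sin(2 * pi * 60 * t) + 0.5 * sin(2 * pi * 120 * t + 1) +
    0.3 * sin(2 * pi * 180 * t + 2)
  out2 <- remove_line_noise(make_epochs(list(comp, comp)), 60, 3)
  for (f in c(60, 120, 180))
    expect_lt(band_power(out2$data[1, 1, ], fs, f),
              0.01 * band_power(comp, fs, f))
  # broadband signal without line energy passes through unchanged
  set.seed(1)
  bb <- as.numeric(signal::filtfilt(signal::butter(4, 0.4), rnorm(1000)))
  bb <- bb - as.numeric(stats::fitted(stats::lm(bb ~ sin(2 * pi * 60 * t) +
                                                  cos(2 * pi * 60 * t))))
  out3 <- remove_line_noise(make_epochs(list(bb, bb)), 60, 1)
  expect_equal(out3$data[1, 1, ], bb, tolerance = 1e-8)
  # harmonics above Nyquist skipped with a warning
  expect_warning(remove_line_noise(make_epochs(list(pure, pure)), 60, 12),
                 "Nyquist")
})

test_that("zero-phase filtering preserves latency and the passband", {
  fs <- 4000; n <- 4000
  imp <- numeric(n); imp[2000] <- 1
  ep <- filter_epochs(make_epochs(list(imp, imp), fs = fs), c(80, 1000))
  expect_lte(abs(which.max(abs(ep$data[1, 1, ])) - 2000), 1)
  t <- (seq_len(n) - 1) / fs
  s40 <- sin(2 * pi * 40 * t)
  out40 <- filter_epochs(make_epochs(list(s40, s40), fs = fs), c(80, 1000))
  expect_lt(sqrt(mean(out40$data[1, 1, ]^2)) / sqrt(mean(s40^2)), 0.10)
  s200 <- sin(2 * pi * 200 * t)
  out200 <- filter_epochs(make_epochs(list(s200, s200), fs = fs),
                          c(80, 1000))
  expect_equal(sqrt(mean(out200$data[1, 1, ]^2)), sqrt(mean(s200^2)),
               tolerance = 0.05)
  expect_error(filter_epochs(make_epochs(list(s40, s40), fs = fs),
                             c(1000, 80)), "inverted")
})

test_that("amplitude rejection matches a brute-force scan", {
  set.seed(3)
  sig <- lapply(1:20, function(i) rnorm(200, sd = runif(1, 10, 40)))
  ep <- make_epochs(sig)
  res <- reject_artifacts(ep, 75)
  brute <- vapply(sig, function(x) max(abs(x)) <= 75, logical(1))
  expect_equal(res$kept, brute)
  expect_equal(res$n_rejected, sum(!brute))
  # single over-threshold trial is dropped
  hot <- make_epochs(list(rnorm(200, sd = 5), c(rep(0, 100), 80, rep(0, 99))))
  expect_equal(reject_artifacts(hot, 75)$n_rejected, 1L)
  # none dropped below threshold
  cold <- make_epochs(lapply(1:4, function(i) rnorm(200, sd = 1)))
  expect_equal(reject_artifacts(cold, 75)$n_rejected, 0L)
  expect_error(reject_artifacts(make_epochs(list(rep(100, 10),
                                                 rep(100, 10))), 75),
               "all trials rejected")
})

test_that("polarity averaging cancels sign-flipping artifact components", {
  fs <- 1000; t <- (0:499) / fs
  neural <- sin(2 * pi * 110 * t)
  artifact <- 0.8 * sin(2 * pi * 220 * t + 0.3)
  ep <- make_epochs(list(neural + artifact, neural - artifact,
                         neural + artifact, neural - artifact),
                    fs = fs,
                    polarity = c("condensation", "rarefaction",
                                 "condensation", "rarefaction"))
  avg <- average_polarities(ep)$T1
  resid <- band_power(ffr_channel(avg), fs, 220)
  expect_lt(resid, 0.01 * band_power(artifact, fs, 220))
  # identical polarity responses reduce to the plain mean
  ep2 <- make_epochs(list(neural, neural, neural, neural), fs = fs)
  expect_equal(ffr_channel(average_polarities(ep2)$T1), neural)
  # unbalanced counts: polarity means still weighted equally
  ep3 <- make_epochs(list(neural + 1, neural + 1, neural - 1),
                     fs = fs,
                     polarity = c("condensation", "condensation",
                                  "rarefaction"))
  expect_equal(mean(ffr_channel(average_polarities(ep3)$T1) - neural), 0,
               tolerance = 1e-12)
  # one polarity missing: warning, plain mean
  ep4 <- make_epochs(list(neural, neural), fs = fs,
                     polarity = c("condensation", "condensation"))
  expect_warning(average_polarities(ep4), "polarity")
})

test_that("bootstrap significance separates FFRs from noise", {
  set.seed(7)
  # strong simulated FFR: per-trial SNR >> 1
  fs <- 2000; n <- 250; t_ms <- -25 + 1000 * (0:(n - 1)) / fs
  sig <- ifelse(t_ms >= 0, 5 * sin(2 * pi * 110 * t_ms / 1000), 0)
  strong <- lapply(1:24, function(i) sig + rnorm(n, sd = 0.5))
  rep_strong <- ffr_snr_and_significance(make_epochs(strong, fs = fs),
                                         response_window_ms = c(0, 100),
                                         n_boot = 500, seed = 1)
  expect_lt(rep_strong$p_value, 0.01)
  expect_gt(rep_strong$snr, 2)
  # response window copied from baseline content gives SNR exactly 1
  flat <- rep(1, n)
  rep_flat <- ffr_snr_and_significance(make_epochs(list(flat, flat),
                                                   fs = fs),
                                       response_window_ms = c(0, 25),
                                       n_boot = 100, seed = 1)
  expect_equal(rep_flat$snr, 1)
  expect_error(ffr_snr_and_significance(make_epochs(strong, fs = fs),
                                        n_boot = 50), "n_boot")
  expect_error(ffr_snr_and_significance(make_epochs(strong, fs = fs),
                                        baseline_window_ms = c(-25, 10)),
               "baseline")
})

test_that("sign-flip paired tests behave at both extremes and match enumeration", {
  a <- c(1.2, 0.8, 1.1, 0.9, 1.3, 1.0, 0.95, 1.05, 1.15, 0.85)
  expect_equal(compare_paired(a, a)$p_value, 1)
  expect_lt(compare_paired(a, a + 10)$p_value, 0.01)
  expect_error(compare_paired(a[1:4], a[1:4]), "5 pairs")
  # n = 10 exhaustive enumeration equals an independent oracle
  set.seed(2)
  b <- a + rnorm(10, 0, 0.3)
  d <- a - b
  w_of <- function(d) { nz <- d != 0
    sum(sign(d[nz]) * rank(abs(d[nz]))) }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  p_oracle <- mean(abs(apply(signs, 1, function(s) w_of(d * s))) >=
                   abs(w_of(d)) - 1e-12)
  res <- compare_paired(a, b)
  expect_true(res$exhaustive)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  # sampled permutation agrees with enumeration within 0.02
  res_s <- compare_paired(c(a, a + 0.2), c(b, b), n_perm = 5000, seed = 4)
  d2 <- c(a, a + 0.2) - c(b, b)
  signs2 <- as.matrix(expand.grid(rep(list(c(-1, 1)), 20)))[
    sample.int(2^20, 20000), ]
  p2 <- mean(abs(apply(signs2, 1, function(s) w_of(d2 * s))) >=
             abs(w_of(d2)) - 1e-12)
  expect_lt(abs(res_s$p_value - p2), 0.02)
})
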