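# shared numeric helpers

# normalized (Pearson) cross-correlation over a bounded lag range.
# Sign convention: positive lag means y lags (is delayed relative to) x,
# i.e. r(lag) = cor(x[t], y[t + lag]).
xcorr_lag <- function(x, y, fs, max_lag_ms = 30) {
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  max_l <- min(n - 3L, round(max_lag_ms / 1000 * fs))
  lags <- -max_l:max_l
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- x[seq_len(n - l)]; b <- y[(1 + l):n]
    } else {
      a <- x[(1 - l):n]; b <- y[seq_len(n + l)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))
  best <- which.max(abs(r))
  list(lag_ms = 1000 * lags[best] / fs, r = r[best],
       lags_ms = 1000 * lags / fs, r_by_lag = r)
}

# Gaussian smoothing along the depth dimension of a depth x time matrix;
# kernel truncated at the probe ends and renormalized per row.
gaussian_smooth_depth <- function(mat, depths_um, sd_um) {
  if (sd_um <= 0) return(mat)
  W <- exp(-outer(depths_um, depths_um, `-`)^2 / (2 * sd_um^2))
  W <- W / rowSums(W)
  W %*% mat
}

rms <- function(x) sqrt(mean(x^2))
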