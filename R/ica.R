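#' Concatenate averaged FFRs into an ICA input matrix
#'
#' Stacks the four tone-averaged multichannel FFRs along time (the standard
#' input for decomposing averaged evoked responses).
#'
#' @param ffrs Named list of `ffr_waveform`s (one per tone).
#' @return channels x time matrix with channel labels as rownames.
#' @export
ica_input_from_ffrs <- function(ffrs) {
  mats <- lapply(ffrs, function(f) f$samples)
  x <- do.call(cbind, mats)
  rownames(x) <- ffrs[[1]]$channels
  x
}

#' Infomax independent component analysis of multichannel FFRs
#'
#' PCA first reduces dimensionality to the smallest number of components
#' retaining `var_threshold` of the variance; the whitened data are then
#' unmixed with natural-gradient Infomax (logistic nonlinearity).
#' Components are ordered by descending total percent variance accounted
#' for (PVAF) so reporting is reproducible regardless of convergence order.
#' Deterministic for a fixed seed.
#'
#' @param x channels x time matrix (averaged FFRs for all tones
#'   concatenated; see [ica_input_from_ffrs()]).
#' @param var_threshold Fraction of variance the retained PCA subspace must
#'   explain (e.g. 0.96 or 0.99).
#' @param seed Integer seed (random initial rotation).
#' @param max_iter Maximum Infomax iterations.
#' @param lrate Initial learning rate (annealed automatically).
#' @return An `ica_decomposition`: `unmixing` (components x channels, the
#'   product of ICA weights and sphering), `ica_weights`, `sphering`,
#'   `spatial_weights` (channels x components, pseudoinverse of
#'   weights x sphering), `activations` (components x time), `pvaf`
#'   (components x channels, percent), `total_pvaf`,
#'   `retained_variance_fraction`, `channel_labels`, plus the centred data
#'   for back-projection checks.
#' @export
fit_ica <- function(x, var_threshold = 0.99, seed = 1,
                    max_iter = 1000, lrate = 0.05) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 channels")
  labs <- rownames(x)
  if (is.null(labs)) labs <- sprintf("ch%02d", seq_len(nrow(x)))
  ctr <- rowMeans(x)
  xc <- x - ctr
  n_t <- ncol(xc)
  cv <- tcrossprod(xc) / n_t
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= var_threshold)[1]
  rank_ok <- ev > 1e-12 * ev[1]
  if (m > sum(rank_ok)) {
    warning("rank-deficient input; reducing to rank ", sum(rank_ok))
    m <- sum(rank_ok)
  }
  P <- diag(1 / sqrt(ev[seq_len(m)]), m) %*% t(eg$vectors[, seq_len(m)])
  y <- P %*% xc                                   # whitened, m x T
  set.seed(seed)
  W <- diag(m)
  if (m > 1) {                                    # small seeded rotation
    Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
    W <- 0.95 * W + 0.05 * Q
  }
  lr <- lrate
  old_dW <- NULL
  for (it in seq_len(max_iter)) {
    u <- W %*% y
    g <- 1 / (1 + exp(-u))
    dW <- lr * (diag(m) + ((1 - 2 * g) %*% t(u)) / n_t) %*% W
    W <- W + dW
    ch <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    if (!is.null(old_dW)) {
      ang <- sum(dW * old_dW) / sqrt(sum(dW^2) * sum(old_dW^2) + 1e-300)
      if (ang < 0) lr <- lr * 0.9                 # anneal on oscillation
    }
    old_dW <- dW
    if (ch < 1e-9) break
  }
  unmix <- W %*% P                                # m x channels
  A <- MASS::ginv(unmix)                          # channels x m
  act <- unmix %*% xc
  # per-component, per-electrode PVAF of the back-projection
  ve <- apply(xc, 1, stats::var)
  if (any(ve == 0)) warning("zero-variance electrode present")
  pv <- matrix(NA_real_, m, nrow(x))
  tot <- numeric(m)
  for (j in seq_len(m)) {
    bp <- A[, j] %o% act[j, ]
    res <- xc - bp
    vr <- apply(res, 1, stats::var)
    pv[j, ] <- 100 * (1 - vr / pmax(ve, 1e-300))
    tot[j] <- 100 * (1 - sum(vr) / sum(ve))
  }
  ord <- order(tot, decreasing = TRUE)
  structure(list(unmixing = unmix[ord, , drop = FALSE],
                 ica_weights = W[ord, , drop = FALSE], sphering = P,
                 spatial_weights = A[, ord, drop = FALSE],
                 activations = act[ord, , drop = FALSE],
                 pvaf = pv[ord, , drop = FALSE],
                 total_pvaf = tot[ord],
                 retained_variance_fraction = cum[m],
                 n_components = m, channel_labels = labs,
                 center = ctr, data = xc),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition: %d components over %d channels (%.1f%% variance retained)>\n",
              x$n_components, length(x$channel_labels),
              100 * x$retained_variance_fraction))
  cat("total PVAF (%):", paste(sprintf("%.1f", x$total_pvaf),
                               collapse = " "), "\n")
  invisible(x)
}

#' Percent variance accounted for by one component at one electrode
#'
#' `100 * (1 - var(signal - back-projection) / var(signal))` at that
#' electrode.
#'
#' @param decomposition An `ica_decomposition`.
#' @param component Component index.
#' @param electrode Electrode index or label.
#' @return Percent (can be negative for a component that adds variance at
#'   that electrode).
#' @export
pvaf <- function(decomposition, component, electrode) {
  if (is.character(electrode))
    electrode <- match(electrode, decomposition$channel_labels)
  if (is.na(electrode) || electrode < 1 ||
      electrode > length(decomposition$channel_labels))
    stop("invalid electrode")
  if (component < 1 || component > decomposition$n_components)
    stop("invalid component")
  if (stats::var(decomposition$data[electrode, ]) == 0)
    stop("zero-variance electrode; PVAF undefined")
  decomposition$pvaf[component, electrode]
}

#' Back-projection of a set of components into channel space
#' @param decomposition An `ica_decomposition`.
#' @param components Component indices (default all).
#' @return channels x time matrix (centred units).
#' @export
ica_backproject <- function(decomposition,
                            components = seq_len(decomposition$n_components)) {
  decomposition$spatial_weights[, components, drop = FALSE] %*%
    decomposition$activations[components, , drop = FALSE]
}

#' Latency of a component relative to the stimulus
#'
#' Cross-correlates the component activation with the stimulus feature and
#' reports the lag of maximum absolute correlation; positive lags mean the
#' activation follows the stimulus. Low peak correlations are flagged
#' unreliable.
#'
#' @param activation Component activation time series (stimulus-aligned,
#'   starting at stimulus onset).
#' @param stimulus_ref Stimulus waveform or envelope at the same rate.
#' @param fs Sampling rate.
#' @param max_lag_ms Search bound (default 30 ms).
#' @param min_abs_r Reliability floor on `|r|` (default 0.2).
#' @return List: `lag_ms`, `r`, `reliable`.
#' @export
component_latency <- function(activation, stimulus_ref, fs,
                              max_lag_ms = 30, min_abs_r = 0.2) {
  xc <- xcorr_lag(stimulus_ref, activation, fs, max_lag_ms)
  list(lag_ms = xc$lag_ms, r = xc$r, reliable = abs(xc$r) >= min_abs_r)
}

#' Power coherence between a component and the stimulus
#'
#' Magnitude of the Welch cross-power spectral density between the
#' component activation and the stimulus waveform. This measures shared
#' power across frequency, not phase-locking.
#'
#' @param activation Component activation.
#' @param stimulus Stimulus waveform at the same rate.
#' @param fs Sampling rate.
#' @param nperseg,overlap Welch parameters.
#' @return data.frame `freq_hz`, `coherence` (|CPSD|).
#' @export
component_power_coherence <- function(activation, stimulus, fs,
                                      nperseg = 1024, overlap = 0.5) {
  sp <- welch_spectrum(stimulus, activation, fs,
                       nperseg = min(nperseg,
                                     2^floor(log2(min(length(activation),
                                                      length(stimulus))))),
                       overlap = overlap)
  data.frame(freq_hz = sp$freq_hz, coherence = Mod(sp$s))
}

#' Rule-based cortical/subcortical component labeling
#'
#' Components explaining at least `min_pvaf` percent of the total variance
#' are labeled by two criteria: latency versus the stimulus and the
#' steepness of their spatial-weight profile over the intracranial
#' electrodes (SD / |mean| of the weights; a volume-conducted distant
#' generator is spatially flat, a local cortical generator has a steep
#' gradient). Short latency + flat weights = putative subcortical; long
#' latency + steep gradient = putative cortical; anything else is
#' unclassified. Labels are invariant to component sign flips and
#' reordering.
#'
#' @param decomposition An `ica_decomposition`.
#' @param latencies_ms Per-component latency (e.g. from
#'   [component_latency()]).
#' @param intracranial Indices or labels of the intracranial electrodes
#'   used for the gradient statistic (default: all electrodes).
#' @param latency_cut_ms Subcortical/cortical latency boundary (default 6).
#' @param gradient_cut SD/|mean| boundary (default 0.5).
#' @param min_pvaf Minimum total PVAF (percent) for labeling (default 10).
#' @return data.frame: `component`, `total_pvaf`, `latency_ms`,
#'   `gradient`, `label` in {putative_subcortical, putative_cortical,
#'   unclassified, excluded}.
#' @export
classify_components <- function(decomposition, latencies_ms,
                                intracranial = NULL,
                                latency_cut_ms = 6, gradient_cut = 0.5,
                                min_pvaf = 10) {
  m <- decomposition$n_components
  stopifnot(length(latencies_ms) == m)
  idx <- if (is.null(intracranial)) seq_along(decomposition$channel_labels)
         else if (is.character(intracranial))
           match(intracranial, decomposition$channel_labels)
         else intracranial
  grad <- vapply(seq_len(m), function(j) {
    w <- decomposition$spatial_weights[idx, j]
    stats::sd(w) / max(abs(mean(w)), 1e-12)
  }, numeric(1))
  label <- vapply(seq_len(m), function(j) {
    if (decomposition$total_pvaf[j] < min_pvaf) return("excluded")
    if (latencies_ms[j] <= latency_cut_ms && grad[j] <= gradient_cut)
      "putative_subcortical"
    else if (latencies_ms[j] > latency_cut_ms && grad[j] > gradient_cut)
      "putative_cortical"
    else "unclassified"
  }, character(1))
  data.frame(component = seq_len(m),
             total_pvaf = decomposition$total_pvaf,
             latency_ms = latencies_ms, gradient = grad, label = label)
}
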