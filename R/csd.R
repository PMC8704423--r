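#' Current source density across laminar depth
#'
#' Smooths the LFP along depth with a Gaussian (kernel truncated and
#' renormalized at the probe ends) and takes the negative second spatial
#' derivative by finite differences. Edge depths are dropped (no padding),
#' so the profile covers the interior contacts. Sinks are negative by
#' convention. The result is reference-free: any depth-constant offset
#' cancels exactly in the second difference.
#'
#' @param lfp_by_depth depths x time numeric matrix (uV), superficial
#'   first.
#' @param spacing_um Uniform contact spacing, micrometres.
#' @param smoothing_sd_um Gaussian SD for depth smoothing (e.g. 250 for
#'   150 um spacing, 125 for 120 um spacing); 0 disables smoothing.
#' @param depths_um Optional contact depths (defaults to
#'   `spacing_um * (0:(n-1))`); must be uniformly spaced.
#' @param fs Sampling rate (kept as metadata).
#' @param t0_ms Epoch start (metadata).
#' @return A `csd_profile`: `csd` (interior-depths x time,
#'   uV/um^2, sink-negative), `depths_um`, `fs`, `t0_ms`, `spacing_um`,
#'   `smoothing_sd_um`.
#' @export
compute_csd <- function(lfp_by_depth, spacing_um, smoothing_sd_um = 0,
                        depths_um = NULL, fs = NA_real_, t0_ms = 0) {
  lfp <- as.matrix(lfp_by_depth)
  nd <- nrow(lfp)
  if (nd < 3) stop("need at least 3 depth channels")
  if (is.null(depths_um)) depths_um <- spacing_um * (seq_len(nd) - 1)
  dd <- diff(depths_um)
  if (any(abs(dd - dd[1]) > 1e-6 * abs(dd[1])))
    stop("non-uniform electrode spacing")
  sm <- gaussian_smooth_depth(lfp, depths_um, smoothing_sd_um)
  interior <- 2:(nd - 1)
  csd <- -(sm[interior - 1, , drop = FALSE] -
           2 * sm[interior, , drop = FALSE] +
           sm[interior + 1, , drop = FALSE]) / spacing_um^2
  structure(list(csd = csd, depths_um = depths_um[interior], fs = fs,
                 t0_ms = t0_ms, spacing_um = spacing_um,
                 smoothing_sd_um = smoothing_sd_um),
            class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile: %d depths (%g-%g um) x %d samples; sinks negative>\n",
              nrow(x$csd), min(x$depths_um), max(x$depths_um), ncol(x$csd)))
  invisible(x)
}

#' Earliest post-onset CSD sink
#'
#' Scans the post-stimulus search window for the first time any depth's
#' CSD crosses below `-k_sd` baseline standard deviations (per depth,
#' estimated from the prestimulus samples; if the baseline is silent an
#' absolute floor of `abs_frac` of the global CSD extremum is used). The
#' earliest crossing identifies the putative thalamorecipient depth.
#'
#' @param csd A `csd_profile` with valid `fs` and `t0_ms`.
#' @param search_window_ms Post-onset window to scan (start >= 0).
#' @param k_sd Threshold in baseline SDs (default 3).
#' @param abs_frac Absolute-threshold fallback as a fraction of
#'   `max(abs(csd))` (default 0.2) when the baseline SD is ~0.
#' @param min_duration_ms The CSD must stay below threshold for at least
#'   this long for a crossing to count as a sink (default 1.5 ms),
#'   suppressing isolated noise excursions.
#' @return List: `found`, `depth_index`, `depth_um`, `latency_ms`
#'   (NA/FALSE when no sink crosses threshold — not an error).
#' @export
find_earliest_sink <- function(csd, search_window_ms = c(0, 60),
                               k_sd = 3, abs_frac = 0.2,
                               min_duration_ms = 1.5) {
  stopifnot(search_window_ms[1] >= 0)
  t_ms <- csd$t0_ms + 1000 * (seq_len(ncol(csd$csd)) - 1) / csd$fs
  ib <- t_ms < 0
  iw <- t_ms >= search_window_ms[1] & t_ms <= search_window_ms[2]
  if (!any(iw)) stop("empty search window")
  glob <- max(abs(csd$csd))
  min_run <- max(1L, round(min_duration_ms / 1000 * csd$fs))
  best_t <- Inf; best_d <- NA_integer_
  for (d in seq_len(nrow(csd$csd))) {
    bsd <- if (any(ib)) stats::sd(csd$csd[d, ib]) else 0
    thr <- if (bsd > 1e-6 * glob) -k_sd * bsd else -abs_frac * glob
    below <- iw & csd$csd[d, ] < thr
    # earliest onset of a run of >= min_run below-threshold samples
    r <- rle(below)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_run)
    if (length(hit)) {
      t_hit <- t_ms[ends[hit[1]] - r$lengths[hit[1]] + 1]
      if (t_hit < best_t) { best_t <- t_hit; best_d <- d }
    }
  }
  if (!is.finite(best_t))
    return(list(found = FALSE, depth_index = NA_integer_,
                depth_um = NA_real_, latency_ms = NA_real_))
  list(found = TRUE, depth_index = best_d,
       depth_um = csd$depths_um[best_d], latency_ms = best_t)
}

#' Stimulus-to-CSD correlation by depth
#'
#' Cross-correlates every depth's CSD trace with a stimulus periodicity
#' feature and reports the signed maximum-magnitude correlation and its
#' lag, so polarity flips across layers remain visible.
#'
#' @param csd A `csd_profile`.
#' @param stimulus_feature Feature vector at the CSD sampling rate (see
#'   [stimulus_feature()]); shorter inputs are aligned at stimulus onset.
#' @param max_lag_ms Lag search bound (default 30 ms).
#' @return data.frame: `depth_um`, `r` (signed), `lag_ms`.
#' @export
stimulus_csd_correlation <- function(csd, stimulus_feature,
                                     max_lag_ms = 30) {
  t_ms <- csd$t0_ms + 1000 * (seq_len(ncol(csd$csd)) - 1) / csd$fs
  i0 <- which.min(abs(t_ms))
  n <- min(length(stimulus_feature), ncol(csd$csd) - i0 + 1)
  feat <- stimulus_feature[seq_len(n)]
  res <- t(vapply(seq_len(nrow(csd$csd)), function(d) {
    xc <- xcorr_lag(feat, csd$csd[d, i0:(i0 + n - 1)], csd$fs, max_lag_ms)
    c(xc$r, xc$lag_ms)
  }, numeric(2)))
  data.frame(depth_um = csd$depths_um, r = res[, 1], lag_ms = res[, 2])
}

#' Multi-unit activity envelope by depth
#'
#' Classic MUA chain: zero-phase bandpass (default 300-3000 Hz), full-wave
#' rectification, zero-phase low-pass envelope (default 200 Hz), per depth.
#'
#' @param raw_by_depth depths x time matrix of broadband signal.
#' @param fs Sampling rate (must support the bandpass; >= 2x upper edge).
#' @param band MUA bandpass, Hz.
#' @param envelope_lowpass_hz Envelope smoothing cut-off, Hz.
#' @return depths x time envelope matrix.
#' @export
extract_mua <- function(raw_by_depth, fs, band = c(300, 3000),
                        envelope_lowpass_hz = 200) {
  raw <- as.matrix(raw_by_depth)
  if (fs < 2 * band[2]) stop("fs too low for MUA band: need >= ", 2 * band[2])
  nyq <- fs / 2
  bp <- signal::butter(3, band / nyq, "pass")
  lp <- signal::butter(3, envelope_lowpass_hz / nyq, "low")
  t(apply(raw, 1, function(x) {
    h <- abs(as.numeric(signal::filtfilt(bp, x)))
    as.numeric(signal::filtfilt(lp, h))
  }))
}
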