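#' Build averaged pseudo-trials
#'
#' Randomly partitions the trials of each tone into disjoint groups of `k`
#' and averages each group, trading trial count for single-trial SNR
#' (pseudo-trial SNR grows roughly as sqrt(k)). Groups are polarity-balanced
#' by interleaving the shuffled condensation and rarefaction trials before
#' grouping. `k = 1` returns shuffled single trials; `k = n_trials` returns
#' one pseudo-trial equal to the (balanced) grand mean.
#'
#' @param epochs An `epoched_recording`.
#' @param k Averaging size (trials per pseudo-trial).
#' @param seed Integer seed for the grouping.
#' @param channel Channel label to extract (default first channel).
#' @param min_pseudo_trials Minimum pseudo-trials required per tone; an
#'   error names the shortfall if not met.
#' @return List: `x` (pseudo-trials x samples matrix), `tone_id`, `fs`,
#'   `t0_ms`, `k`.
#' @export
make_averaged_trials <- function(epochs, k, seed = 1, channel = NULL,
                                 min_pseudo_trials = 1) {
  stopifnot(k >= 1)
  ch <- if (is.null(channel)) 1L
        else match(channel, epochs$channel_meta$label)
  set.seed(seed)
  xs <- list(); labs <- character(0)
  for (tn in unique(epochs$tone_id)) {
    idx <- which(epochs$tone_id == tn)
    n <- length(idx)
    n_pseudo <- floor(n / k)
    if (n_pseudo < min_pseudo_trials)
      stop("tone ", tn, ": ", n, " trials give ", n_pseudo,
           " pseudo-trials at k=", k, " (need ", min_pseudo_trials, ")")
    pol <- epochs$polarity[idx]
    by_pol <- split(idx, pol)
    by_pol <- lapply(by_pol, sample)
    ord <- as.integer(t(do.call(cbind, lapply(by_pol, function(v)
      v[seq_len(min(lengths(by_pol)))]))))
    ord <- c(ord, setdiff(unlist(by_pol), ord))   # leftovers at the end
    for (g in seq_len(n_pseudo)) {
      gi <- ord[((g - 1) * k + 1):(g * k)]
      m <- epochs$data[gi, ch, , drop = FALSE]
      dim(m) <- c(length(gi), dim(epochs$data)[3])
      xs[[length(xs) + 1L]] <- colMeans(m)
      labs <- c(labs, tn)
    }
  }
  list(x = do.call(rbind, xs), tone_id = labs, fs = epochs$fs,
       t0_ms = epochs$t0_ms, k = k)
}

# (f0, delta-f0) feature matrix from a pitch track
track_features <- function(track) {
  f0 <- track$f0_hz
  cbind(f0 = f0, df0 = c(0, diff(f0)))
}

#' Pitch tracks of pseudo-trials
#'
#' Runs [track_pitch()] over every pseudo-trial waveform, restricted to the
#' post-onset response portion.
#'
#' @param pseudo Result of [make_averaged_trials()].
#' @param response_window_ms Portion of the epoch to track (default 0 to
#'   250 ms).
#' @param ... Passed to [track_pitch()].
#' @return List of `pitch_track`s (one per pseudo-trial), with `tone_id`
#'   attribute.
#' @export
pseudo_trial_tracks <- function(pseudo, response_window_ms = c(0, 250), ...) {
  t_ms <- pseudo$t0_ms + 1000 * (seq_len(ncol(pseudo$x)) - 1) / pseudo$fs
  sel <- t_ms >= response_window_ms[1] & t_ms <= response_window_ms[2]
  tracks <- lapply(seq_len(nrow(pseudo$x)), function(i)
    track_pitch(pseudo$x[i, sel], pseudo$fs, ...))
  attr(tracks, "tone_id") <- pseudo$tone_id
  tracks
}

#' Fit the HMM tone decoder
#'
#' Trains one left-to-right Gaussian HMM per tone on (F0, delta-F0) feature
#' sequences extracted from pitch tracks.
#'
#' @param pitch_tracks List of `pitch_track`s.
#' @param labels Tone label per track (>= 2 tracks per tone).
#' @param n_states,n_iter,var_floor Passed to [fit_lr_hmm()].
#' @return An `hmm_decoder`: per-tone models plus the label set.
#' @export
fit_hmm_decoder <- function(pitch_tracks, labels, n_states = 4,
                            n_iter = 20, var_floor = 1) {
  lev <- sort(unique(labels))
  feats <- lapply(pitch_tracks, track_features)
  models <- lapply(lev, function(tn) {
    tr <- feats[labels == tn]
    if (length(tr) < 2) stop("need >= 2 training tracks per tone (", tn, ")")
    fit_lr_hmm(tr, n_states = n_states, n_iter = n_iter,
               var_floor = var_floor)
  })
  structure(list(models = stats::setNames(models, lev), levels = lev),
            class = "hmm_decoder")
}

#' Decode tone labels with a fitted HMM decoder
#' @param decoder An `hmm_decoder`.
#' @param pitch_tracks List of `pitch_track`s.
#' @return Character vector of decoded labels (log-likelihood argmax; ties
#'   go to the lowest tone index and are counted in the `"ties"` attribute).
#' @export
predict_hmm_decoder <- function(decoder, pitch_tracks) {
  n_ties <- 0L
  out <- vapply(pitch_tracks, function(tr) {
    o <- track_features(tr)
    ll <- vapply(decoder$models, loglik_lr_hmm, numeric(1), obs = o)
    best <- which(ll >= max(ll) - 1e-12)
    if (length(best) > 1) n_ties <<- n_ties + 1L
    decoder$levels[best[1]]
  }, character(1))
  attr(out, "ties") <- n_ties
  out
}

#' Cross-validated confusion matrix for HMM tone decoding
#'
#' Leave-one-out over tracks by default: for each held-out track the
#' decoder is refit on the remaining tracks, guaranteeing no train/test
#' overlap. Rows (true tone) are normalized to sum to 1.
#'
#' @param pitch_tracks List of `pitch_track`s.
#' @param labels True tone per track.
#' @param cv `"loo"` (default), `"kfold"` (stratified k-fold, faster for
#'   many tracks) or `"none"` (fit on all, predict all; diagnostics only).
#' @param n_folds Folds for `cv = "kfold"`.
#' @param fold_seed Seed for the stratified fold assignment.
#' @param averaging_size Bookkeeping: the trial-averaging size that
#'   produced the tracks.
#' @param ... Passed to [fit_hmm_decoder()].
#' @return A `confusion_matrix`: row-stochastic K x K matrix with `counts`
#'   and `averaging_size` attributes.
#' @export
decode_confusion <- function(pitch_tracks, labels,
                             cv = c("loo", "kfold", "none"),
                             n_folds = 4, fold_seed = 1,
                             averaging_size = NA, ...) {
  cv <- match.arg(cv)
  lev <- sort(unique(labels))
  pred <- if (cv == "loo") {
    vapply(seq_along(pitch_tracks), function(i) {
      dec <- fit_hmm_decoder(pitch_tracks[-i], labels[-i], ...)
      predict_hmm_decoder(dec, pitch_tracks[i])[1]
    }, character(1))
  } else if (cv == "kfold") {
    set.seed(fold_seed)
    fold <- integer(length(labels))
    for (tn in lev) {
      idx <- sample(which(labels == tn))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    out <- character(length(labels))
    for (f in seq_len(n_folds)) {
      te <- fold == f
      dec <- fit_hmm_decoder(pitch_tracks[!te], labels[!te], ...)
      out[te] <- predict_hmm_decoder(dec, pitch_tracks[te])
    }
    out
  } else {
    dec <- fit_hmm_decoder(pitch_tracks, labels, ...)
    predict_hmm_decoder(dec, pitch_tracks)
  }
  counts <- table(factor(labels, lev), factor(pred, lev))
  cm <- sweep(unclass(counts), 1, pmax(rowSums(counts), 1), `/`)
  structure(cm, counts = unclass(counts), averaging_size = averaging_size,
            class = c("confusion_matrix", class(cm)))
}

#' Mean decoding accuracy of a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return Mean of the diagonal (chance = 1/K).
#' @export
decoding_accuracy <- function(cm) mean(diag(as.matrix(cm)))
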