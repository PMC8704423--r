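# Left-to-right Gaussian hidden Markov model (diagonal covariance),
# trained by Baum-Welch in log space. Small and purpose-built for decoding
# pitch-contour feature sequences; no general HMM machinery is needed.

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# log emission densities: T x S matrix for one sequence (T x D)
lr_hmm_logb <- function(obs, means, vars) {
  S <- nrow(means)
  out <- vapply(seq_len(S), function(s) {
    -0.5 * colSums((t(obs) - means[s, ])^2 / vars[s, ] +
                   log(2 * pi * vars[s, ]))
  }, numeric(nrow(obs)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

# scaled forward pass; returns log-likelihood and (optionally) log-alpha
lr_hmm_forward <- function(logb, log_pi, log_A) {
  Tn <- nrow(logb); S <- ncol(logb)
  la <- matrix(-Inf, Tn, S)
  la[1, ] <- log_pi + logb[1, ]
  if (Tn > 1) for (t in 2:Tn)
    for (s in seq_len(S))
      la[t, s] <- log_sum_exp(la[t - 1, ] + log_A[, s]) + logb[t, s]
  list(loglik = log_sum_exp(la[Tn, ]), log_alpha = la)
}

lr_hmm_backward <- function(logb, log_A) {
  Tn <- nrow(logb); S <- ncol(logb)
  lb <- matrix(0, Tn, S)
  if (Tn > 1) for (t in (Tn - 1):1)
    for (s in seq_len(S))
      lb[t, s] <- log_sum_exp(log_A[s, ] + logb[t + 1, ] + lb[t + 1, ])
  lb
}

#' Fit a left-to-right Gaussian HMM to feature sequences
#'
#' States may self-transition or advance to the next state only (last state
#' absorbing); the chain starts in state 1. Emissions are diagonal-
#' covariance Gaussians with a variance floor so degenerate (constant)
#' features cannot collapse the model.
#'
#' @param seqs List of T x D feature matrices (one per training sequence).
#' @param n_states Number of states (default 4).
#' @param n_iter Baum-Welch iterations (default 20).
#' @param var_floor Variance floor per feature dimension (recycled;
#'   default 1, i.e. 1 Hz^2 on F0-like features).
#' @return `lr_hmm` model: `means`, `vars` (S x D), `log_A`, `log_pi`,
#'   `loglik_trace` (total training log-likelihood per iteration,
#'   nondecreasing up to the variance floor).
#' @export
fit_lr_hmm <- function(seqs, n_states = 4, n_iter = 20, var_floor = 1) {
  seqs <- lapply(seqs, function(s) {
    if (is.null(dim(s))) s <- matrix(s, ncol = 1)
    as.matrix(s)
  })
  D <- ncol(seqs[[1]])
  var_floor <- rep_len(var_floor, D)
  # init: pool observations by equal-duration segments
  means <- matrix(0, n_states, D); vars <- matrix(1, n_states, D)
  for (s in seq_len(n_states)) {
    seg <- do.call(rbind, lapply(seqs, function(o) {
      Tn <- nrow(o)
      i0 <- floor((s - 1) * Tn / n_states) + 1
      i1 <- floor(s * Tn / n_states)
      o[i0:i1, , drop = FALSE]
    }))
    means[s, ] <- colMeans(seg)
    vars[s, ] <- pmax(apply(seg, 2, stats::var), var_floor)
  }
  vars[!is.finite(vars)] <- var_floor
  A <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states - 1)) A[s, s:(s + 1)] <- c(0.6, 0.4)
  A[n_states, n_states] <- 1
  log_A <- log(A)
  log_pi <- c(0, rep(-Inf, n_states - 1))
  llt <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    num_A <- matrix(0, n_states, n_states)
    den_A <- numeric(n_states)
    sum_g <- matrix(0, n_states, D)
    sum_g2 <- matrix(0, n_states, D)
    cnt_g <- numeric(n_states)
    ll <- 0
    for (o in seqs) {
      logb <- lr_hmm_logb(o, means, vars)
      fw <- lr_hmm_forward(logb, log_pi, log_A)
      lb <- lr_hmm_backward(logb, log_A)
      ll <- ll + fw$loglik
      lg <- fw$log_alpha + lb - fw$loglik
      g <- exp(lg)
      Tn <- nrow(o)
      for (t in seq_len(Tn)) {
        sum_g <- sum_g + g[t, ] %o% o[t, ]
        sum_g2 <- sum_g2 + g[t, ] %o% (o[t, ]^2)
      }
      cnt_g <- cnt_g + colSums(g)
      if (Tn > 1) for (t in seq_len(Tn - 1)) {
        lxi <- outer(fw$log_alpha[t, ], logb[t + 1, ] + lb[t + 1, ], `+`) +
          log_A - fw$loglik
        xi <- exp(lxi)
        num_A <- num_A + xi
        den_A <- den_A + rowSums(xi)
      }
    }
    llt[it] <- ll
    # M-step restricted to the left-to-right support
    for (s in seq_len(n_states - 1)) {
      if (den_A[s] > 0) {
        stay <- num_A[s, s] / den_A[s]
        adv <- num_A[s, s + 1] / den_A[s]
        tot <- stay + adv
        if (tot > 0) {
          A[s, ] <- 0; A[s, s] <- stay / tot; A[s, s + 1] <- adv / tot
        }
      }
    }
    log_A <- log(A)
    ok <- cnt_g > 1e-8
    means[ok, ] <- sum_g[ok, , drop = FALSE] / cnt_g[ok]
    v <- sum_g2[ok, , drop = FALSE] / cnt_g[ok] - means[ok, , drop = FALSE]^2
    vars[ok, ] <- pmax(v, rep(var_floor, each = sum(ok)))
  }
  structure(list(n_states = n_states, means = means, vars = vars,
                 log_A = log_A, log_pi = log_pi, loglik_trace = llt),
            class = "lr_hmm")
}

#' Log-likelihood of a sequence under a fitted left-to-right HMM
#' @param model An `lr_hmm`.
#' @param obs T x D feature matrix.
#' @return Scalar log-likelihood.
#' @export
loglik_lr_hmm <- function(model, obs) {
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 1)
  logb <- lr_hmm_logb(as.matrix(obs), model$means, model$vars)
  lr_hmm_forward(logb, model$log_pi, model$log_A)$loglik
}
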