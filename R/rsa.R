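#' Representational similarity between two confusion matrices
#'
#' Pearson correlation over the 12 off-diagonal cells (the diagonals —
#' raw accuracies — are removed so only the pattern of confusions counts),
#' with a permutation p-value obtained by shuffling the off-diagonal cell
#' assignment of the second matrix.
#'
#' @param cm_a,cm_b Confusion matrices of identical shape.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List: `r`, `p_value`, `n_perm`.
#' @export
rsa_similarity <- function(cm_a, cm_b, n_perm = 10000, seed = 1) {
  a <- as.matrix(cm_a); b <- as.matrix(cm_b)
  if (!all(dim(a) == dim(b))) stop("confusion matrices differ in shape")
  off <- row(a) != col(a)
  va <- a[off]; vb <- b[off]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in off-diagonal cells; similarity undefined")
  r <- stats::cor(va, vb)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stats::cor(va, sample(vb)), numeric(1))
  p <- (1 + sum(abs(null) >= abs(r) - 1e-12)) / (n_perm + 1)
  list(r = r, p_value = p, n_perm = n_perm)
}

# symmetrized confusion dissimilarity between tones within one matrix:
# d(i, j) = 1 - (c_ij + c_ji)/2, diagonal 0
confusion_dissimilarity <- function(cm) {
  c_ <- as.matrix(cm)
  d <- 1 - (c_ + t(c_)) / 2
  diag(d) <- 0
  pmax(d, 0)
}

#' MDS embedding of confusion matrices with Procrustes alignment
#'
#' For each confusion matrix, the four tones are embedded in 2-D by
#' classical MDS of the symmetrized confusion dissimilarity
#' `1 - (c_ij + c_ji)/2` (diagonal removed). Every configuration is then
#' Procrustes-aligned (rotation, scaling, translation) to the first so the
#' confusion spaces of different recording levels/species can be overlaid.
#'
#' @param cms Named list of >= 2 confusion matrices.
#' @param n_perm,seed Passed to [rsa_similarity()] for the pairwise table.
#' @return An `rsa_result`: `coords` (list of aligned 4 x 2 configurations),
#'   `disparity` (symmetric Procrustes sum of squares vs the first
#'   configuration), `pairwise_r` / `pairwise_p` (between-matrix similarity
#'   over off-diagonal cells).
#' @export
mds_procrustes <- function(cms, n_perm = 10000, seed = 1) {
  if (length(cms) < 2) stop("need at least 2 confusion matrices")
  if (is.null(names(cms))) names(cms) <- paste0("cm", seq_along(cms))
  k_target <- 2L
  coords <- lapply(cms, function(cm) {
    d <- confusion_dissimilarity(cm)
    xy <- stats::cmdscale(stats::as.dist(d), k = k_target)
    if (ncol(xy) < k_target) {
      warning("rank-deficient dissimilarity; embedding padded to 2-D")
      xy <- cbind(xy, matrix(0, nrow(xy), k_target - ncol(xy)))
    }
    rownames(xy) <- rownames(as.matrix(cm))
    xy
  })
  ref <- coords[[1]]
  aligned <- coords
  disparity <- numeric(length(coords))
  for (i in seq_along(coords)) {
    pr <- vegan::procrustes(ref, coords[[i]], symmetric = FALSE)
    aligned[[i]] <- pr$Yrot
    disparity[i] <- vegan::procrustes(ref, coords[[i]], symmetric = TRUE)$ss
  }
  names(disparity) <- names(cms)
  n <- length(cms)
  pr_mat <- matrix(NA_real_, n, n, dimnames = list(names(cms), names(cms)))
  pp_mat <- pr_mat
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { pr_mat[i, j] <- 1; next }
    s <- tryCatch(
      rsa_similarity(cms[[i]], cms[[j]], n_perm = n_perm, seed = seed),
      error = function(e) {
        warning("pairwise similarity ", names(cms)[i], "-", names(cms)[j],
                " undefined: ", conditionMessage(e))
        list(r = NA_real_, p_value = NA_real_)
      })
    pr_mat[i, j] <- s$r; pp_mat[i, j] <- s$p_value
  }
  structure(list(coords = aligned, disparity = disparity,
                 pairwise_r = pr_mat, pairwise_p = pp_mat),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat("<rsa_result:", length(x$coords), "aligned MDS configurations>\n")
  cat("Procrustes disparity vs first:\n")
  print(round(x$disparity, 4))
  cat("pairwise off-diagonal correlations:\n")
  print(round(x$pairwise_r, 3))
  invisible(x)
}
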