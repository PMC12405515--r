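# Distribution-level evaluation metrics for generative models, computed on
# embedding sets (any row-wise embedding: built-in features, classifier
# logits, or external encoder output loaded from CSV).

#' Frechet distance between two embedding sets
#'
#' `||m - m'||^2 + Tr(C + C' - 2 (C C')^{1/2})` where m, C are the sample
#' mean and covariance of each set (the FID construction, with the encoder
#' left pluggable). The matrix square root uses a symmetric
#' eigendecomposition of `C^{1/2} C' C^{1/2}`; eigenvalues below zero
#' (numerical noise) are clipped to zero, so the result is deterministic
#' and non-negative up to round-off.
#'
#' @param E,E_prime numeric matrices, rows = embeddings.
#' @param shrinkage ridge added to both covariances (`C + shrinkage * I`);
#'   required when `N <= d` makes the covariances rank-deficient.
#' @return non-negative scalar.
#' @export
frechet_distance <- function(E, E_prime, shrinkage = 0) {
  E <- as.matrix(E); E_prime <- as.matrix(E_prime)
  pd_assert(ncol(E) == ncol(E_prime), "embedding dimensions differ")
  pd_assert(nrow(E) >= 2L && nrow(E_prime) >= 2L, "need N >= 2 per set")
  d <- ncol(E)
  if ((nrow(E) <= d || nrow(E_prime) <= d) && shrinkage <= 0) {
    stop("covariance is rank-deficient (N <= d); pass shrinkage > 0 ",
         "or use more samples / fewer embedding dimensions", call. = FALSE)
  }
  m1 <- colMeans(E); m2 <- colMeans(E_prime)
  C1 <- stats::cov(E) + diag(shrinkage, d)
  C2 <- stats::cov(E_prime) + diag(shrinkage, d)
  e1 <- eigen(C1, symmetric = TRUE)
  s1 <- e1$vectors %*% (sqrt(pmax(e1$values, 0)) * t(e1$vectors))
  mid <- s1 %*% C2 %*% s1
  ev <- eigen((mid + t(mid)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((m1 - m2)^2) + sum(diag(C1)) + sum(diag(C2)) - 2 * tr_sqrt
}

#' Inception-style score from class probabilities
#'
#' `exp(E_x KL(p(y|x) || p(y)))` with the marginal `p(y)` estimated as the
#' column mean of the probability matrix. Lies in `[1, n_classes]`.
#'
#' @param P matrix with one probability row per generated sample.
#' @param n_splits average the score over this many contiguous row splits
#'   (default 1 = no splitting).
#' @return scalar score.
#' @export
inception_score <- function(P, n_splits = 1) {
  P <- as.matrix(P)
  pd_assert(all(abs(rowSums(P) - 1) < 1e-6), "rows of P must sum to 1")
  pd_assert(all(P >= 0), "probabilities must be non-negative")
  one <- function(M) {
    py <- colMeans(M)
    kl <- apply(M, 1L, function(p) {
      nz <- p > 0
      sum(p[nz] * (log(p[nz]) - log(py[nz])))
    })
    exp(mean(kl))
  }
  if (n_splits <= 1L) return(one(P))
  idx <- split(seq_len(nrow(P)), cut(seq_len(nrow(P)), n_splits, labels = FALSE))
  mean(vapply(idx, function(i) one(P[i, , drop = FALSE]), 0))
}

#' Density and coverage of a generated set against a real set
#'
#' k-NN manifold metrics: the real manifold is the union of closed balls
#' `B(E_i, NND_k(E_i))` where `NND_k` is the distance to the k-th nearest
#' neighbour within the real set (self excluded). Density counts, averaged
#' over generated points and divided by k, how many real balls contain
#' each generated point; coverage is the fraction of real points whose
#' ball contains at least one generated point.
#'
#' @param E real embeddings (rows); `nrow(E) > k`.
#' @param E_prime generated embeddings.
#' @param k neighbourhood size (default 5).
#' @return named list `density`, `coverage`.
#' @export
density_coverage <- function(E, E_prime, k = 5) {
  E <- as.matrix(E); E_prime <- as.matrix(E_prime)
  pd_assert(nrow(E) > k, "k must be smaller than the number of real points")
  d_rr <- sqrt(cross_dist2(E, E))
  radii <- apply(d_rr, 1L, function(r) sort(r)[k + 1L])  # k-th NN, self excluded
  d_rg <- sqrt(cross_dist2(E, E_prime))                  # real x generated
  member <- sweep(d_rg, 1L, radii, "<=")
  density <- sum(member) / (k * ncol(member))
  coverage <- mean(apply(member, 1L, any))
  list(density = density, coverage = coverage)
}

#' Unbiased squared maximum mean discrepancy (RBF kernel)
#'
#' The three-term unbiased estimator: within-set kernel means with the
#' diagonal excluded, minus twice the cross-set kernel mean. Kernel is
#' `exp(-||x-y||^2 / (2 h^2))`; by default the bandwidth h is the median
#' pairwise Euclidean distance of the pooled sets (median heuristic).
#'
#' @param E,E_prime embedding matrices with >= 2 rows each.
#' @param bandwidth kernel bandwidth; `NULL` for the median heuristic.
#' @return scalar (can be slightly negative; unbiased estimator).
#' @export
mmd_cmmd <- function(E, E_prime, bandwidth = NULL) {
  E <- as.matrix(E); E_prime <- as.matrix(E_prime)
  m <- nrow(E); n <- nrow(E_prime)
  pd_assert(m >= 2L && n >= 2L, "need at least 2 points per set")
  d2_xx <- cross_dist2(E, E)
  d2_yy <- cross_dist2(E_prime, E_prime)
  d2_xy <- cross_dist2(E, E_prime)
  if (is.null(bandwidth)) {
    pool <- sqrt(c(d2_xx[upper.tri(d2_xx)], d2_yy[upper.tri(d2_yy)], as.vector(d2_xy)))
    bandwidth <- stats::median(pool)
    if (bandwidth == 0) bandwidth <- 1
  }
  pd_assert(bandwidth > 0, "bandwidth must be positive")
  kxx <- exp(-d2_xx / (2 * bandwidth^2)); diag(kxx) <- 0
  kyy <- exp(-d2_yy / (2 * bandwidth^2)); diag(kyy) <- 0
  kxy <- exp(-d2_xy / (2 * bandwidth^2))
  sum(kxx) / (m * (m - 1)) + sum(kyy) / (n * (n - 1)) - 2 * sum(kxy) / (m * n)
}

#' Coefficient of determination
#'
#' `1 - sum((y - g)^2) / sum((y - mean(y))^2)`. Negative values occur when
#' the prediction fits worse than the ground-truth mean.
#'
#' @param y ground-truth vector (non-constant, length >= 2).
#' @param g predicted vector of equal length.
#' @return scalar R squared.
#' @export
r2_score <- function(y, g) {
  pd_assert(length(y) == length(g) && length(y) >= 2L, "equal lengths >= 2 required")
  pd_assert(all(is.finite(y)) && all(is.finite(g)), "non-finite inputs")
  s_tot <- sum((y - mean(y))^2)
  pd_assert(s_tot > 0, "R^2 undefined for constant ground truth")
  1 - sum((y - g)^2) / s_tot
}

#' Pearson correlation with strict degenerate-input handling
#'
#' @param x,y equal-length numeric vectors, both non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  pd_assert(length(x) == length(y) && length(x) >= 2L, "equal lengths >= 2 required")
  pd_assert(stats::sd(x) > 0 && stats::sd(y) > 0, "correlation undefined for constant input")
  stats::cor(x, y)
}

#' F1 agreement between significance flag vectors
#'
#' Treats the ground-truth-derived flags as the positive labels and the
#' generated-derived flags as predictions; returns
#' `2 TP / (2 TP + FP + FN)`. When neither vector has a positive the score
#' is defined as 1 (with a warning): both analyses agree that nothing
#' changed.
#'
#' @param gt_flags,gen_flags equal-length logical vectors.
#' @return scalar in `[0, 1]`.
#' @export
f1_significant <- function(gt_flags, gen_flags) {
  pd_assert(length(gt_flags) == length(gen_flags), "flag vectors must have equal length")
  gt <- as.logical(gt_flags); gen <- as.logical(gen_flags)
  tp <- sum(gt & gen); fp <- sum(!gt & gen); fn <- sum(gt & !gen)
  if (tp + fp + fn == 0L) {
    warning("no positives in either flag vector; F1 defined as 1")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}
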