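#' Nearest-neighbor weighted bootstrap augmentation
#'
#' Generates synthetic feature vectors for a class by convex combination of
#' randomly chosen seed points with their nearest neighbors, the resampling
#' scheme used to balance unequal trial counts before classifier training.
#' For each synthetic sample a seed point \eqn{x_{k_0}} is drawn uniformly,
#' its \eqn{r} Euclidean nearest neighbors \eqn{x_{k_1},\dots,x_{k_r}} are
#' located, non-negative coefficients \eqn{c_0,\dots,c_r} are drawn from a
#' folded Gaussian and clipped to \eqn{[0, r]}, and the sample is
#' \eqn{\sum_{i=0}^r w_i x_{k_i}} with \eqn{w_i = c_i / \sum_d c_d}. Every
#' generated sample therefore lies in the convex hull of its neighborhood.
#'
#' @param x Numeric matrix, one row per original sample of the class.
#' @param n_target Number of synthetic samples to generate.
#' @param r Neighbor count (default 5).
#' @param gaussian_mu,gaussian_sigma Location and scale of the Gaussian the
#'   mixing coefficients are drawn from (folded to non-negative, then
#'   clipped at `r`).
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return List with `samples` (`n_target` x `ncol(x)` matrix) and
#'   `seed_index` (which original row seeded each sample).
#' @export
neighbor_bootstrap <- function(x, n_target, r = 5, gaussian_mu = 0,
                               gaussian_sigma = 1, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (r < 1) stop("`r` must be >= 1")
  if (n_target < 1) stop("`n_target` must be >= 1")
  if (gaussian_sigma <= 0) stop("`gaussian_sigma` must be > 0")
  if (n < r + 1)
    stop(sprintf("need at least r + 1 = %d samples in the class, got %d",
                 r + 1, n))
  d2 <- as.matrix(stats::dist(x))^2
  with_seed(seed, {
    out <- matrix(0, n_target, ncol(x))
    seed_idx <- integer(n_target)
    for (s in seq_len(n_target)) {
      k0 <- sample.int(n, 1L)
      nb <- order(d2[k0, ])
      nb <- setdiff(nb, k0)[seq_len(r)]
      idx <- c(k0, nb)
      repeat {
        ci <- pmin(abs(stats::rnorm(r + 1, gaussian_mu, gaussian_sigma)), r)
        if (sum(ci) > 0) break
      }
      w <- ci / sum(ci)
      out[s, ] <- as.numeric(w %*% x[idx, , drop = FALSE])
      seed_idx[s] <- k0
    }
    colnames(out) <- colnames(x)
    list(samples = out, seed_index = seed_idx)
  })
}

#' Stratified k-fold cross-validation split
#'
#' Partitions `n` indices into `k` disjoint test folds whose sizes differ by
#' at most one; when `labels` are given the split is stratified so that each
#' fold's per-class counts also differ by at most one, which stabilizes
#' 10-fold evaluation on the unbalanced trial counts typical of patient
#' sessions.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param labels Optional class labels of length `n` for stratification.
#' @param seed Optional integer seed for the shuffle.
#' @return List of `k` integer vectors of test indices.
#' @export
kfold_split <- function(n, k = 10, labels = NULL, seed = NULL) {
  if (n < k) stop(sprintf("cannot split n = %d samples into k = %d folds", n, k))
  if (k < 2) stop("`k` must be >= 2")
  with_seed(seed, {
    fold_of <- integer(n)
    if (is.null(labels)) {
      fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      stopifnot(length(labels) == n)
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        # contiguous cyclic run keeps overall fold sizes within one of
        # each other across classes
        fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    }
    lapply(seq_len(k), function(f) which(fold_of == f))
  })
}

#' Cross-validation error (mean squared error)
#'
#' \eqn{(1/N) \sum_p (d_p - y_p)^2} between desired and obtained classifier
#' outputs; zero iff they agree exactly.
#'
#' @param desired,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
cv_error <- function(desired, predicted) {
  if (length(desired) != length(predicted))
    stop("`desired` and `predicted` must have equal length")
  if (length(desired) < 1) stop("empty input")
  mean((desired - predicted)^2)
}
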