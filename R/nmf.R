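# Nonnegative matrix factorization by multiplicative Frobenius updates
# (Lee-Seung). Small dense problems only: the binding-signal matrices here
# are (sites x factors) with a handful of columns.

#' Nonnegative matrix factorization of a binding-signal matrix
#'
#' Factorizes a nonnegative site-by-factor signal matrix V into nonnegative
#' W (sites x rank) and H (rank x factors) minimizing the Frobenius error
#' ||V - WH||_F via multiplicative updates, which never increase the error.
#' Initialization is nonnegative-random and seeded, so results are
#' deterministic given the seed.
#'
#' @param V nonnegative numeric matrix (sites x factors).
#' @param rank factorization rank, `0 < rank < min(dim(V))` recommended;
#'   must be positive and at most `min(dim(V))`.
#' @param maxIter maximum number of update sweeps.
#' @param tol stop when the relative error improvement per sweep falls
#'   below this value.
#' @param seed RNG seed for the initialization.
#' @param nStart number of random restarts; the best (lowest final error)
#'   run is returned.
#' @return an [NMFResult-class].
#' @export
nmfBinding <- function(V, rank, maxIter = 2000, tol = 1e-10, seed = 1,
                       nStart = 1) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (rank <= 0) stop("rank must be positive")
  if (rank > min(dim(V))) stop("rank must not exceed min(dim(V))")
  eps <- .Machine$double.eps
  best <- NULL
  for (s in seq_len(nStart)) {
    set.seed(seed + s - 1L)
    W <- matrix(runif(nrow(V) * rank, 0.1, 1), nrow(V), rank) * sqrt(mean(V) / rank)
    H <- matrix(runif(rank * ncol(V), 0.1, 1), rank, ncol(V)) * sqrt(mean(V) / rank)
    errs <- numeric(maxIter)
    prev <- Inf
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H, H) + eps))
      err <- sqrt(sum((V - W %*% H)^2))
      errs[it] <- err
      if (is.finite(prev) && prev - err < tol * max(prev, eps)) break
      prev <- err
    }
    res <- new("NMFResult", basis = W, coefficients = H,
               rank = as.integer(rank), errorTrace = errs[seq_len(it)])
    if (is.null(best) || reconstructionError(res) < reconstructionError(best))
      best <- res
  }
  best
}
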