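## Surrogate variants from a kernel via eigendecomposition (SVD of the
## implicit transformed-variant matrix).

#' Extract surrogate variants from a kernel
#'
#' Eigendecomposes `K = U D^2 U'` and returns `X* = U D` over the
#' components with materially nonzero eigenvalue, so that
#' `X* X*' = K` (after clipping) when `df` is `"full"`.  The columns are
#' orthogonal surrogate variants for the unknown transformed variants
#' underlying the kernel; truncating to `df < full` keeps the leading
#' `df` components.
#'
#' Column signs are fixed deterministically (largest-magnitude entry
#' positive); the sign is irrelevant to every downstream gram matrix and
#' test statistic, which is asserted in the test suite.
#'
#' @param K a [Kernel-class] or plain symmetric PSD matrix.
#' @param df `"full"` (all components with eigenvalue above tolerance) or
#'   a positive integer no larger than the number of surviving
#'   components.
#' @param tol relative eigenvalue tolerance: components with
#'   `lambda <= tol * lambda_max` are treated as exactly zero.
#' @return a [SurrogateVariants-class].
#' @export
extractSurrogates <- function(K, df = "full", tol = 1e-10) {
  if (is(K, "Kernel")) { v <- values(K); lab <- K@measure }
  else { v <- as.matrix(K); lab <- "user" }
  n <- nrow(v)
  e <- eigen(v, symmetric = TRUE)
  lam <- e$values
  lmax <- max(lam, 0)
  keep <- which(lam > tol * lmax)
  if (lmax <= 0 || length(keep) == 0)
    stop("kernel is numerically zero: no surviving component")
  if (!identical(df, "full")) {
    df <- as.integer(df)
    if (df < 1L) stop("df must be >= 1")
    if (df > length(keep))
      stop(sprintf("df = %d exceeds the %d surviving components",
                   df, length(keep)))
    keep <- keep[seq_len(df)]
  }
  d <- sqrt(lam[keep])
  X <- e$vectors[, keep, drop = FALSE] %*% diag(d, length(keep))
  ## deterministic sign: largest-|entry| of each column made positive
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(v)
  new("SurrogateVariants", scores = X, singularValues = d, measure = lab)
}

#' @describeIn extractSurrogates surrogates straight from a distance
#'   matrix: Gower double-centering of the squared distances and a single
#'   eigendecomposition, keeping the components with positive eigenvalue
#'   (identical to `extractSurrogates(distanceToKernel(D))`, without
#'   reconstructing the intermediate kernel).
#' @param D a [DistanceMatrix-class] or plain symmetric zero-diagonal
#'   matrix.
#' @export
distanceToSurrogates <- function(D, df = "full", tol = 1e-10) {
  if (is(D, "DistanceMatrix")) { v <- values(D); lab <- D@measure }
  else { v <- as.matrix(D); lab <- "user" }
  A <- -0.5 * v^2
  K <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  sv <- extractSurrogates((K + t(K)) / 2, df = df, tol = tol)
  sv@measure <- lab
  sv
}
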