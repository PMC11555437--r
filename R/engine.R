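## Permutation score-test engine: endogenous kernels, quadratic-form
## statistics over a shared permutation plan, and the rank-based
## calibrations (per-kernel min-P and the two-level omnibus).

#' Build the three endogenous kernels
#'
#' From surrogate variants `X*` and a treatment vector `T`:
#' `K^M = X* X*'` (main), `K^I = (X* . T)(X* . T)'` (interaction, `.` the
#' row-wise Hadamard product, so `K^I_ij = T_i T_j K^M_ij`), and
#' `K^B = K^M + K^I`, which equals the gram matrix of the concatenation
#' `(X* | X* . T)` exactly.
#'
#' @param X a [SurrogateVariants-class] or an n x df matrix.
#' @param treat length-n treatment vector.
#' @return `list(M =, I =, B =)` of n x n PSD matrices.
#' @export
buildEndogenousKernels <- function(X, treat) {
  if (is(X, "SurrogateVariants")) X <- scores(X)
  if (nrow(X) != length(treat)) stop("treatment length mismatch")
  KM <- tcrossprod(X)
  KI <- tcrossprod(X * treat)
  list(M = KM, I = KI, B = KM + KI)
}

#' Variance-component score statistic
#'
#' The quadratic form `r' K r` of null-model residuals `r` against an
#' endogenous kernel; nonnegative for PSD `K`, and an estimate of the sum
#' of squared (main, interaction, or both) surrogate-variant effects.
#'
#' @param r residual vector.
#' @param K n x n matrix.
#' @return a scalar.
#' @export
scoreStatistic <- function(r, K) {
  if (length(r) != nrow(K) || nrow(K) != ncol(K))
    stop("dimension mismatch")
  drop(crossprod(r, K %*% r))
}

#' Shared permutation plan
#'
#' One plan of `R` rearrangements of `1..n` is generated per analysis and
#' reused by every statistic and every kernel, which is what lets the
#' min-P nulls capture the dependence among the component tests.
#'
#' @param n number of samples.
#' @param R number of rearrangements (ignored when `exhaustive`).
#' @param seed optional integer seed.
#' @param exhaustive enumerate all `n!` permutations (small n only).
#' @return list with `n`, `R`, `seed` and the n x R index matrix `perms`.
#' @export
permutationPlan <- function(n, R = 3000L, seed = NULL,
                            exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration is limited to n <= 8")
    perms <- .allPerms(n)
  } else {
    if (R < 1L) stop("R must be >= 1")
    perms <- vapply(seq_len(R), function(i) sample.int(n), integer(n))
  }
  list(n = n, R = ncol(perms),
       seed = if (is.null(seed)) NA_integer_ else seed, perms = perms)
}

.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    top <- sub[seq_len(pos - 1L), , drop = FALSE]
    bot <- if (pos <= n - 1L) sub[pos:(n - 1L), , drop = FALSE]
           else sub[0L, , drop = FALSE]
    rbind(top, matrix(n, 1L, ncol(sub)), bot)
  })
  do.call(cbind, cols)
}

#' Empirical permutation p-value
#'
#' `P = (1 + sum_r 1[T(r) >= T(obs)]) / (R + 1)` for statistics where
#' large values are extreme (`direction = "geq"`), or with `<=` for
#' min-P statistics where small values are extreme.  The observed
#' arrangement counts as one of the rearrangements (the exchangeable
#' convention), so the smallest attainable p-value is `1/(R+1)` and the
#' p-value is exactly uniform under the null, which the nested min-P
#' recalibrations rely on.
#'
#' @param observed observed statistic.
#' @param null vector of null statistics.
#' @param direction `"geq"` or `"leq"`.
#' @return p-value in `(0, 1]`.
#' @export
empiricalPValue <- function(observed, null, direction = c("geq", "leq")) {
  direction <- match.arg(direction)
  k <- if (direction == "geq") sum(null >= observed)
       else sum(null <= observed)
  (1 + k) / (length(null) + 1)
}

#' Pooled within-set p-values
#'
#' Pools the observed statistic with the `R` permutation statistics and
#' converts every element to its p-value within the pooled set of
#' `R + 1` values (self included):
#' `P(x) = #\{z in pool: z >= x\} / (R + 1)` for `direction = "geq"`.
#' The first returned element is the observed statistic's p-value and
#' equals [empiricalPValue()]; the rest are the permutation null
#' p-values on the identical footing, which is what makes the min-P
#' statistics and their permutation nulls exchangeable.
#'
#' @param observed observed statistic.
#' @param null vector of R null statistics.
#' @param direction `"geq"` (score statistics) or `"leq"` (min-P
#'   statistics).
#' @return vector of R + 1 p-values, observed first.
#' @export
pooledPValues <- function(observed, null, direction = c("geq", "leq")) {
  direction <- match.arg(direction)
  v <- c(observed, null)
  m <- length(v)
  if (direction == "geq") {
    (m + 1 - rank(v, ties.method = "min")) / m
  } else {
    rank(v, ties.method = "max") / m
  }
}

## ---------------------------------------------------------------------------
## Internal fast paths.
## ---------------------------------------------------------------------------

## Observed + null score statistics for a list of surrogate-score
## matrices, all sharing one permuted-residual matrix.  Equivalent to
## r' K r with K the endogenous kernels, but computed as squared column
## norms of X*' r: r' (X X') r = ||X' r||^2.
.engineStats <- function(Xlist, treat, resid, permIdx) {
  n <- length(resid)
  Rmat <- matrix(resid[permIdx], nrow = n)
  lapply(Xlist, function(X) {
    XT <- X * treat
    obsM <- sum(crossprod(X, resid)^2)
    obsI <- sum(crossprod(XT, resid)^2)
    nullM <- colSums(crossprod(X, Rmat)^2)
    nullI <- colSums(crossprod(XT, Rmat)^2)
    list(obs = c(M = obsM, I = obsI, B = obsM + obsI),
         null = cbind(M = nullM, I = nullI, B = nullM + nullI))
  })
}

## Per-kernel calibration.  All R + 1 arrangements (observed first) are
## converted to pooled p-values per endogenous target; the min-P
## statistic is the per-arrangement minimum over the three targets and
## its p-value is the proportion of arrangements at least as extreme.
.calibrateKernel <- function(st) {
  R <- nrow(st$null)
  pAll <- vapply(1:3,
                 function(k) pooledPValues(st$obs[k], st$null[, k]),
                 numeric(R + 1))
  colnames(pAll) <- c("M", "I", "B")
  p <- pAll[1, ]
  minAll <- pmin(pAll[, 1], pAll[, 2], pAll[, 3])
  minP <- minAll[1]
  list(p = p, pNull = pAll[-1, , drop = FALSE], minP = minP,
       minPNull = minAll[-1], pKernel = mean(minAll <= minP))
}

## Two-level omnibus across kernels from per-kernel calibrations: the
## per-arrangement minima over kernels are recalibrated per target, and
## the per-arrangement minima of those rank transforms give the overall
## p-value.  The observed arrangement stays element 1 throughout.
.calibrateOmnibus <- function(calibs) {
  R <- nrow(calibs[[1]]$pNull)
  omniAll <- sapply(c("M", "I", "B"), function(k) {
    do.call(pmin, lapply(calibs, function(cl) c(cl$p[k], cl$pNull[, k])))
  })                                                  # (R + 1) x 3
  tOmni <- omniAll[1, ]
  pOmni <- vapply(1:3, function(k) mean(omniAll[, k] <= omniAll[1, k]),
                  numeric(1))
  names(pOmni) <- names(tOmni) <- c("M", "I", "B")
  q <- vapply(1:3,
              function(k) rank(omniAll[, k],
                               ties.method = "max") / (R + 1),
              numeric(R + 1))
  overallAll <- pmin(q[, 1], q[, 2], q[, 3])
  tOverall <- unname(overallAll[1])  # equals min(pOmni) by construction
  pOverall <- mean(overallAll <= tOverall)
  list(tOmnibus = tOmni, pOmnibus = pOmni, omniNull = omniAll[-1, ],
       tOverall = tOverall, pOverall = pOverall)
}

## ---------------------------------------------------------------------------
## Public single-kernel test.
## ---------------------------------------------------------------------------

#' Association test for one input kernel
#'
#' Runs the permutation variance-component score tests for the three
#' endogenous kernels built from one input kernel, and combines them by
#' the min-P statistic calibrated against its own permutation null.
#'
#' @param K a [Kernel-class] (or PSD matrix).
#' @param meta a [SampleMetadata-class] aligned to the kernel rows.
#' @param plan a [permutationPlan()]; created from `nPerm`/`seed` when
#'   omitted.
#' @param df `"full"` or integer; see [extractSurrogates()].
#' @param nPerm,seed used when `plan` is `NULL`.
#' @return a [SingleKernelResult-class].
#' @export
testSingleKernel <- function(K, meta, plan = NULL, df = "full",
                             nPerm = 3000L, seed = NULL) {
  fit <- fitNullModel(meta)
  n <- length(fit$residuals)
  if (is.null(plan)) plan <- permutationPlan(n, nPerm, seed)
  sv <- extractSurrogates(K, df = df)
  st <- .engineStats(list(scores(sv)), meta@treatment, fit$residuals,
                     plan$perms)[[1]]
  cal <- .calibrateKernel(st)
  lab <- if (is(K, "Kernel")) K@measure else "user"
  alpha <- if (is(K, "Kernel")) K@alpha else NA_real_
  new("SingleKernelResult", measure = lab, alpha = as.numeric(alpha),
      statObs = st$obs, statNull = st$null, p = cal$p, pNull = cal$pNull,
      minP = cal$minP, minPNull = cal$minPNull, pKernel = cal$pKernel)
}
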