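# Naive reference implementation, written as literal loops over the
# defining counts, used to check the vectorized engine.
#
# Two stages, checked at different strictness:
#  - oracleStats recomputes the observed/null quadratic-form statistics
#    from scratch (clipped kernel, elementwise r'Kr); compared to the
#    engine at floating-point tolerance.
#  - oracleCalibrate runs the whole p-value pipeline by brute force on a
#    given set of statistic arrays, under the pooled convention (the
#    observed arrangement is one of the R + 1 arrangements at every
#    level).  When fed the engine's own arrays the comparison is exact:
#    the rank arithmetic must agree on ties, where in-theory-equal
#    statistics differ only by float noise.

oracleClipKernel <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
}

oracleQuadForm <- function(r, K) {
  s <- 0
  for (i in seq_along(r)) for (j in seq_along(r))
    s <- s + r[i] * K[i, j] * r[j]
  s
}

# kernels: list of raw input kernel matrices; perms: n x R indices
oracleStats <- function(kernels, resid, treat, perms) {
  R <- ncol(perms)
  lapply(kernels, function(K) {
    KM <- oracleClipKernel(K)
    KI <- outer(treat, treat) * KM
    EK <- list(M = KM, I = KI, B = KM + KI)
    obs <- vapply(EK, function(Kk) oracleQuadForm(unname(resid), Kk),
                  numeric(1))
    null <- matrix(0, R, 3, dimnames = list(NULL, c("M", "I", "B")))
    for (r in seq_len(R)) {
      rp <- resid[perms[, r]]
      null[r, ] <- sapply(EK, function(Kk) oracleQuadForm(rp, Kk))
    }
    list(obs = obs, null = null)
  })
}

# stats: list per kernel of list(obs = numeric(3), null = R x 3).
# Arrangement 1 is the observed one; arrangements 2..R+1 are the
# permutations.
oracleCalibrate <- function(stats) {
  R <- nrow(stats[[1]]$null)
  M <- R + 1
  perKernel <- lapply(stats, function(st) {
    # pooled p-value of every arrangement, per endogenous target
    pAll <- matrix(0, M, 3, dimnames = list(NULL, c("M", "I", "B")))
    for (k in 1:3) {
      pool <- c(st$obs[k], st$null[, k])
      for (a in seq_len(M)) {
        cnt <- 0
        for (b in seq_len(M)) if (pool[b] >= pool[a]) cnt <- cnt + 1
        pAll[a, k] <- cnt / M
      }
    }
    minAll <- apply(pAll, 1, min)
    cnt <- 0
    for (a in seq_len(M)) if (minAll[a] <= minAll[1]) cnt <- cnt + 1
    list(p = pAll[1, ], pNull = pAll[-1, , drop = FALSE],
         minP = minAll[1], minPNull = minAll[-1], pKernel = cnt / M)
  })
  # omnibus across kernels, per endogenous target
  omniAll <- matrix(0, M, 3, dimnames = list(NULL, c("M", "I", "B")))
  for (k in 1:3) for (a in seq_len(M))
    omniAll[a, k] <- min(sapply(perKernel, function(z)
      if (a == 1) z$p[k] else z$pNull[a - 1, k]))
  tOmni <- omniAll[1, ]
  pOmni <- numeric(3); names(pOmni) <- names(tOmni) <- c("M", "I", "B")
  for (k in 1:3) {
    cnt <- 0
    for (a in seq_len(M)) if (omniAll[a, k] <= omniAll[1, k])
      cnt <- cnt + 1
    pOmni[k] <- cnt / M
  }
  # overall: rank-transform each target's omnibus minima within the
  # pooled set (<= direction), take per-arrangement minima, compare
  q <- matrix(0, M, 3)
  for (k in 1:3) for (a in seq_len(M)) {
    cnt <- 0
    for (b in seq_len(M)) if (omniAll[b, k] <= omniAll[a, k])
      cnt <- cnt + 1
    q[a, k] <- cnt / M
  }
  overallAll <- apply(q, 1, min)
  cnt <- 0
  for (a in seq_len(M)) if (overallAll[a] <= overallAll[1])
    cnt <- cnt + 1
  list(perKernel = perKernel, tOmni = tOmni, pOmni = pOmni,
       omniNull = omniAll[-1, ], tOverall = overallAll[1],
       pOverall = cnt / M)
}

# Engine statistic arrays extracted from an OmniKResult, in oracle form.
engineStatArrays <- function(result) {
  lapply(result@results, function(r) list(obs = r@statObs,
                                          null = r@statNull))
}
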