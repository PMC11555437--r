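## Comparison combiners: Fisher, Brown, Simes on the per-kernel
## endogenous permutation p-values.  These are the naive alternatives to
## the min-P recalibration; under dependence Fisher and Simes inflate the
## family-wise error, which the simulation harness demonstrates.

#' Combine dependent p-values (Fisher / Brown / Simes)
#'
#' Combines a vector of p-values into one.  `fisher`:
#' `X2 = -2 sum log p` against chi-square with `2m` df.  `simes`:
#' `min_k m p_(k) / k`.  `brown`: Fisher's statistic against a scaled
#' chi-square whose scale and df are moment-matched using the covariance
#' of `-2 log p` estimated empirically from a permutation-null p-value
#' matrix (`nullP`, one row per permutation, one column per test).
#'
#' P-values of exactly 0 (impossible for the package's own pooled
#' permutation p-values, whose floor is `1/(R+1)`, but possible for
#' user-supplied ones) are clamped to `pMin` with a warning before
#' taking logs.
#'
#' @param p vector of `m >= 2` p-values.
#' @param method `"fisher"`, `"brown"` or `"simes"`.
#' @param nullP R x m matrix of null p-values (required for `brown`).
#' @param pMin clamp value for zero p-values (use `1/R`).
#' @return list with `method`, `p` (combined), and the inputs, classed
#'   `"omnikCombined"`.
#' @export
combinePValues <- function(p, method = c("fisher", "brown", "simes"),
                           nullP = NULL, pMin = NULL) {
  method <- match.arg(method)
  m <- length(p)
  if (m < 2L) stop("need at least 2 p-values")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (any(p == 0)) {
    if (is.null(pMin))
      stop("p-value of 0 requires pMin (use 1/R) to clamp")
    warning("p-value of 0 clamped to pMin = ", pMin, call. = FALSE)
    p <- pmax(p, pMin)
  }
  comb <- switch(method,
    fisher = {
      X2 <- -2 * sum(log(p))
      pchisq(X2, df = 2 * m, lower.tail = FALSE)
    },
    simes = {
      ps <- sort(p)
      min(1, min(m * ps / seq_len(m)))
    },
    brown = {
      if (is.null(nullP)) stop("brown requires a null p-value matrix")
      if (!is.null(pMin)) nullP <- pmax(nullP, pMin)
      if (any(nullP <= 0)) stop("null p-values must be positive (clamp with pMin)")
      X2 <- -2 * sum(log(p))
      S <- cov(-2 * log(nullP))
      EX <- 2 * m
      VX <- sum(S)
      cc <- VX / (2 * EX)
      dfB <- 2 * EX^2 / VX
      pchisq(X2 / cc, df = dfB, lower.tail = FALSE)
    })
  structure(list(method = method, p = comb, inputs = p),
            class = "omnikCombined")
}

#' @export
print.omnikCombined <- function(x, ...) {
  cat(sprintf("%s combination of %d p-values: p = %.4g\n",
              x$method, length(x$inputs), x$p))
  invisible(x)
}

#' Apply the comparison combiners to an OmniK result
#'
#' Combines the same `3 x |Gamma|` endogenous-by-input-kernel permutation
#' p-values that feed the min-P omnibus, so the comparison is
#' like-for-like.  Brown's covariance comes from the cached permutation
#' null p-value matrices.
#'
#' @param result an [OmniKResult-class].
#' @param methods subset of `c("fisher", "brown", "simes")`.
#' @return named numeric vector of combined p-values.
#' @export
altCombine <- function(result, methods = c("fisher", "brown", "simes")) {
  p <- unlist(lapply(result@results, function(r) r@p))
  nullP <- do.call(cbind, lapply(result@results, function(r) r@pNull))
  pMin <- 1 / result@R
  vapply(methods, function(mth)
    suppressWarnings(
      combinePValues(p, mth, nullP = nullP, pMin = pMin)$p),
    numeric(1))
}
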