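## Null model: response on treatment and covariates only.

#' Fit the null regression model
#'
#' Fits `y ~ 1 + T + Z` by ordinary least squares (gaussian) or
#' maximum-likelihood logistic regression (binomial).  The score tests
#' permute the response residuals `y - yhat0` of this fit; under either
#' family the alternative-model effect terms are never fitted.
#'
#' @param meta a [SampleMetadata-class].
#' @return a list with `family`, `coefficients`, `fitted`, `residuals`
#'   and the `design` matrix, classed `"omnikNullFit"`.
#' @export
fitNullModel <- function(meta) {
  stopifnot(is(meta, "SampleMetadata"))
  y <- meta@response
  X <- cbind(`(Intercept)` = 1, treatment = meta@treatment,
             meta@covariates)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient null design matrix")
  if (meta@family == "gaussian") {
    fit <- lm.fit(X, y)
    fitted <- drop(X %*% fit$coefficients)
  } else {
    if (length(unique(y)) < 2L) stop("degenerate response")
    fit <- glm.fit(X, y, family = binomial())
    if (!fit$converged) stop("logistic null model did not converge")
    if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
      stop("perfect or quasi-perfect separation in the null model")
    fitted <- fit$fitted.values
  }
  structure(list(family = meta@family, coefficients = fit$coefficients,
                 fitted = fitted, residuals = y - fitted, design = X),
            class = "omnikNullFit")
}

#' @export
print.omnikNullFit <- function(x, ...) {
  cat("Null model fit (", x$family, "), n = ", length(x$fitted), "\n",
      sep = "")
  print(x$coefficients)
  invisible(x)
}
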