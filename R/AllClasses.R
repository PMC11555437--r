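#' @useDynLib OmniK, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cov glm.fit lm.fit pchisq rbinom rgamma rmultinom rnorm
#'   runif sd binomial ks.test
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## CountTable: n samples x p taxa nonnegative counts, samples in rows.
## ---------------------------------------------------------------------------

#' Sample-by-taxon count table
#'
#' An S4 container for a microbiome (or any variant) count matrix with
#' samples in rows and taxa in columns.  Validity enforces nonnegative,
#' non-missing counts, unique sample and taxon identifiers, at least two
#' samples and two taxa, and strictly positive row sums (every sample must
#' have been observed at least once).
#'
#' @slot counts numeric matrix of nonnegative counts, `dimnames` carrying
#'   sample ids (rows) and taxon ids (columns).
#'
#' @seealso [countTable()], [readCountTable()]
#' @export
setClass("CountTable", representation(counts = "matrix"))

setValidity("CountTable", function(object) {
  x <- object@counts
  msg <- character()
  if (!is.numeric(x)) msg <- c(msg, "counts must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "counts must carry sample ids (rownames) and taxon ids (colnames)")
  if (anyNA(x)) msg <- c(msg, "missing values in counts")
  else if (any(x < 0)) msg <- c(msg, "negative counts")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    msg <- c(msg, sprintf("duplicate sample id: %s",
                          rownames(x)[anyDuplicated(rownames(x))]))
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    msg <- c(msg, sprintf("duplicate taxon id: %s",
                          colnames(x)[anyDuplicated(colnames(x))]))
  if (nrow(x) < 2L || ncol(x) < 2L)
    msg <- c(msg, "need at least 2 samples and 2 taxa")
  if (is.numeric(x) && !anyNA(x) && any(rowSums(x) <= 0))
    msg <- c(msg, "sample with all-zero counts")
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of nonnegative counts.
#' @param sampleIDs,taxonIDs optional ids; taken from `dimnames(counts)`
#'   when omitted.
#' @param taxaAreRows set to `TRUE` when `counts` arrives taxa-in-rows
#'   (the common QIIME export orientation); it is transposed so that the
#'   stored matrix is always samples-in-rows.
#' @return a [CountTable-class] object.
#' @export
countTable <- function(counts, sampleIDs = NULL, taxonIDs = NULL,
                       taxaAreRows = FALSE) {
  counts <- as.matrix(counts)
  if (taxaAreRows) counts <- t(counts)
  if (!is.null(sampleIDs)) rownames(counts) <- sampleIDs
  if (!is.null(taxonIDs)) colnames(counts) <- taxonIDs
  new("CountTable", counts = counts)
}

#' @describeIn countTable extract the count matrix (samples in rows).
#' @param x a `CountTable`.
#' @export
countData <- function(x) x@counts

#' @describeIn countTable sample identifiers.
#' @export
sampleIDs <- function(x) {
  if (is(x, "CountTable")) rownames(x@counts) else x@sampleIDs
}

#' @describeIn countTable taxon identifiers.
#' @export
taxonIDs <- function(x) colnames(x@counts)

setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@counts), "samples x",
      ncol(object@counts), "taxa\n")
  cat("  total counts per sample:",
      paste(range(rowSums(object@counts)), collapse = " - "), "\n")
})

## ---------------------------------------------------------------------------
## SampleMetadata: response, treatment, covariates.
## ---------------------------------------------------------------------------

#' Sample metadata: response, treatment and covariates
#'
#' Holds the regression variables aligned to the samples of a
#' [CountTable-class]: a response `y` (continuous, or 0/1 for the binomial
#' family), a treatment `T` (typically 0/1), and an optional covariate
#' matrix `Z`.  No missing values are allowed.
#'
#' @slot sampleIDs character vector of sample ids.
#' @slot response numeric response vector.
#' @slot treatment numeric treatment vector.
#' @slot covariates numeric covariate matrix (0 columns when none).
#' @slot family `"gaussian"` or `"binomial"`.
#' @export
setClass("SampleMetadata",
         representation(sampleIDs = "character", response = "numeric",
                        treatment = "numeric", covariates = "matrix",
                        family = "character"))

setValidity("SampleMetadata", function(object) {
  n <- length(object@sampleIDs)
  msg <- character()
  if (anyDuplicated(object@sampleIDs)) msg <- c(msg, "duplicate sample id")
  if (length(object@response) != n) msg <- c(msg, "response length mismatch")
  if (length(object@treatment) != n) msg <- c(msg, "treatment length mismatch")
  if (nrow(object@covariates) != n) msg <- c(msg, "covariate row mismatch")
  if (anyNA(object@response) || anyNA(object@treatment) ||
      anyNA(object@covariates))
    msg <- c(msg, "missing values in metadata")
  if (!object@family %in% c("gaussian", "binomial"))
    msg <- c(msg, "family must be 'gaussian' or 'binomial'")
  if (object@family == "binomial" && !all(object@response %in% c(0, 1)))
    msg <- c(msg, "binomial response must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct SampleMetadata
#'
#' @param response numeric response vector (0/1 for `family = "binomial"`).
#' @param treatment numeric treatment vector (typically 0/1).
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param family `"gaussian"` or `"binomial"`.
#' @param sampleIDs sample ids; defaults to `names(response)` or `1..n`.
#' @return a [SampleMetadata-class] object.
#' @export
sampleMetadata <- function(response, treatment, covariates = NULL,
                           family = c("gaussian", "binomial"),
                           sampleIDs = NULL) {
  family <- match.arg(family)
  n <- length(response)
  if (is.null(sampleIDs))
    sampleIDs <- if (!is.null(names(response))) names(response)
                 else as.character(seq_len(n))
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
  }
  rownames(covariates) <- sampleIDs
  new("SampleMetadata", sampleIDs = as.character(sampleIDs),
      response = as.numeric(response), treatment = as.numeric(treatment),
      covariates = covariates, family = family)
}

#' @describeIn sampleMetadata the response vector.
#' @param x a `SampleMetadata`.
#' @export
response <- function(x) x@response

#' @describeIn sampleMetadata the treatment vector.
#' @export
treatment <- function(x) x@treatment

#' @describeIn sampleMetadata the covariate matrix.
#' @export
covariates <- function(x) x@covariates

setMethod("show", "SampleMetadata", function(object) {
  cat("SampleMetadata:", length(object@sampleIDs), "samples,",
      ncol(object@covariates), "covariates, family =", object@family, "\n")
})

## ---------------------------------------------------------------------------
## DistanceMatrix and Kernel.
## ---------------------------------------------------------------------------

#' Ecological distance matrix
#'
#' A symmetric, zero-diagonal, nonnegative matrix of pairwise
#' beta-diversity distances/dissimilarities between samples, labelled by
#' the measure that produced it.
#'
#' @slot values n x n numeric matrix.
#' @slot measure measure label, e.g. `"jaccard"`, `"braycurtis"`,
#'   `"uwunifrac"`, `"gunifrac"`, `"wunifrac"`.
#' @slot alpha generalized-UniFrac exponent in `[0, 1]`; `NA` otherwise.
#' @export
setClass("DistanceMatrix",
         representation(values = "matrix", measure = "character",
                        alpha = "numeric"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "not square")
  if (!isSymmetric(unname(v), tol = 1e-10)) msg <- c(msg, "not symmetric")
  if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "nonzero diagonal")
  if (any(v < -1e-12)) msg <- c(msg, "negative distances")
  if (length(msg)) msg else TRUE
})

.distanceMatrix <- function(values, measure, alpha = NA_real_) {
  values[values < 0] <- 0          # clip numerical noise
  diag(values) <- 0
  values <- (values + t(values)) / 2
  new("DistanceMatrix", values = values, measure = measure,
      alpha = as.numeric(alpha))
}

#' @describeIn distanceToKernel extract the numeric matrix of a
#'   `DistanceMatrix` or `Kernel`.
#' @export
values <- function(x) x@values

#' @describeIn distanceToKernel the measure label.
#' @export
measure <- function(x) x@measure

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@measure,
      if (!is.na(object@alpha)) sprintf(", alpha = %g", object@alpha) else "",
      "): ", nrow(object@values), " samples\n", sep = "")
})

#' Positive semi-definite sample-similarity kernel
#'
#' An n x n positive semi-definite similarity matrix, here obtained from an
#' ecological distance matrix by Gower double-centering of the squared
#' distances, with negative eigenvalues (arising from non-Euclidean
#' dissimilarities such as Bray-Curtis) clipped to zero.
#'
#' @slot values n x n numeric matrix.
#' @slot measure measure label of the distance it came from (or
#'   `"user"`).
#' @slot alpha generalized-UniFrac exponent or `NA`.
#' @slot psdClipped `TRUE` if any materially negative eigenvalue was
#'   zeroed during construction.
#' @export
setClass("Kernel",
         representation(values = "matrix", measure = "character",
                        alpha = "numeric", psdClipped = "logical"))

setValidity("Kernel", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("not square")
  if (!isSymmetric(unname(v), tol = 1e-8)) return("not symmetric")
  TRUE
})

setMethod("show", "Kernel", function(object) {
  cat("Kernel (", object@measure,
      if (!is.na(object@alpha)) sprintf(", alpha = %g", object@alpha) else "",
      "): ", nrow(object@values), " samples",
      if (object@psdClipped) ", PSD-clipped" else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## SurrogateVariants.
## ---------------------------------------------------------------------------

#' Surrogate variants extracted from a kernel
#'
#' The matrix `X* = U D` from the eigendecomposition `K = U D^2 U'` of a
#' positive semi-definite kernel: orthogonal, lower-dimensional linear
#' stand-ins for the unknown transformed variants underlying the kernel.
#' Columns are ordered by decreasing singular value; squared column norms
#' equal the kernel eigenvalues; with `df` equal to the number of nonzero
#' eigenvalues, `X* X*'` reconstructs the kernel.
#'
#' @slot scores n x df numeric matrix `X*`.
#' @slot singularValues the df singular values, non-increasing, positive.
#' @slot measure source kernel label.
#' @export
setClass("SurrogateVariants",
         representation(scores = "matrix", singularValues = "numeric",
                        measure = "character"))

setValidity("SurrogateVariants", function(object) {
  d <- object@singularValues
  if (length(d) != ncol(object@scores)) return("df mismatch")
  if (any(d <= 0)) return("singular values must be positive")
  if (is.unsorted(rev(d))) return("singular values must be non-increasing")
  TRUE
})

#' @describeIn extractSurrogates the n x df surrogate-variant matrix.
#' @export
scores <- function(x) x@scores

#' @describeIn extractSurrogates the singular values.
#' @export
singularValues <- function(x) x@singularValues

setMethod("show", "SurrogateVariants", function(object) {
  cat("SurrogateVariants (", object@measure, "): ",
      nrow(object@scores), " samples x ", ncol(object@scores),
      " components\n", sep = "")
})

## ---------------------------------------------------------------------------
## Test results.
## ---------------------------------------------------------------------------

#' Per-input-kernel association test result
#'
#' Observed and permutation-null variance-component score statistics for
#' the three endogenous kernels (main `M`, interaction `I`, both `B`),
#' their permutation p-values (pooled convention: the observed
#' arrangement counts among the rearrangements), and the min-P
#' combination across the three with its own permutation calibration.
#'
#' @slot measure input kernel label.
#' @slot alpha generalized-UniFrac exponent or `NA`.
#' @slot statObs named numeric(3): observed `T^M`, `T^I`, `T^B`.
#' @slot statNull R x 3 matrix of null statistics (shared permutations).
#' @slot p named numeric(3): permutation p-values `P^M`, `P^I`, `P^B`.
#' @slot pNull R x 3 matrix of the permutations' pooled null p-values.
#' @slot minP the min-P statistic `T_(h) = min(P^M, P^I, P^B)`.
#' @slot minPNull length-R null values of the min-P statistic.
#' @slot pKernel the calibrated per-kernel p-value `P_(h)`.
#' @export
setClass("SingleKernelResult",
         representation(measure = "character", alpha = "numeric",
                        statObs = "numeric", statNull = "matrix",
                        p = "numeric", pNull = "matrix", minP = "numeric",
                        minPNull = "numeric", pKernel = "numeric"))

setMethod("show", "SingleKernelResult", function(object) {
  cat("SingleKernelResult (", object@measure,
      if (!is.na(object@alpha)) sprintf(", alpha = %g", object@alpha) else "",
      "), R = ", nrow(object@statNull), "\n", sep = "")
  cat(sprintf("  P^M = %.4g  P^I = %.4g  P^B = %.4g  ->  P_(h) = %.4g\n",
              object@p["M"], object@p["I"], object@p["B"], object@pKernel))
})

#' @describeIn testSingleKernel the calibrated per-kernel p-value `P_(h)`.
#' @export
pKernel <- function(x) x@pKernel

#' @describeIn testSingleKernel the three endogenous p-values
#'   (`M`, `I`, `B`).
#' @export
pEndogenous <- function(x) x@p

#' Omnibus OmniK result across input kernels
#'
#' The two-level min-P omnibus over the per-kernel results: first across
#' input kernels for each endogenous target (main/interaction/both), then
#' across the three targets, all calibrated on one shared permutation
#' plan.
#'
#' @slot results named list of [SingleKernelResult-class], one per input
#'   kernel.
#' @slot tOmnibus named numeric(3): observed `T^M/T^I/T^B_OmniK`
#'   (minima over kernels of the endogenous p-values).
#' @slot pOmnibus named numeric(3): their calibrated p-values
#'   `P^M/P^I/P^B_OmniK`.
#' @slot tOverall observed `T_OmniK = min(pOmnibus)`.
#' @slot pOverall the overall calibrated `P_OmniK`.
#' @slot R number of permutations; @slot seed seed used (NA if none);
#' @slot df degrees of freedom used ( `Inf` codes "full").
#' @slot family model family.
#' @export
setClass("OmniKResult",
         representation(results = "list", tOmnibus = "numeric",
                        pOmnibus = "numeric", tOverall = "numeric",
                        pOverall = "numeric", R = "integer",
                        seed = "numeric", df = "numeric",
                        family = "character"))

setMethod("show", "OmniKResult", function(object) {
  cat("OmniKResult:", length(object@results), "input kernels, R =",
      object@R, ", family =", object@family, "\n")
  for (nm in names(object@results))
    cat(sprintf("  P_(%s) = %.4g\n", nm, object@results[[nm]]@pKernel))
  cat(sprintf("  P^M_OmniK = %.4g  P^I_OmniK = %.4g  P^B_OmniK = %.4g\n",
              object@pOmnibus["M"], object@pOmnibus["I"],
              object@pOmnibus["B"]))
  cat(sprintf("  P_OmniK = %.4g\n", object@pOverall))
})

#' @describeIn omniKTest the overall omnibus p-value `P_OmniK`.
#' @export
pOmniK <- function(x) x@pOverall

#' @describeIn omniKTest the three endogenous omnibus p-values
#'   `P^M/P^I/P^B_OmniK`.
#' @export
pOmnibus <- function(x) x@pOmnibus

#' @describeIn omniKTest the list of per-kernel results.
#' @export
kernelResults <- function(x) x@results
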