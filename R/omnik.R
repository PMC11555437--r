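## The OmniK omnibus test across multiple input kernels.

#' OmniK: omnibus kernel machine regression test
#'
#' Tests jointly for main and treatment-interaction effects of the
#' variants underlying one or more input kernels.  For each input kernel,
#' surrogate variants are extracted by SVD, three endogenous kernels
#' (main/interaction/both) are formed, and permutation variance-component
#' score tests are run on one shared permutation plan.  P-values are then
#' combined by the two-level min-P omnibus: across input kernels per
#' endogenous target, and across the three targets.
#'
#' @param table a [CountTable-class] (or `NULL` when `kernels` is a list
#'   of precomputed [Kernel-class] objects / PSD matrices).
#' @param tree rooted [ape::phylo]; needed for UniFrac measures.
#' @param meta a [SampleMetadata-class]; harmonized to `table` when a
#'   table is given.
#' @param kernels character vector of measure labels (see
#'   [defaultKernelSet()]) or a named list of precomputed kernels.
#' @param nPerm number of permutations `R`.
#' @param df `"full"` or integer degrees of freedom for the surrogates.
#' @param seed optional integer seed for the permutation plan (always
#'   recorded in the result).
#' @return an [OmniKResult-class].
#' @examples
#' set.seed(1)
#' ct <- simulateCounts(dmParameters(rep(1/20, 20), 0.02, 500), n = 30)
#' tr <- synthTree(20, seed = 2)
#' meta <- sampleMetadata(response = rnorm(30),
#'                        treatment = rbinom(30, 1, 0.5),
#'                        sampleIDs = sampleIDs(ct))
#' res <- omniKTest(ct, tr, meta, nPerm = 200, seed = 3)
#' pOmniK(res)
#' @export
omniKTest <- function(table = NULL, tree = NULL, meta,
                      kernels = defaultKernelSet(), nPerm = 3000L,
                      df = "full", seed = NULL) {
  if (is.character(kernels)) {
    if (is.null(table)) stop("a count table is needed to compute kernels")
    h <- harmonize(table, tree, meta)
    Ks <- ecologicalKernels(h$table, h$tree, kernels)
    meta <- h$meta
  } else {
    Ks <- kernels
    if (is.null(names(Ks)))
      names(Ks) <- paste0("kernel", seq_along(Ks))
  }
  fit <- fitNullModel(meta)
  n <- length(fit$residuals)
  if (!is.null(seed)) set.seed(seed)
  plan <- permutationPlan(n, nPerm)
  omniKFromKernels(Ks, meta, plan, df = df,
                   seed = if (is.null(seed)) NA_real_ else seed,
                   nullFit = fit)
}

#' @describeIn omniKTest run OmniK on precomputed kernels with an
#'   explicit permutation plan (used by the simulation harness and the
#'   exhaustive-enumeration tests).
#' @param plan a [permutationPlan()].
#' @param nullFit optional precomputed [fitNullModel()] result.
#' @export
omniKFromKernels <- function(kernels, meta, plan, df = "full",
                             seed = NA_real_, nullFit = NULL) {
  if (is.null(nullFit)) nullFit <- fitNullModel(meta)
  Xlist <- lapply(kernels, function(K) {
    if (is(K, "SurrogateVariants")) {
      X <- scores(K)
      if (!identical(df, "full")) {
        df <- as.integer(df)
        if (df > ncol(X))
          stop(sprintf("df = %d exceeds the %d surviving components",
                       df, ncol(X)))
        X <- X[, seq_len(df), drop = FALSE]
      }
      X
    } else scores(extractSurrogates(K, df))
  })
  st <- .engineStats(Xlist, meta@treatment, nullFit$residuals, plan$perms)
  calibs <- lapply(st, .calibrateKernel)
  omni <- .calibrateOmnibus(calibs)
  results <- lapply(names(st), function(nm) {
    K <- kernels[[nm]]
    new("SingleKernelResult",
        measure = if (is(K, "Kernel")) K@measure else nm,
        alpha = if (is(K, "Kernel")) as.numeric(K@alpha) else NA_real_,
        statObs = st[[nm]]$obs, statNull = st[[nm]]$null,
        p = calibs[[nm]]$p, pNull = calibs[[nm]]$pNull,
        minP = calibs[[nm]]$minP, minPNull = calibs[[nm]]$minPNull,
        pKernel = calibs[[nm]]$pKernel)
  })
  names(results) <- names(st)
  dfNum <- if (identical(df, "full")) Inf else as.numeric(df)
  new("OmniKResult", results = results, tOmnibus = omni$tOmnibus,
      pOmnibus = omni$pOmnibus, tOverall = omni$tOverall,
      pOverall = omni$pOverall, R = as.integer(plan$R),
      seed = as.numeric(seed), df = dfNum, family = meta@family)
}

#' Recompute the omnibus on a subset of kernels
#'
#' Rebuilds the omnibus p-values for any subset of the input kernels from
#' the cached permutation-null arrays of an existing result; no new
#' permutations are run, so the subsetted result is exactly what a fresh
#' analysis with that kernel set and the same plan would give.
#'
#' @param result an [OmniKResult-class].
#' @param measures names of the kernels to keep.
#' @return an [OmniKResult-class] on the subset.
#' @export
omniKSubset <- function(result, measures) {
  keep <- result@results[measures]
  if (any(vapply(keep, is.null, logical(1))))
    stop("unknown kernel name")
  calibs <- lapply(keep, function(r)
    list(p = r@p, pNull = r@pNull, minP = r@minP, minPNull = r@minPNull,
         pKernel = r@pKernel))
  omni <- .calibrateOmnibus(calibs)
  new("OmniKResult", results = keep, tOmnibus = omni$tOmnibus,
      pOmnibus = omni$pOmnibus, tOverall = omni$tOverall,
      pOverall = omni$pOverall, R = result@R, seed = result@seed,
      df = result@df, family = result@family)
}

#' Serialize an OmniK result
#'
#' Flat list (JSON-ready) with per-kernel `P_M`, `P_I`, `P_B`,
#' `P_minp`, the omnibus block, and the run parameters.
#'
#' @param result an [OmniKResult-class].
#' @param path optional path; when given the JSON is written there.
#' @return the list, invisibly when written to file.
#' @export
resultToJSON <- function(result, path = NULL) {
  per <- lapply(result@results, function(r)
    list(P_M = r@p[["M"]], P_I = r@p[["I"]], P_B = r@p[["B"]],
         P_minp = r@pKernel))
  out <- list(kernels = per,
              omnibus = list(P_M = result@pOmnibus[["M"]],
                             P_I = result@pOmnibus[["I"]],
                             P_B = result@pOmnibus[["B"]],
                             P_OmniK = result@pOverall),
              R = result@R, seed = result@seed,
              df = if (is.infinite(result@df)) "full" else result@df,
              family = result@family)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
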