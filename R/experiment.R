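## Monte-Carlo experiment harness: empirical rejection rates of the
## per-kernel tests, the omnibus components, OmniK, and the comparison
## combiners, over replicated simulated datasets.

#' Run a simulation experiment
#'
#' For each replicate: simulate Dirichlet-multinomial counts over a fixed
#' random tree, generate covariates/treatment/response per the scenario,
#' compute the ecological kernels, run the full permutation analysis on
#' one shared plan, and record rejection at the chosen level for every
#' method.  The tree, the Dirichlet-multinomial parameters and the PAM
#' effect cluster are drawn once per experiment; counts, design and
#' permutations are redrawn per replicate.  Fully reproducible from
#' `seed`.
#'
#' @param scenario a [simulationScenario()].
#' @param reps number of replicates.
#' @param perms permutations `R` per replicate.
#' @param seed integer seed for the whole experiment.
#' @param p number of taxa (when `params` is `NULL`; default 100).
#' @param params optional [dmParameters()]; synthetic defaults otherwise.
#' @param tree optional fixed tree; a random one otherwise.
#' @param measures input-kernel set (default the seven candidates).
#' @param dfs vector of degrees-of-freedom settings; `"full"` and/or
#'   integers.  The first entry supplies the per-kernel, omnibus and
#'   combiner columns; additional entries add `OmniK_df<k>` columns.
#' @param combiners also record Fisher/Brown/Simes rejections.
#' @param level significance level (default 0.05).
#' @param verbose print per-replicate progress every 100 replicates.
#' @return an object of class `"omnikExperiment"`: list with `rates`
#'   (data.frame of method, rejection rate in percent, binomial SE),
#'   `pvalues` (reps x method matrix), `scenario`, `seed`, `R`.
#' @export
runExperiment <- function(scenario, reps, perms = 1000L, seed = 1L,
                          p = 100L, params = NULL, tree = NULL,
                          measures = defaultKernelSet(), dfs = "full",
                          combiners = TRUE, level = 0.05,
                          verbose = FALSE) {
  set.seed(seed)
  if (is.null(tree)) tree <- synthTree(if (is.null(params)) p
                                       else length(params@proportions))
  if (is.null(params)) params <- defaultDMParams(length(tree$tip.label))
  clusterTaxa <- if (scenario$effect == "null") character()
    else pamEffectCluster(tree, scenario$nClusters, scenario$cluster)

  dfLab <- function(d) if (identical(d, "full")) "full" else
    as.character(d)
  cols <- c(paste0("K_", measures), "OmniK_M", "OmniK_I", "OmniK_B",
            "OmniK")
  if (combiners) cols <- c(cols, "fisher", "brown", "simes")
  extraDfs <- if (length(dfs) > 1L) dfs[-1L] else list()
  for (d in extraDfs) cols <- c(cols, paste0("OmniK_df", dfLab(d)))
  pv <- matrix(NA_real_, reps, length(cols),
               dimnames = list(NULL, cols))

  for (it in seq_len(reps)) {
    tab <- simulateCounts(params, scenario$n)
    meta <- suppressWarnings(generateDesign(tab, scenario, clusterTaxa))
    Ks <- lapply(ecologicalDistances(tab, tree, measures),
                 distanceToSurrogates)
    plan <- permutationPlan(scenario$n, perms)
    res <- omniKFromKernels(Ks, meta, plan, df = dfs[[1L]])
    pv[it, seq_along(measures)] <-
      vapply(res@results, pKernel, numeric(1))
    pv[it, c("OmniK_M", "OmniK_I", "OmniK_B")] <- res@pOmnibus
    pv[it, "OmniK"] <- res@pOverall
    if (combiners)
      pv[it, c("fisher", "brown", "simes")] <- altCombine(res)
    for (d in extraDfs) {
      rd <- omniKFromKernels(Ks, meta, plan, df = d)
      pv[it, paste0("OmniK_df", dfLab(d))] <- rd@pOverall
    }
    if (verbose && it %% 100L == 0L)
      message("replicate ", it, "/", reps)
  }
  rej <- colMeans(pv <= level)
  rates <- data.frame(method = cols, rate = 100 * rej,
                      se = 100 * sqrt(rej * (1 - rej) / reps),
                      reps = reps, row.names = NULL)
  structure(list(rates = rates, pvalues = pv, scenario = scenario,
                 seed = seed, R = perms, level = level),
            class = "omnikExperiment")
}

#' @export
print.omnikExperiment <- function(x, ...) {
  cat("Simulation experiment (", x$scenario$effect, ", ",
      x$scenario$family, "/", x$scenario$design, ", n = ",
      x$scenario$n, "), ", nrow(x$pvalues), " reps, R = ", x$R,
      "\n", sep = "")
  print(x$rates, digits = 3)
  invisible(x)
}

#' Write a rejection-rate table as TSV
#'
#' @param x an `"omnikExperiment"`.
#' @param path output path.
#' @export
writeExperiment <- function(x, path) {
  write.table(x$rates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
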