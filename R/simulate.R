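## Dirichlet-multinomial count simulation, phylogenetic effect clusters,
## and the covariate/treatment/response generators for the type-I-error
## and power experiments.

#' Dirichlet-multinomial parameters
#'
#' Mean proportions `pi` on the simplex, overdispersion
#' `theta = 1/(1 + sum gamma)` in `[0, 1)` (`theta = 0` is a plain
#' multinomial), and the per-sample total count.
#'
#' @slot proportions numeric simplex vector.
#' @slot theta overdispersion scalar.
#' @slot totalCount sequencing depth per sample.
#' @export
setClass("DMParams",
         representation(proportions = "numeric", theta = "numeric",
                        totalCount = "numeric"))

setValidity("DMParams", function(object) {
  msg <- character()
  if (any(object@proportions < 0)) msg <- c(msg, "negative proportion")
  if (abs(sum(object@proportions) - 1) > 1e-8)
    msg <- c(msg, "proportions must sum to 1")
  if (object@theta < 0 || object@theta >= 1)
    msg <- c(msg, "theta must be in [0, 1)")
  if (object@totalCount < 1) msg <- c(msg, "totalCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn simulateCounts construct Dirichlet-multinomial parameters.
#' @param proportions simplex vector of mean taxon proportions.
#' @param theta overdispersion in `[0, 1)`.
#' @param totalCount per-sample total count (default 10000).
#' @export
dmParameters <- function(proportions, theta, totalCount = 10000) {
  new("DMParams", proportions = proportions / sum(proportions),
      theta = as.numeric(theta), totalCount = as.numeric(totalCount))
}

setMethod("show", "DMParams", function(object) {
  cat("DMParams:", length(object@proportions), "taxa, theta =",
      object@theta, ", total =", object@totalCount, "\n")
})

#' Synthetic default Dirichlet-multinomial parameters
#'
#' A reproducible stand-in for parameters estimated from a real cohort:
#' mean proportions drawn once from a flat Dirichlet and sorted
#' decreasingly (a plausibly skewed taxon-frequency profile), with
#' moderate overdispersion.
#'
#' @param p number of taxa.
#' @param theta overdispersion (default 0.02).
#' @param totalCount per-sample depth (default 10000).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return a `DMParams` object.
#' @export
defaultDMParams <- function(p = 100, theta = 0.02, totalCount = 10000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rgamma(p, shape = 1, rate = 1)
  dmParameters(sort(g / sum(g), decreasing = TRUE), theta, totalCount)
}

#' Estimate Dirichlet-multinomial parameters from counts
#'
#' Method-of-moments estimates: proportions as count-weighted means, and
#' the Weir & Hill moment estimator of the overdispersion
#' `theta = 1/(1 + sum gamma)` from the between- vs within-sample mean
#' squares.  A negative moment estimate (no detectable overdispersion)
#' is truncated to 0.
#'
#' @param table a [CountTable-class] with at least 2 samples.
#' @return a `DMParams` object.
#' @export
estimateDMParams <- function(table) {
  m <- countData(table)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples")
  Ni <- rowSums(m)
  pihat <- colSums(m) / sum(m)
  P <- m / Ni
  MSP <- sum(Ni * rowSums((P - matrix(pihat, n, ncol(m),
                                      byrow = TRUE))^2)) / (n - 1)
  MSG <- sum(Ni * rowSums(P * (1 - P))) / sum(Ni - 1)
  Nc <- (sum(Ni) - sum(Ni^2) / sum(Ni)) / (n - 1)
  theta <- (MSP - MSG) / (MSP + (Nc - 1) * MSG)
  dmParameters(pihat, max(theta, 0), mean(Ni))
}

#' Simulate Dirichlet-multinomial counts
#'
#' Each sample draws its composition from
#' `Dirichlet(gamma), gamma = pi (1 - theta) / theta`, then counts from
#' `Multinomial(totalCount)`; `theta = 0` skips the Dirichlet step.
#' Rows are independent.
#'
#' @param params a `DMParams`.
#' @param n number of samples.
#' @param seed optional seed.
#' @return a [CountTable-class] with samples `s1..sn`, taxa `t1..tp`.
#' @export
simulateCounts <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(params, "DMParams"))
  p <- length(params@proportions)
  total <- params@totalCount
  counts <- matrix(0, n, p)
  for (i in seq_len(n)) {
    prob <- params@proportions
    if (params@theta > 0) {
      gam <- prob * (1 - params@theta) / params@theta
      g <- rgamma(p, shape = gam, rate = 1)
      if (sum(g) > 0) prob <- g / sum(g)
    }
    counts[i, ] <- rmultinom(1, size = total, prob = prob)
  }
  countTable(counts, sampleIDs = paste0("s", seq_len(n)),
             taxonIDs = paste0("t", seq_len(p)))
}

#' Random bifurcating tree fixture
#'
#' A random rooted bifurcating tree over `p` labelled leaves with
#' positive branch lengths, standing in for a real reference phylogeny.
#'
#' @param p number of leaves (taxa), labelled `t1..tp`.
#' @param seed optional seed.
#' @return an [ape::phylo].
#' @export
synthTree <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validateTree(ape::rtree(p, tip.label = paste0("t", seq_len(p))))
}

#' Phylogenetically coherent effect cluster
#'
#' Partitions the leaves into `k` clusters by PAM (k-medoids, classic
#' build+swap via [cluster::pam()]) on the leaf-to-leaf cophenetic
#' distances, and returns the taxa of the requested cluster.
#' Deterministic given the tree.
#'
#' @param tree an [ape::phylo].
#' @param k number of clusters (default 5).
#' @param clusterID which cluster to return, in `1..k`.
#' @return character vector of taxon ids.
#' @export
pamEffectCluster <- function(tree, k = 5L, clusterID = 1L) {
  tree <- validateTree(tree)
  if (k > length(tree$tip.label)) stop("k exceeds the number of leaves")
  if (clusterID < 1L || clusterID > k) stop("cluster id out of range")
  if (k == length(tree$tip.label)) return(tree$tip.label[clusterID])
  D <- ape::cophenetic.phylo(tree)
  cl <- cluster::pam(stats::as.dist(D), k = k, cluster.only = TRUE)
  names(cl)[cl == clusterID]
}

## ---------------------------------------------------------------------------
## Scenarios.
## ---------------------------------------------------------------------------

#' Simulation scenario
#'
#' Bundles the knobs of one simulation condition: sample size, model
#' family, treatment design, the basis transform `f`, the effect pattern
#' and its magnitudes.  Effect magnitudes default to the canonical
#' settings per family: main-only `beta1 = 2`; interaction-only
#' `beta2 = 1` (gaussian) or `3` (binomial); both
#' `(beta1, beta2) = (2, -1)` (gaussian) or `(-1.5, 3)` (binomial), with
#' the effect cluster split in two for the "both" pattern.  The fixed
#' regression coefficients are `alpha1 = 0` (intercept), `alpha2 = 1`
#' (treatment), `alpha3 = 0.5` (each covariate).
#'
#' @param n sample size.
#' @param family `"gaussian"` or `"binomial"`.
#' @param design `"rct"` (treatment `Bern(0.5)`) or `"observational"`
#'   (treatment depends on the covariates through a logistic model).
#' @param transform `f`: `"standardize"` (per-taxon mean 0, variance 1;
#'   a linear relationship) or `"presence_absence"` (indicator of count
#'   `> 0`; a discrete non-linear relationship).
#' @param effect `"null"`, `"main_only"`, `"interaction_only"` or
#'   `"both"`.
#' @param cluster effect-cluster id in `1..nClusters`.
#' @param nClusters PAM cluster count (default 5).
#' @param beta1,beta2 override the default effect magnitudes.
#' @return a classed list.
#' @export
simulationScenario <- function(n = 100L,
                               family = c("gaussian", "binomial"),
                               design = c("rct", "observational"),
                               transform = c("standardize",
                                             "presence_absence"),
                               effect = c("null", "main_only",
                                          "interaction_only", "both"),
                               cluster = 1L, nClusters = 5L,
                               beta1 = NULL, beta2 = NULL) {
  family <- match.arg(family); design <- match.arg(design)
  transform <- match.arg(transform); effect <- match.arg(effect)
  if (is.null(beta1))
    beta1 <- switch(effect, null = 0, main_only = 2,
                    interaction_only = 0,
                    both = if (family == "gaussian") 2 else -1.5)
  if (is.null(beta2))
    beta2 <- switch(effect, null = 0, main_only = 0,
                    interaction_only = if (family == "gaussian") 1 else 3,
                    both = if (family == "gaussian") -1 else 3)
  structure(list(n = as.integer(n), family = family, design = design,
                 transform = transform, effect = effect,
                 cluster = as.integer(cluster),
                 nClusters = as.integer(nClusters),
                 beta1 = beta1, beta2 = beta2,
                 alpha1 = 0, alpha2 = 1, alpha3 = 0.5),
            class = "omnikScenario")
}

#' @export
print.omnikScenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: n = %d, %s response, %s design, f = %s, effect = %s (beta1 = %g, beta2 = %g), cluster P%d\n",
    x$n, x$family, x$design, x$transform, x$effect, x$beta1, x$beta2,
    x$cluster))
  invisible(x)
}

.standardizeCols <- function(m, warnDrop = TRUE) {
  sds <- apply(m, 2, sd)
  keep <- sds > 0
  if (!all(keep) && warnDrop)
    warning(sum(!keep), " constant taxa dropped from effect transform",
            call. = FALSE)
  m <- m[, keep, drop = FALSE]
  scale(m)
}

#' Generate covariates, treatment and response for a scenario
#'
#' `z1 ~ Bern(0.5)`; `z2` is correlated with the microbiome: 0.5 times
#' the row-mean of the standardized abundances of a random 10% taxon
#' subset, plus standard normal noise.  Treatment is `Bern(0.5)` in the
#' randomized design, or `Bern(expit(0.5 (z1s + z2s)))` with
#' standardized covariates in the observational design.  The response
#' follows the linear (plus `N(0,1)` error) or logistic model with the
#' scenario's coefficients; the effect term applies `f` to the selected
#' cluster's abundances (split in half between main and interaction for
#' the "both" pattern).
#'
#' @param table a [CountTable-class].
#' @param scenario a [simulationScenario()].
#' @param clusterTaxa taxa carrying the effect (ignored for the null
#'   pattern).
#' @param seed optional seed.
#' @return a [SampleMetadata-class]; the effect taxa used are attached
#'   as `attr(, "truth")`.
#' @export
generateDesign <- function(table, scenario, clusterTaxa = character(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- countData(table)
  n <- nrow(m)
  stopifnot(n == scenario$n)
  ## covariates
  z1 <- rbinom(n, 1, 0.5)
  nSel <- max(1L, round(0.1 * ncol(m)))
  sel <- sample(ncol(m), nSel)
  Xsel <- .standardizeCols(m[, sel, drop = FALSE], warnDrop = FALSE)
  z2base <- if (ncol(Xsel)) rowMeans(Xsel) else numeric(n)
  z2 <- 0.5 * z2base + rnorm(n)
  ## treatment
  tr <- if (scenario$design == "rct") {
    rbinom(n, 1, 0.5)
  } else {
    zs <- scale(cbind(z1, z2))
    rbinom(n, 1, stats::plogis(0.5 * rowSums(zs)))
  }
  ## effect term
  eff <- numeric(n)
  truth <- list(mainTaxa = character(), interactionTaxa = character())
  if (scenario$effect != "null" && length(clusterTaxa)) {
    fX <- m[, clusterTaxa, drop = FALSE]
    fX <- if (scenario$transform == "presence_absence") (fX > 0) * 1
          else .standardizeCols(fX)
    pp <- ncol(fX)
    if (pp > 0) {
      if (scenario$effect == "both") {
        i1 <- seq_len(ceiling(pp / 2)); i2 <- setdiff(seq_len(pp), i1)
      } else if (scenario$effect == "main_only") {
        i1 <- seq_len(pp); i2 <- integer(0)
      } else { i1 <- integer(0); i2 <- seq_len(pp) }
      if (length(i2) == 0 && scenario$effect == "both") i2 <- i1
      if (length(i1))
        eff <- eff + rowSums(fX[, i1, drop = FALSE]) * scenario$beta1
      if (length(i2))
        eff <- eff + rowSums(fX[, i2, drop = FALSE]) * tr * scenario$beta2
      truth <- list(mainTaxa = colnames(fX)[i1],
                    interactionTaxa = colnames(fX)[i2])
    }
  }
  lp <- scenario$alpha1 + tr * scenario$alpha2 +
    scenario$alpha3 * z1 + scenario$alpha3 * z2 + eff
  y <- if (scenario$family == "gaussian") lp + rnorm(n)
       else rbinom(n, 1, stats::plogis(lp))
  meta <- sampleMetadata(response = y, treatment = tr,
                         covariates = cbind(z1 = z1, z2 = z2),
                         family = scenario$family,
                         sampleIDs = sampleIDs(table))
  attr(meta, "truth") <- truth
  meta
}

#' Simulate one complete dataset
#'
#' Convenience wrapper: tree, Dirichlet-multinomial parameters, counts,
#' effect cluster and design for one scenario, reproducible from the
#' seed.
#'
#' @param scenario a [simulationScenario()].
#' @param p number of taxa (when `params` is `NULL`).
#' @param params optional `DMParams`; synthetic defaults otherwise.
#' @param tree optional tree; a random one otherwise.
#' @param seed optional seed.
#' @return `list(table, tree, meta, truth)`.
#' @export
simulateDataset <- function(scenario, p = 100L, params = NULL,
                            tree = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- synthTree(if (is.null(params)) p
                                       else length(params@proportions))
  if (is.null(params)) params <- defaultDMParams(length(tree$tip.label))
  tab <- simulateCounts(params, scenario$n)
  clusterTaxa <- if (scenario$effect == "null") character()
    else pamEffectCluster(tree, scenario$nClusters, scenario$cluster)
  meta <- suppressWarnings(generateDesign(tab, scenario, clusterTaxa))
  list(table = tab, tree = tree, meta = meta,
       truth = c(attr(meta, "truth"),
                 list(scenario = scenario, clusterTaxa = clusterTaxa)))
}
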