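## Ecological beta-diversity distances and their conversion to PSD kernels.

.properNames <- function(v, ids) {
  dimnames(v) <- list(ids, ids)
  v
}

#' Per-sample relative abundances
#'
#' Counts are converted to per-sample proportions before any
#' abundance-weighted measure; no rarefaction is performed, keeping the
#' distances stable under sampling depth.
#'
#' @param table a [CountTable-class].
#' @return n x p matrix of row proportions.
#' @export
relativeAbundance <- function(table) {
  m <- countData(table)
  m / rowSums(m)
}

#' Jaccard distance
#'
#' Presence-absence distance `1 - |A_i intersect A_j| / |A_i union A_j|`
#' where `A_i` is the set of taxa with count > 0 in sample i.
#'
#' @param table a [CountTable-class].
#' @return a [DistanceMatrix-class].
#' @export
jaccardDistance <- function(table) {
  pa <- (countData(table) > 0) * 1
  shared <- tcrossprod(pa)
  sizes <- rowSums(pa)
  un <- outer(sizes, sizes, "+") - shared
  d <- 1 - shared / un
  .distanceMatrix(.properNames(unname(d), sampleIDs(table)), "jaccard")
}

#' Bray-Curtis dissimilarity
#'
#' `sum_j |u_j - v_j| / sum_j (u_j + v_j)` on per-sample proportions,
#' computed through [vegan::vegdist()].
#'
#' @param table a [CountTable-class].
#' @return a [DistanceMatrix-class].
#' @export
brayCurtisDistance <- function(table) {
  p <- relativeAbundance(table)
  d <- as.matrix(vegan::vegdist(p, method = "bray"))
  .distanceMatrix(.properNames(unname(d), sampleIDs(table)), "braycurtis")
}

## Branch structure of a tree: indicator of leaves under each edge, plus
## edge lengths.  Precomputed once per tree and reused across samples.
.branchStructure <- function(tree, taxonOrder) {
  p <- length(tree$tip.label)
  E <- nrow(tree$edge)
  M <- matrix(0, p, E)
  childEdges <- split(seq_len(E), factor(tree$edge[, 1],
                                         levels = seq_len(p + tree$Nnode)))
  for (e in ape::postorder(tree)) {
    v <- tree$edge[e, 2]
    if (v <= p) {
      M[v, e] <- 1
    } else {
      ch <- childEdges[[v]]
      M[, e] <- as.numeric(rowSums(M[, ch, drop = FALSE]) > 0)
    }
  }
  idx <- match(taxonOrder, tree$tip.label)
  if (anyNA(idx)) stop("taxon not found in tree: ",
                       paste(taxonOrder[is.na(idx)], collapse = ", "))
  list(leafByEdge = M[idx, , drop = FALSE], lengths = tree$edge.length)
}

#' UniFrac-family distances
#'
#' Computes unweighted, generalized, or weighted(-normalized) UniFrac
#' from a rooted tree with branch lengths.  Unweighted is the fraction of
#' branch length unique to either sample among branch length present in
#' at least one; weighted is `sum b|p_A - p_B| / sum b(p_A + p_B)` on
#' per-sample proportions (range `[0, 1]`); generalized uses branch
#' weights `(p_A + p_B)^alpha` and coincides with weighted at
#' `alpha = 1`.
#'
#' @param table a [CountTable-class].
#' @param tree a rooted [ape::phylo] whose leaves cover the table's taxa.
#' @param variant `"unweighted"`, `"generalized"` or `"weighted"`.
#' @param alpha exponent in `[0, 1]` for the generalized variant.
#' @return a [DistanceMatrix-class].
#' @export
unifracDistance <- function(table, tree,
                            variant = c("unweighted", "generalized",
                                        "weighted"),
                            alpha = NULL) {
  variant <- match.arg(variant)
  if (variant == "generalized") {
    if (is.null(alpha) || is.na(alpha) || alpha < 0 || alpha > 1)
      stop("generalized UniFrac needs alpha in [0, 1]")
  } else alpha <- NA_real_
  tree <- validateTree(tree)
  bs <- .branchStructure(tree, taxonIDs(table))
  cum <- relativeAbundance(table) %*% bs$leafByEdge
  out <- unifrac_pairwise(cum, bs$lengths,
                          if (is.na(alpha)) numeric(0) else alpha)
  d <- switch(variant,
              unweighted = out$unweighted,
              weighted = out$weighted,
              generalized = out$generalized[[1]])
  lab <- switch(variant, unweighted = "uwunifrac",
                weighted = "wunifrac", generalized = "gunifrac")
  .distanceMatrix(.properNames(d, sampleIDs(table)), lab, alpha)
}

#' The standard set of ecological distances
#'
#' Computes the seven-candidate set used throughout: Jaccard,
#' Bray-Curtis, unweighted UniFrac, generalized UniFrac at
#' `alpha = 0.25, 0.5, 0.75`, and weighted UniFrac.  UniFrac variants are
#' computed in one pass over branch pairs.
#'
#' @param table a [CountTable-class].
#' @param tree rooted [ape::phylo]; when `NULL` only the non-phylogenetic
#'   measures are returned.
#' @param measures subset of
#'   `c("jaccard","braycurtis","uwunifrac","gunifrac:<a>","wunifrac")`.
#' @return named list of [DistanceMatrix-class] objects.
#' @export
ecologicalDistances <- function(table, tree = NULL,
                                measures = defaultKernelSet()) {
  out <- list()
  ids <- sampleIDs(table)
  alphas <- as.numeric(sub("^gunifrac:", "",
                           grep("^gunifrac:", measures, value = TRUE)))
  needTree <- any(measures %in% c("uwunifrac", "wunifrac")) ||
    length(alphas)
  if (needTree) {
    if (is.null(tree)) stop("UniFrac measures need a tree")
    tree <- validateTree(tree)
    bs <- .branchStructure(tree, taxonIDs(table))
    cum <- relativeAbundance(table) %*% bs$leafByEdge
    uf <- unifrac_pairwise(cum, bs$lengths, alphas)
  }
  for (m in measures) {
    out[[m]] <-
      if (m == "jaccard") jaccardDistance(table)
      else if (m == "braycurtis") brayCurtisDistance(table)
      else if (m == "uwunifrac")
        .distanceMatrix(.properNames(uf$unweighted, ids), "uwunifrac")
      else if (m == "wunifrac")
        .distanceMatrix(.properNames(uf$weighted, ids), "wunifrac")
      else if (grepl("^gunifrac:", m)) {
        a <- as.numeric(sub("^gunifrac:", "", m))
        .distanceMatrix(.properNames(uf$generalized[[match(a, alphas)]], ids),
                        "gunifrac", a)
      } else stop("unknown measure: ", m)
  }
  out
}

#' @describeIn ecologicalDistances the default seven-kernel candidate set.
#' @export
defaultKernelSet <- function() {
  c("jaccard", "braycurtis", "uwunifrac",
    "gunifrac:0.25", "gunifrac:0.5", "gunifrac:0.75", "wunifrac")
}

#' Convert a distance matrix to a positive semi-definite kernel
#'
#' Gower double-centering of the element-wise squared distances,
#' `K = -1/2 (I - 11'/n) D^2 (I - 11'/n)`, followed by eigenvalue
#' clipping: negative eigenvalues (possible for semimetrics such as
#' Bray-Curtis or Jaccard) are set to zero and the kernel reconstructed.
#' `psdClipped` records whether any materially negative eigenvalue was
#' removed.
#'
#' @param D a [DistanceMatrix-class] or a plain symmetric zero-diagonal
#'   matrix.
#' @param clipTol relative threshold below which a negative eigenvalue is
#'   considered material (default `1e-8` of the largest magnitude).
#' @return a [Kernel-class].
#' @export
distanceToKernel <- function(D, clipTol = 1e-8) {
  if (is(D, "DistanceMatrix")) {
    v <- values(D); lab <- D@measure; alpha <- D@alpha
  } else {
    v <- as.matrix(D); lab <- "user"; alpha <- NA_real_
    if (nrow(v) != ncol(v) || !isSymmetric(unname(v), tol = 1e-10))
      stop("distance matrix must be square and symmetric")
    if (any(diag(v) != 0)) stop("distance matrix must have zero diagonal")
  }
  A <- -0.5 * v^2
  K <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  lmax <- max(abs(e$values), 0)
  clipped <- lmax > 0 && any(e$values < -clipTol * lmax)
  lam <- pmax(e$values, 0)
  Kc <- e$vectors %*% (lam * t(e$vectors))
  Kc <- (Kc + t(Kc)) / 2
  dimnames(Kc) <- dimnames(v)
  new("Kernel", values = Kc, measure = lab, alpha = as.numeric(alpha),
      psdClipped = clipped)
}

#' @describeIn distanceToKernel compute the full kernel set from a count
#'   table (distances then Gower conversion).
#' @param table a [CountTable-class]; @param tree optional tree;
#' @param measures measure labels as in [ecologicalDistances()].
#' @export
ecologicalKernels <- function(table, tree = NULL,
                              measures = defaultKernelSet()) {
  lapply(ecologicalDistances(table, tree, measures), distanceToKernel)
}
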