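# Small fixtures built in code.

fixtureCounts <- function(n = 6, p = 8, seed = 1, total = 200) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = 5), n, p)
  m[m < 2] <- 0                       # some absences
  m[rowSums(m) == 0, 1] <- 1          # keep row sums positive
  countTable(m, sampleIDs = paste0("s", seq_len(n)),
             taxonIDs = paste0("t", seq_len(p)))
}

fixtureMeta <- function(n = 6, seed = 2, family = "gaussian",
                        ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  y <- if (family == "gaussian") rnorm(n) else rbinom(n, 1, 0.5)
  if (family == "binomial" && length(unique(y)) < 2) y[1] <- 1 - y[1]
  sampleMetadata(response = y, treatment = rbinom(n, 1, 0.5),
                 covariates = cbind(z = rnorm(n)), family = family,
                 sampleIDs = ids)
}

# random PSD matrix of given rank
fixturePSD <- function(n, rank = n, seed = 1) {
  set.seed(seed)
  P <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(P)
}

# distance matrix from Euclidean points (embeddable, no clipping needed)
fixtureEuclideanDist <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  as.matrix(dist(matrix(rnorm(n * d), n)))
}
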