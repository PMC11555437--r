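test_that("endogenous kernels obey the additivity and degenerate-treatment identities", {
  X <- scores(extractSurrogates(fixturePSD(9, seed = 71)))
  # T = 0: no interaction kernel; T = 1: K^I = K^M
  k0 <- buildEndogenousKernels(X, rep(0, 9))
  expect_equal(k0$I, matrix(0, 9, 9))
  expect_equal(k0$B, k0$M)
  k1 <- buildEndogenousKernels(X, rep(1, 9))
  expect_equal(k1$I, k1$M)
  expect_equal(k1$B, 2 * k1$M)
  # K^B additivity is exact and matches the concatenated gram matrix
  set.seed(72)
  tr <- rbinom(9, 1, 0.5)
  kk <- buildEndogenousKernels(X, tr)
  expect_identical(kk$B, kk$M + kk$I)
  conc <- tcrossprod(cbind(X, X * tr))
  expect_equal(kk$B, conc, tolerance = 1e-12)
  # all three PSD
  for (k in kk)
    expect_gt(min(eigen(k, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  expect_error(buildEndogenousKernels(X, rep(1, 5)), "mismatch")
})

test_that("score statistic is the quadratic form", {
  expect_equal(scoreStatistic(c(1, -1), diag(2)), 2)
  expect_equal(scoreStatistic(c(1, -1),
                              matrix(c(1, -1, -1, 1), 2, 2)), 4)
  expect_equal(scoreStatistic(c(0, 0), fixturePSD(2, seed = 1)), 0)
  expect_error(scoreStatistic(c(1, 2, 3), diag(2)), "dimension")
})

test_that("empirical p-values count the observed arrangement and ties", {
  # observed counts as one of the R + 1 arrangements
  expect_equal(empiricalPValue(5, c(1, 2, 3)), 1 / 4)
  expect_equal(empiricalPValue(0.5, c(1, 2, 3)), 1)
  expect_equal(empiricalPValue(2, c(1, 2, 2, 3)), 4 / 5)  # ties count
  expect_equal(empiricalPValue(2, c(1, 2, 3), "leq"), 3 / 4)
})

test_that("pooled p-values put every arrangement on the same footing", {
  # pool (2, 1, 2, 3): #\{>= x\}/4 per element
  expect_equal(pooledPValues(2, c(1, 2, 3)), c(0.75, 1, 0.75, 0.25))
  # ties: all equal values share the full count
  expect_equal(pooledPValues(2, c(2, 2)), c(1, 1, 1))
  x <- c(4, 1, 4, 2)
  naive <- sapply(seq_along(x), function(a)
    sum(x >= x[a]) / length(x))
  expect_equal(pooledPValues(x[1], x[-1]), naive)
  naive_leq <- sapply(seq_along(x), function(a)
    sum(x <= x[a]) / length(x))
  expect_equal(pooledPValues(x[1], x[-1], "leq"), naive_leq)
  # observed element reproduces empiricalPValue
  expect_equal(pooledPValues(2.5, c(1, 2, 3))[1],
               empiricalPValue(2.5, c(1, 2, 3)))
})

test_that("permutation plans are reproducible bijections; exhaustive is complete", {
  p1 <- permutationPlan(15, R = 50, seed = 81)
  p2 <- permutationPlan(15, R = 50, seed = 81)
  expect_identical(p1$perms, p2$perms)
  expect_true(all(apply(p1$perms, 2, function(z)
    identical(sort(z), 1:15))))
  ex <- permutationPlan(4, exhaustive = TRUE)
  expect_equal(ex$R, 24L)
  expect_equal(anyDuplicated(t(ex$perms)), 0L)
  expect_error(permutationPlan(9, exhaustive = TRUE), "n <= 8")
})

test_that("identity permutation reproduces observed statistics; constant residuals are invariant", {
  K <- fixturePSD(6, seed = 82)
  meta <- fixtureMeta(6, seed = 83)
  fit <- fitNullModel(meta)
  plan <- permutationPlan(6, R = 10, seed = 84)
  plan$perms[, 1] <- 1:6      # plant the identity
  res <- testSingleKernel(K, meta, plan = plan)
  expect_equal(res@statNull[1, ], res@statObs, tolerance = 1e-10)
  # constant residual vector: every permuted statistic identical
  X <- scores(extractSurrogates(K))
  st <- OmniK:::.engineStats(list(X), treatment(meta), rep(2, 6),
                             plan$perms)[[1]]
  expect_equal(max(st$null[, "M"]) - min(st$null[, "M"]), 0,
               tolerance = 1e-9 * max(st$null[, "M"]))
})

test_that("p-values are scale-invariant in the residuals", {
  K1 <- fixturePSD(12, seed = 85)
  K2 <- fixturePSD(12, rank = 5, seed = 86)
  meta <- fixtureMeta(12, seed = 87)
  fit <- fitNullModel(meta)
  plan <- permutationPlan(12, R = 200, seed = 88)
  Xl <- lapply(list(K1, K2), function(K) scores(extractSurrogates(K)))
  a <- OmniK:::.engineStats(Xl, treatment(meta), fit$residuals,
                            plan$perms)
  b <- OmniK:::.engineStats(Xl, treatment(meta), 7.3 * fit$residuals,
                            plan$perms)
  for (h in 1:2) {
    ca <- OmniK:::.calibrateKernel(a[[h]])
    cb <- OmniK:::.calibrateKernel(b[[h]])
    expect_equal(ca$p, cb$p)
    expect_equal(ca$pKernel, cb$pKernel)
  }
})

test_that("engine matches the brute-force oracle exactly on exhaustive n = 4", {
  set.seed(90)
  n <- 4
  K1 <- fixturePSD(4, seed = 91)
  D <- fixtureEuclideanDist(4, seed = 92)
  A <- -0.5 * D^2
  K2 <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  meta <- sampleMetadata(response = rnorm(4), treatment = c(0, 1, 1, 0),
                         covariates = cbind(z = rnorm(4)),
                         sampleIDs = as.character(1:4))
  fit <- fitNullModel(meta)
  plan <- permutationPlan(4, exhaustive = TRUE)
  res <- omniKFromKernels(list(k1 = K1, k2 = K2), meta, plan)
  # statistics agree with independent quadratic-form loops at float tol
  ost <- oracleStats(list(k1 = K1, k2 = K2), fit$residuals,
                     c(0, 1, 1, 0), plan$perms)
  for (h in 1:2) {
    expect_equal(res@results[[h]]@statObs, ost[[h]]$obs,
                 tolerance = 1e-10)
    expect_equal(res@results[[h]]@statNull, ost[[h]]$null,
                 tolerance = 1e-10)
  }
  # every p-value of the calibration pipeline matches the double-loop
  # reference exactly, on the shared statistic arrays
  orc <- oracleCalibrate(engineStatArrays(res))
  for (h in 1:2) {
    expect_identical(unname(res@results[[h]]@p),
                     unname(orc$perKernel[[h]]$p))
    expect_identical(unname(res@results[[h]]@pNull),
                     unname(orc$perKernel[[h]]$pNull))
    expect_identical(res@results[[h]]@pKernel,
                     orc$perKernel[[h]]$pKernel)
  }
  expect_identical(unname(res@pOmnibus), unname(orc$pOmni))
  expect_identical(res@tOverall, orc$tOverall)
  expect_identical(res@pOverall, orc$pOverall)
})
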