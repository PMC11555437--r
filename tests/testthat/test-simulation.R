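test_that("Dirichlet-multinomial rows sum to the total and are seed-reproducible", {
  par <- dmParameters(c(0.5, 0.3, 0.2), theta = 0.1)
  ct <- simulateCounts(par, n = 25, seed = 131)
  expect_true(all(rowSums(countData(ct)) == 10000))
  ct2 <- simulateCounts(par, n = 25, seed = 131)
  expect_identical(countData(ct), countData(ct2))
  expect_error(dmParameters(c(0.5, 0.5), theta = -0.1), "theta")
})

test_that("theta = 0 reduces to a plain multinomial (variance check)", {
  par <- dmParameters(c(0.6, 0.3, 0.1), theta = 0, totalCount = 300)
  ct <- simulateCounts(par, n = 2000, seed = 132)
  v <- apply(countData(ct), 2, var)
  vExp <- 300 * par@proportions * (1 - par@proportions)
  expect_lt(max(abs(v / vExp - 1)), 0.2)   # MC tolerance at n = 2000
})

test_that("method-of-moments recovers Dirichlet-multinomial parameters", {
  truth <- dmParameters(c(0.5, 0.3, 0.2), theta = 0.1,
                        totalCount = 2000)
  ct <- simulateCounts(truth, n = 1000, seed = 133)
  est <- estimateDMParams(ct)
  expect_equal(unname(est@proportions), truth@proportions, tolerance = 0.05)
  expect_equal(est@theta, 0.1, tolerance = 0.03)
  # multinomial data: theta estimate near zero
  ct0 <- simulateCounts(dmParameters(c(0.4, 0.4, 0.2), 0, 2000),
                        n = 500, seed = 134)
  expect_lt(estimateDMParams(ct0)@theta, 0.005)
  # identical proportion rows at huge depth: no overdispersion signal
  flat <- countTable(matrix(rep(c(5000, 3000, 2000), each = 10), 10, 3,
                            dimnames = list(paste0("s", 1:10),
                                            paste0("t", 1:3))))
  expect_equal(estimateDMParams(flat)@theta, 0)
  expect_error(estimateDMParams(
    countTable(matrix(1:2, 1, 2,
                      dimnames = list("a", c("x", "y"))))))
})

test_that("synthetic trees pair with simulated tables", {
  tr <- synthTree(10, seed = 135)
  expect_equal(sort(tr$tip.label), sort(paste0("t", 1:10)))
  expect_true(all(tr$edge.length >= 0))
  expect_true(ape::is.rooted(tr))
  d <- ape::cophenetic.phylo(tr)
  expect_true(isSymmetric(d) && all(d[upper.tri(d)] > 0))
  expect_identical(ape::write.tree(synthTree(10, seed = 135)),
                   ape::write.tree(tr))
  ct <- simulateCounts(defaultDMParams(10, seed = 136), n = 5)
  expect_setequal(taxonIDs(ct), tr$tip.label)
})

test_that("PAM effect clusters partition the leaves and find planted clades", {
  # two well-separated 3-leaf clades
  tr <- ape::read.tree(text =
    "((t1:0.1,(t2:0.1,t3:0.1):0.1):5,(t4:0.1,(t5:0.1,t6:0.1):0.1):5);")
  got <- lapply(1:2, function(k) pamEffectCluster(tr, 2, k))
  expect_setequal(sapply(got, length), c(3, 3))
  joint <- sort(unlist(got))
  expect_identical(joint, sort(tr$tip.label))
  # each cluster is one clade
  expect_true(setequal(got[[1]], c("t1", "t2", "t3")) ||
              setequal(got[[1]], c("t4", "t5", "t6")))
  # exhaustive 2-medoid search agrees on the induced partition
  D <- ape::cophenetic.phylo(tr)
  best <- NULL; bestCost <- Inf
  for (i in 1:5) for (j in (i + 1):6) {
    cost <- sum(pmin(D[, i], D[, j]))
    if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
  }
  assign <- apply(D[, best], 1, which.min)
  expect_equal(as.numeric(sort(table(assign))), c(3, 3))
  # k = leaves: singletons; clusters always partition
  tr2 <- synthTree(7, seed = 137)
  singles <- unlist(lapply(1:7, function(k) pamEffectCluster(tr2, 7, k)))
  expect_setequal(singles, tr2$tip.label)
  cl5 <- unlist(lapply(1:5, function(k) pamEffectCluster(tr2, 5, k)))
  expect_identical(sort(cl5), sort(tr2$tip.label))
  expect_error(pamEffectCluster(tr2, 5, 9), "out of range")
})

test_that("scenario constructor applies the canonical effect magnitudes", {
  expect_equal(simulationScenario(effect = "main_only")$beta1, 2)
  expect_equal(simulationScenario(effect = "main_only")$beta2, 0)
  expect_equal(simulationScenario(effect = "interaction_only")$beta2, 1)
  expect_equal(simulationScenario(effect = "interaction_only",
                                  family = "binomial")$beta2, 3)
  bo <- simulationScenario(effect = "both")
  expect_equal(c(bo$beta1, bo$beta2), c(2, -1))
  bob <- simulationScenario(effect = "both", family = "binomial")
  expect_equal(c(bob$beta1, bob$beta2), c(-1.5, 3))
  expect_equal(bo$alpha2, 1)
  expect_equal(bo$alpha3, 0.5)
})

test_that("design generator produces the stated covariate/treatment structure", {
  par <- defaultDMParams(50, seed = 138)
  sc_r <- simulationScenario(n = 2000, design = "rct")
  tab <- simulateCounts(par, 2000, seed = 139)
  meta_r <- generateDesign(tab, sc_r, seed = 140)
  expect_true(all(treatment(meta_r) %in% 0:1))
  expect_lt(abs(mean(treatment(meta_r)) - 0.5), 0.05)
  # randomized: T independent of z2
  expect_lt(abs(cor(treatment(meta_r), covariates(meta_r)[, "z2"])),
            0.06)
  # observational: T positively driven by the covariates
  sc_o <- simulationScenario(n = 2000, design = "observational")
  meta_o <- generateDesign(tab, sc_o, seed = 141)
  zsum <- rowSums(scale(covariates(meta_o)))
  expect_gt(cor(treatment(meta_o), zsum), 0.15)
  # z2 is correlated with the microbiome by construction
  expect_gt(sd(covariates(meta_r)[, "z2"]), 0.8)
})

test_that("effect transforms and the null scenario behave as declared", {
  # presence_absence of (0, 3, 1) is (0, 1, 1)
  m <- rbind(s1 = c(0, 3, 1), s2 = c(2, 0, 5))
  expect_identical(((m > 0) * 1)[1, ], c(0, 1, 1))
  # null scenario: response carries no count signal beyond covariates
  par <- defaultDMParams(30, seed = 142)
  tab <- simulateCounts(par, 100, seed = 143)
  sc <- simulationScenario(n = 100, effect = "null")
  meta <- generateDesign(tab, sc, seed = 144)
  fit <- lm(response(meta) ~ treatment(meta) + covariates(meta))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.5)   # alpha2 = 1
  # reproducibility
  meta2 <- generateDesign(tab, sc, seed = 144)
  expect_identical(response(meta), response(meta2))
})

test_that("experiment harness is reproducible and returns well-formed rates", {
  sc <- simulationScenario(n = 30, effect = "null")
  ex1 <- runExperiment(sc, reps = 4, perms = 60, seed = 145, p = 20,
                       measures = c("jaccard", "braycurtis"),
                       combiners = FALSE)
  ex2 <- runExperiment(sc, reps = 4, perms = 60, seed = 145, p = 20,
                       measures = c("jaccard", "braycurtis"),
                       combiners = FALSE)
  expect_identical(ex1$pvalues, ex2$pvalues)
  expect_true(all(ex1$rates$rate >= 0 & ex1$rates$rate <= 100))
  expect_identical(ex1$rates$method,
                   c("K_jaccard", "K_braycurtis", "OmniK_M", "OmniK_I",
                     "OmniK_B", "OmniK"))
  # extra df columns appear when requested
  ex3 <- runExperiment(sc, reps = 2, perms = 50, seed = 146, p = 20,
                       measures = c("jaccard", "braycurtis"),
                       dfs = list("full", 2), combiners = FALSE)
  expect_true("OmniK_df2" %in% colnames(ex3$pvalues))
})
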