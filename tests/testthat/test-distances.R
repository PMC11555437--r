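test_that("Jaccard distance matches the set formula", {
  # presence sets {t1,t2} vs {t2,t3}: 1 - 1/3 = 2/3
  m <- rbind(s1 = c(3, 1, 0), s2 = c(0, 5, 2))
  colnames(m) <- paste0("t", 1:3)
  d <- values(jaccardDistance(countTable(m)))
  expect_equal(d["s1", "s2"], 2 / 3)
  # identical samples -> 0; disjoint -> 1
  m2 <- rbind(a = c(1, 2, 0, 0), b = c(3, 9, 0, 0), c = c(0, 0, 1, 1))
  colnames(m2) <- paste0("t", 1:4)
  d2 <- values(jaccardDistance(countTable(m2)))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # cross-check against vegan's binary Jaccard on a random fixture
  ct <- fixtureCounts(8, 12, seed = 7)
  dv <- as.matrix(vegan::vegdist(countData(ct) > 0, "jaccard",
                                 binary = TRUE))
  expect_equal(unname(values(jaccardDistance(ct))), unname(dv),
               tolerance = 1e-12)
})

test_that("Bray-Curtis works on proportions and matches hand computation", {
  m <- rbind(s1 = c(1, 2, 0), s2 = c(2, 1, 0))
  colnames(m) <- paste0("t", 1:3)
  d <- values(brayCurtisDistance(countTable(m)))
  expect_equal(d["s1", "s2"], 1 / 3)
  # depth invariance: scaling one sample's counts changes nothing
  m2 <- m; m2["s2", ] <- m2["s2", ] * 10
  expect_equal(values(brayCurtisDistance(countTable(m2)))["s1", "s2"],
               1 / 3)
  m3 <- rbind(a = c(1, 2, 0, 0), b = c(1, 2, 0, 0), c = c(0, 0, 3, 1))
  colnames(m3) <- paste0("t", 1:4)
  d3 <- values(brayCurtisDistance(countTable(m3)))
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 1)
})

test_that("UniFrac distances behave on a star tree and identical samples", {
  # star tree with unit branches via a comb with zero internal branches
  tr <- ape::read.tree(text = "((t1:1,t2:1):0,t3:1):0;")
  m <- rbind(s1 = c(10, 0, 0), s2 = c(0, 10, 0), s3 = c(5, 5, 0))
  colnames(m) <- paste0("t", 1:3)
  ct <- countTable(m + 0)
  duw <- values(unifracDistance(ct, tr, "unweighted"))
  expect_equal(duw["s1", "s2"], 1)  # all observed branch length unique
  dw <- values(unifracDistance(ct, tr, "weighted"))
  expect_equal(dw["s1", "s2"], 1)
  # identical abundance vectors -> 0 under all variants
  m2 <- rbind(a = c(4, 2, 1), b = c(4, 2, 1), c = c(1, 0, 9))
  colnames(m2) <- paste0("t", 1:3)
  ct2 <- countTable(m2)
  for (v in c("unweighted", "weighted"))
    expect_equal(values(unifracDistance(ct2, tr, v))["a", "b"], 0)
  expect_equal(values(unifracDistance(ct2, tr, "generalized",
                                      alpha = 0.5))["a", "b"], 0)
  expect_error(unifracDistance(ct2, tr, "generalized", alpha = 1.5),
               "alpha")
})

test_that("generalized UniFrac at alpha = 1 equals normalized weighted", {
  ct <- fixtureCounts(10, 15, seed = 11)
  tr <- synthTree(15, seed = 12)
  g1 <- values(unifracDistance(ct, tr, "generalized", alpha = 1))
  w <- values(unifracDistance(ct, tr, "weighted"))
  expect_lt(max(abs(g1 - w)), 1e-10)
})

test_that("UniFrac agrees with the phyloseq reference implementation", {
  skip_if_not_installed("phyloseq")
  ct <- fixtureCounts(9, 14, seed = 21)
  tr <- synthTree(14, seed = 22)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(countData(ct)), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  ref_uw <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                       normalized = TRUE))
  ids <- sampleIDs(ct)
  expect_equal(unname(values(unifracDistance(ct, tr, "unweighted"))),
               unname(ref_uw[ids, ids]), tolerance = 1e-8)
  expect_equal(unname(values(unifracDistance(ct, tr, "weighted"))),
               unname(ref_w[ids, ids]), tolerance = 1e-8)
})

test_that("every distance matrix is symmetric, zero-diagonal, nonnegative", {
  ct <- fixtureCounts(7, 20, seed = 31)
  tr <- synthTree(20, seed = 32)
  ds <- ecologicalDistances(ct, tr)
  expect_named(ds, defaultKernelSet())
  for (d in ds) {
    v <- values(d)
    expect_true(isSymmetric(unname(v)))
    expect_true(all(diag(v) == 0))
    expect_true(all(v >= 0))
    expect_true(all(v <= 1 + 1e-12))
  }
})
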