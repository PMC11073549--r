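test_that("Spearman map handles ranks, ties and degenerate input", {
  a <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearmanMap(a, a), 1)
  expect_equal(spearmanMap(1:5, 5:1), -1)
  expect_equal(spearmanMap(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # invariant to strictly monotone transforms
  set.seed(71)
  for (r in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(spearmanMap(x, y), spearmanMap(exp(x), y^3 + 2 * y),
                 tolerance = 1e-12)
  }
  expect_error(spearmanMap(rep(1, 5), rnorm(5)), "constant")
})

test_that("Dice coefficient obeys its identities", {
  expect_equal(diceCoefficient(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(diceCoefficient(c(TRUE, TRUE), c(TRUE, TRUE)), 1)
  expect_equal(diceCoefficient(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(diceCoefficient(logical(4), logical(4)), 1)
  set.seed(73)
  for (r in 1:20) {
    a <- runif(40) > 0.5; b <- runif(40) > 0.5
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
    expect_gte(diceCoefficient(a, b), 0)
    expect_lte(diceCoefficient(a, b), 1)
  }
})

test_that("similarity-vs-n collapses at the full sample and on equal tasks", {
  set.seed(79)
  A <- matrix(rnorm(12 * 30, 0.4), 12, 30)
  B <- A + matrix(rnorm(12 * 30, sd = 0.3), 12, 30)
  full <- spearmanMap(oneSampleMap(A)@t, oneSampleMap(B)@t)
  cur <- similarityVsN(A, B, nGrid = c(5L, 12L), nRepeats = 5L, seed = 3L)
  expect_equal(cur$rhoMean[cur$n == 12L], full)
  expect_equal(cur$rhoSd[cur$n == 12L], 0)
  # identical tasks: rho = 1 at every n
  curI <- similarityVsN(A, A, nGrid = c(4L, 8L), nRepeats = 3L, seed = 4L)
  expect_true(all(curI$rhoMean == 1) && all(curI$rhoSd == 0))
  expect_error(similarityVsN(A, B, nGrid = 2L), ">= 3")
})

test_that("edge subsampling reproduces the full-map similarity", {
  set.seed(83)
  a <- rnorm(500); b <- a + rnorm(500)
  full <- spearmanMap(a, b)
  # k = all edges: every subsample equals the full map
  rs <- edgeSubsampleSimilarity(a, b, k = 500L, nReps = 5L, seed = 5L)
  expect_equal(rs, rep(full, 5L))
  expect_true(all(edgeSubsampleSimilarity(a, a, 50L, 20L, seed = 6L) == 1))
  # subsample mean consistent with the full-map value
  rs2 <- edgeSubsampleSimilarity(a, b, k = 100L, nReps = 400L, seed = 7L)
  expect_lt(abs(mean(rs2) - full), 3 * sd(rs2) / sqrt(400) + 0.02)
})

test_that("region-wise profiles are the off-diagonal rows of the edge map", {
  idx <- edgeIndex(4L)
  mapA <- c(1, 2, 3, 4, 5, 6)   # edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  mapB <- c(2, 1, 4, 3, 6, 5)
  rs <- regionwiseSimilarity(mapA, mapB, idx)
  # hand profile for region 1: A = (1,2,3) vs B = (2,1,4)
  expect_equal(rs[1L], cor(c(1, 2, 3), c(2, 1, 4), method = "spearman"))
  expect_equal(rs[4L], cor(c(3, 5, 6), c(4, 6, 5), method = "spearman"))
  expect_true(all(regionwiseSimilarity(mapA, mapA, idx) == 1))
  # 268 regions: profile vectors have 267 entries
  idx268 <- edgeIndex(268L)
  set.seed(89)
  m1 <- rnorm(nEdges(idx268)); m2 <- m1 + rnorm(nEdges(idx268))
  rs268 <- regionwiseSimilarity(m1, m2, idx268)
  expect_length(rs268, 268L)
  M1 <- matrix(0, 268, 268); M1[edgePairs(idx268)] <- m1
  M1[edgePairs(idx268)[, 2:1]] <- m1
  M2 <- matrix(0, 268, 268); M2[edgePairs(idx268)] <- m2
  M2[edgePairs(idx268)[, 2:1]] <- m2
  expect_length(M1[10, -10], 267L)
  expect_equal(rs268[10L],
               cor(M1[10, -10], M2[10, -10], method = "spearman"))
})

test_that("subject-level similarity compares activation and network maps", {
  set.seed(97)
  ns <- 10L
  sharedAct <- matrix(rnorm(ns * 30), ns, 30)
  actA <- sharedAct + matrix(rnorm(ns * 30, sd = 0.2), ns, 30)
  actB <- sharedAct + matrix(rnorm(ns * 30, sd = 0.2), ns, 30)
  netA <- matrix(rnorm(ns * 100), ns, 100)
  netB <- matrix(rnorm(ns * 100), ns, 100)
  res <- subjectLevelSimilarity(actA, actB, netA, netB)
  expect_gt(res$meanActivationRho, res$meanNetworkRho)
  expect_lt(res$p, 0.05)
  expect_equal(res$df, ns - 1L)
  # Cohen's d equals the brute-force mean/sd of the paired differences
  dd <- res$activationRho - res$networkRho
  expect_equal(res$cohensD, mean(dd) / sd(dd), tolerance = 1e-12)
  expect_equal(res$pairedT, mean(dd) / (sd(dd) / sqrt(ns)),
               tolerance = 1e-12)
  # degenerate: identical maps across tasks -> rho 1, zero-variance sentinel
  expect_warning(
    resI <- subjectLevelSimilarity(actA, actA, netA, netA),
    "zero variance")
  expect_true(all(resI$activationRho == 1) && all(resI$networkRho == 1))
  expect_equal(resI$pairedT, 0)
})

test_that("Mantel test: identity, null calibration, relabeling invariance", {
  set.seed(101)
  maps <- matrix(rnorm(15 * 40), 15, 40)
  D <- subjectDistances(maps)
  expect_true(isSymmetric(D) && all(diag(D) == 0))
  res <- mantelTest(D, D, nPerm = 199L, nResample = 50L, seed = 9L)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  # joint relabeling leaves r unchanged
  D2 <- subjectDistances(matrix(rnorm(15 * 40), 15, 40))
  perm <- sample(15L)
  r0 <- mantelTest(D, D2, nPerm = 99L, nResample = 20L, seed = 10L)$r
  r1 <- mantelTest(D[perm, perm], D2[perm, perm], nPerm = 99L,
                   nResample = 20L, seed = 10L)$r
  expect_equal(r0, r1, tolerance = 1e-12)
  # permutation p approximately uniform under independence
  set.seed(11)
  ps <- replicate(120L, {
    A <- subjectDistances(matrix(rnorm(10 * 20), 10, 20))
    B <- subjectDistances(matrix(rnorm(10 * 20), 10, 20))
    mantelTest(A, B, nPerm = 99L, nResample = 10L,
               seed = sample.int(1e6, 1L))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(mantelTest(D[1:3, 1:3], D[1:3, 1:3]), "at least 4")
})

test_that("SNR filter retains elements above threshold in every task", {
  set.seed(103)
  # contrasts drawn N(d * sigma, sigma^2) with d = 1: estimated SNR near 1
  M <- matrix(rnorm(200 * 50, mean = 2, sd = 2), 200, 50)
  res <- snrFilter(M, threshold = 0.5)
  expect_lt(abs(res$median - 1), 0.2)
  # zero-mean contrast: nothing retained
  M0 <- matrix(rnorm(50 * 20), 50, 20)
  res0 <- snrFilter(M0, threshold = 0.5)
  expect_length(res0$retained, 0L)
  # disjoint high-SNR sets across two tasks: empty intersection
  A <- cbind(matrix(rnorm(30 * 5, 3), 30, 5), matrix(rnorm(30 * 5), 30, 5))
  B <- cbind(matrix(rnorm(30 * 5), 30, 5), matrix(rnorm(30 * 5, 3), 30, 5))
  resAB <- snrFilter(list(A = A, B = B), threshold = 0.5)
  expect_length(resAB$retained, 0L)
})

test_that("activation filter retains jointly strong regions", {
  set.seed(107)
  base <- matrix(rnorm(30 * 6, 0, 1), 30, 6)
  base[, 3L] <- base[, 3L] + 2   # |d| ~ 2 in both tasks
  A <- base + matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
  B <- base + matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
  keep <- activationFilter(list(A = A, B = B), dThreshold = 0.8)
  expect_true(3L %in% keep)
  expect_length(activationFilter(list(A = A, B = B), dThreshold = Inf), 0L)
  expect_equal(activationFilter(list(A = A, B = B), dThreshold = -1),
               1:6, ignore_attr = TRUE)
})
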