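test_that("one-sample map matches t.test and handles degenerate elements", {
  set.seed(41)
  M <- matrix(rnorm(20 * 5, 0.3), 20, 5)
  g <- oneSampleMap(M, correction = "none")
  for (k in 1:5) {
    ref <- t.test(M[, k])
    expect_equal(g@t[k], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(g@p[k], ref$p.value, tolerance = 1e-10)
  }
  # all-zero element: t = 0, p = 1
  M0 <- cbind(M, zero = 0)
  g0 <- oneSampleMap(M0, correction = "none")
  expect_equal(g0@t[6L], 0)
  expect_equal(g0@p[6L], 1)
  expect_equal(g0@dof, 19)
})

test_that("one-sample power tracks the noncentral-t closed form", {
  set.seed(43)
  n <- 30L; nel <- 2000L; delta <- 0.5
  M <- matrix(rnorm(n * nel, mean = delta), n, nel)
  g <- oneSampleMap(M, correction = "none")
  emp <- mean(g@p < 0.05)
  tc <- qt(0.975, n - 1L)
  ncp <- delta * sqrt(n)
  closed <- pt(-tc, n - 1L, ncp = ncp) + 1 - pt(tc, n - 1L, ncp = ncp)
  expect_lt(abs(emp - closed), 0.03)
})

test_that("one-sample type-I rate is nominal under the null", {
  set.seed(47)
  g <- oneSampleMap(matrix(rnorm(15 * 10000L), 15, 10000L),
                    correction = "none")
  rate <- mean(g@p < 0.05)
  expect_gt(rate, 0.04); expect_lt(rate, 0.06)
})

test_that("paired map is the one-sample map of differences", {
  set.seed(53)
  A <- matrix(rnorm(60), 12, 5); B <- matrix(rnorm(60), 12, 5)
  gp <- pairedMap(A, B, correction = "none")
  g1 <- oneSampleMap(A - B, correction = "none")
  expect_equal(gp@t, g1@t)
  expect_equal(gp@p, g1@p)
  # identical inputs: all t = 0
  expect_true(all(pairedMap(A, A, correction = "none")@t == 0))
  # constant shift recovered as the mean effect
  gs <- pairedMap(A + 0.7, A, correction = "none")
  expect_equal(gs@effect, rep(0.7, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  rownames(B) <- paste0("s", 1:12)
  A2 <- A; rownames(A2) <- paste0("x", 1:12)
  expect_error(pairedMap(A2, B, correction = "none"), "same subjects")
})

test_that("Holm procedure rejects per the step-down sequence", {
  expect_equal(holmMask(c(0.01, 0.02, 0.04), 0.05), rep(TRUE, 3))
  expect_equal(holmMask(c(0.03), 0.05), TRUE)
  expect_equal(holmMask(c(0.03, 0.04), 0.05), c(FALSE, FALSE))
})

test_that("BH procedure rejects per the step-up thresholds", {
  expect_equal(bhMask(c(0.01, 0.02, 0.2), 0.05), c(TRUE, TRUE, FALSE))
  expect_false(any(bhMask(rep(1, 10), 0.05)))
})

test_that("Holm controls FWER and BH controls FDR on global nulls", {
  set.seed(59)
  nrep <- 1000L; nel <- 200L
  fwe <- 0L; fdrsum <- 0
  for (r in seq_len(nrep)) {
    p <- runif(nel)
    if (any(holmMask(p, 0.05))) fwe <- fwe + 1L
    nrej <- sum(bhMask(p, 0.05))
    if (nrej > 0) fdrsum <- fdrsum + 1  # all rejections false under null
  }
  mc <- 2 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(fwe / nrep, 0.05 + mc)
  expect_lte(fdrsum / nrep, 0.05 + mc)
})

test_that("Holm is between Bonferroni and BH in rejections", {
  set.seed(61)
  for (r in 1:500) {
    m <- sample(3:40, 1L)
    p <- runif(m)^sample(1:3, 1L)
    bonf <- p <= 0.05 / m
    holm <- holmMask(p, 0.05)
    bh <- bhMask(p, 0.05)
    expect_true(all(holm[bonf]))   # Holm rejects a superset of Bonferroni
    expect_true(all(bh[holm]))     # and a subset of BH
  }
})

test_that("t-to-r transform follows the printed formula", {
  expect_equal(tToR(0, 10), 0)
  expect_equal(tToR(3, 10), sqrt(0.5))
  expect_equal(tToR(-3, 10), -sqrt(0.5))
  # identity r^2 + (N - 1)/(t^2 + N - 1) = 1 on a grid
  for (N in c(2, 10, 242)) {
    t <- seq(-20, 20, by = 0.5)
    r <- tToR(t, N)
    expect_equal(r^2 + (N - 1) / (t^2 + N - 1), rep(1, length(t)),
                 tolerance = 1e-12)
  }
  # odd, strictly increasing, saturating at +/-1
  t <- seq(-50, 50, by = 0.25)
  r <- tToR(t, 20)
  expect_equal(r, -tToR(-t, 20))
  expect_true(all(diff(r) > 0))
  expect_lt(abs(tToR(1e8, 20) - 1), 1e-10)
})

test_that("top-fraction sign test reproduces hand-computed tables", {
  # construct maps whose top 8 elements have signs giving [[3,1],[1,3]]
  tA <- c(9, 8, 7, -6, 5, -4, 3, -2, rep(0.1, 792))
  tB <- c(-9, 8, -7, -6, 5, 4, -3, 2, rep(0.1, 792))
  resA <- topFractionSignTest(tA, tB, fraction = 0.01)
  expect_equal(resA$k, 8L)
  expect_equal(unname(resA$table["mapA", ]), c(5, 3))
  # a 2x2 with cells [[3,1],[1,3]]: OR = 9, p via enumeration oracle
  t1 <- c(1, 2, 3, -4); t2 <- c(1, -2, -3, -4)
  res <- topFractionSignTest(t1, t2, fraction = 1)
  expect_equal(unname(res$table), rbind(c(3, 1), c(1, 3)))
  expect_equal(res$oddsRatio, 9)
  # enumeration oracle: hypergeometric masses <= observed, fixed margins
  obs <- dhyper(3, 4, 4, 4)
  pref <- sum(dhyper(0:4, 4, 4, 4)[dhyper(0:4, 4, 4, 4) <= obs + 1e-12])
  expect_equal(res$p, pref, tolerance = 1e-12)
  # identical maps with balanced signs: p = 1
  tb <- c(5, -5, 4, -4)
  resb <- topFractionSignTest(tb, tb, fraction = 1)
  expect_equal(resb$p, 1)
})

test_that("system summaries count and normalize significant edges", {
  idx <- edgeIndex(4L)
  systems <- c("A", "A", "B", "B")
  # edges: (1,2) within A, (3,4) within B significant
  mask <- logical(6L)
  mask[pairToPos(idx, 1L, 2L)] <- TRUE
  mask[pairToPos(idx, 3L, 4L)] <- TRUE
  ss <- systemSummaries(mask, idx, systems)
  expect_equal(unname(ss$degree), c(1L, 1L, 1L, 1L))
  expect_equal(ss$normalized["A", "A"], 1)   # 1 of 1 within-A edge
  expect_equal(ss$normalized["B", "B"], 1)
  expect_equal(ss$normalized["A", "B"], 0)   # 0 of 4 between edges
  # degenerate masks
  ss0 <- systemSummaries(rep(FALSE, 6L), idx, systems)
  expect_true(all(ss0$degree == 0) && all(ss0$normalized == 0))
  ss1 <- systemSummaries(rep(TRUE, 6L), idx, systems)
  expect_true(all(ss1$normalized == 1))
  expect_error(systemSummaries(mask, idx, c("A", NA, "B", "B")),
               "nlabeled")
})

test_that("group one-sample t equals an intercept-only GLM over subjects", {
  set.seed(67)
  M <- matrix(rnorm(25 * 4, 0.2), 25, 4)
  g <- oneSampleMap(M, correction = "none")
  sm <- glmContrast(glmFit(M, interceptDesign(25L)), 1)
  expect_equal(g@t, sm@t, tolerance = 1e-10)
})
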