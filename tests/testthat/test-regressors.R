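test_that("HRF triplet matches the sampled double-gamma kernel", {
  # unit impulse (one stimulus frame) at t = 0: main column = kernel samples
  td <- taskDesign(data.frame(condition = "c", onset = 0, duration = 2),
                   nFrames = 17L, tr = 2)
  main <- hrfTriplet(td, "c")[, 1L]
  expect_equal(main, refHrfKernel(seq(0, 32, by = 2)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # sampled peak within one TR of the numerically located analytic peak
  analyticPeak <- optimize(function(t) refHrfKernel(t),
                           interval = c(0, 15), maximum = TRUE)$maximum
  samplePeak <- (which.max(main) - 1L) * 2
  expect_lte(abs(samplePeak - analyticPeak), 2)
  # condition with zero blocks: all three columns zero
  tz <- taskDesign(data.frame(condition = "other", onset = 0, duration = 2),
                   nFrames = 17L, tr = 2)
  trip <- hrfTriplet(tz, "c", knownConditions = "c")
  expect_true(all(trip == 0))
  expect_error(hrfTriplet(td, "nonexistent"), "unknown condition")
})

test_that("boxcar variant uses half-open [onset, onset + duration) frames", {
  td <- taskDesign(data.frame(condition = "c", onset = 10, duration = 20),
                   nFrames = 40L, tr = 2)
  bx <- hrfTriplet(td, "c", hrf = "boxcar")[, 1L]
  expect_equal(which(bx == 1), 6:15)  # 0-based frames 5..14
  expect_true(all(bx[-(6:15)] == 0))
})

test_that("HRF convolution is linear over disjoint block sets", {
  dA <- taskDesign(data.frame(condition = "c", onset = 10, duration = 30),
                   nFrames = 120L, tr = 2)
  dB <- taskDesign(data.frame(condition = "c", onset = 100, duration = 40),
                   nFrames = 120L, tr = 2)
  dAB <- taskDesign(data.frame(condition = c("c", "c"),
                               onset = c(10, 100), duration = c(30, 40)),
                    nFrames = 120L, tr = 2)
  expect_equal(hrfTriplet(dA, "c") + hrfTriplet(dB, "c"),
               hrfTriplet(dAB, "c"), tolerance = 1e-10)
})

test_that("FIR basis is the set of lagged stimulus indicators", {
  td <- makeTaskDesign()
  expect_equal(ncol(firBasis(td, nLags = 12L)), 24L)
  # single stimulus frame at t = 0: column k has one 1 at frame k + 1
  imp <- taskDesign(data.frame(condition = "c", onset = 0, duration = 2),
                    nFrames = 10L, tr = 2)
  fb <- firBasis(imp, nLags = 3L)
  for (k in 0:2) expect_equal(which(fb[, k + 1L] == 1), k + 1L)
  # block on 0-based frames 4..6, two lags
  blk <- taskDesign(data.frame(condition = "c", onset = 8, duration = 6),
                    nFrames = 12L, tr = 2)
  fb2 <- firBasis(blk, nLags = 2L)
  expect_equal(which(fb2[, 1L] == 1), 5:7)
  expect_equal(which(fb2[, 2L] == 1), 6:8)
})

test_that("FIR columns conserve total stimulus mass for interior events", {
  blk <- taskDesign(data.frame(condition = "c", onset = 20, duration = 10),
                    nFrames = 100L, tr = 2)
  nL <- 6L
  fb <- firBasis(blk, nLags = nL)
  expect_equal(sum(fb), nL * 5)  # 5 stimulus frames, far from run end
})

test_that("cosine basis has the documented counts and monotonicity", {
  expect_equal(ncol(cosineBasis(280L, 2, 187)), 5L)
  expect_equal(ncol(cosineBasis(100L, 2, 1e9)), 0L)
  expect_equal(ncol(cosineBasis(100L, 2, 100)), 3L)
  # unit norm
  cb <- cosineBasis(280L, 2, 187)
  expect_equal(colSums(cb^2), rep(1, 5L), ignore_attr = TRUE)
  # monotone in cutoff (non-increasing) and in run length (non-decreasing)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(50:400, 1L); tr <- runif(1L, 0.5, 3)
    cuts <- sort(runif(2L, 20, 500))
    expect_gte(ncol(cosineBasis(n, tr, cuts[1L])),
               ncol(cosineBasis(n, tr, cuts[2L])))
    expect_lte(ncol(cosineBasis(n, tr, cuts[1L])),
               ncol(cosineBasis(n + 50L, tr, cuts[1L])))
  }
})

test_that("motion expansion yields the ordered 24-parameter set", {
  m <- matrix(rnorm(30), 5L, 6L)
  em <- expandMotion(m)
  expect_equal(ncol(em), 24L)
  # constant column: derivative all zero
  m2 <- m; m2[, 3L] <- 1
  expect_true(all(expandMotion(m2)[, 9L] == 0))
  # hand arithmetic on [0, 1, 3]
  m3 <- cbind(c(0, 1, 3), matrix(0, 3L, 5L)) + 0
  m3[, 2:6] <- rnorm(15)
  em3 <- expandMotion(m3)
  expect_equal(em3[, 7L], c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(em3[, 13L], c(0, 1, 9), ignore_attr = TRUE)
  expect_equal(em3[, 19L], c(0, 1, 4), ignore_attr = TRUE)
  expect_error(expandMotion(m[, 1:5]), "6 columns")
})

test_that("design presets assemble the documented column blocks", {
  td <- makeTaskDesign()
  conf <- makeConfounds(280L)
  den <- denoiseDesign(td, conf)
  expect_equal(ncol(signalValues(den)), 57L)  # 24 FIR + 24 + 3 + 5 + 1
  expect_equal(sum(designRoles(den) == "fir"), 24L)
  expect_equal(ncol(signalValues(edgeDesign(td))), 7L)
  expect_equal(ncol(signalValues(activationDesign(td, conf))), 39L)
  # gsr toggle drops exactly the global column
  expect_equal(ncol(signalValues(denoiseDesign(td, conf, gsr = FALSE))), 56L)
  # intercept-only
  io <- interceptDesign(10L)
  expect_equal(signalValues(io), matrix(1, 10L, 1L,
                                        dimnames = list(NULL, "intercept")))
  # frame mismatch and duplicate names are rejected
  expect_error(buildDesign(list(motion = matrix(1, 5L, 1L),
                                cosine = matrix(1, 6L, 1L))),
               "frame count mismatch")
  dup <- matrix(rnorm(10), 5L, 2L, dimnames = list(NULL, c("a", "a")))
  expect_error(buildDesign(list(motion = dup)), "duplicate")
})
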