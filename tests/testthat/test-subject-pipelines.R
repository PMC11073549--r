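# Small task cohorts for pipeline checks (generated fresh, fixed seeds).
smallCohort <- function(nSubjects = 4L, nRegions = 16L, seed = 77L,
                        deltaMagnitude = 0.3, dissociation = FALSE) {
  cfg <- cohortConfig(nSubjects = nSubjects, nRegions = nRegions,
                      nDeltaEdges = 12L, deltaMagnitude = deltaMagnitude,
                      dissociation = dissociation, seed = seed)
  list(config = cfg, cohort = suppressWarnings(generateCohort(cfg)))
}

test_that("denoising residuals are orthogonal to the nuisance design", {
  sc <- smallCohort()
  run <- sc$cohort$taskA[[1L]]
  cfg <- pipelineConfig()
  den <- denoiseRun(run, cfg)
  X <- signalValues(denoiseDesign(run@design, run@confounds,
                                  removeTask = TRUE))
  dots <- crossprod(X, signalValues(den))
  norms <- outer(sqrt(colSums(X^2)), sqrt(colSums(signalValues(den)^2)))
  expect_lt(max(abs(dots) / norms), 1e-8)
  # a parcel equal to a confound column is annihilated
  run2 <- run
  vals <- signalValues(run@parcels)
  vals[, 1L] <- run@confounds$csf
  run2@parcels <- parcelSeries(vals, tr = repTime(run@parcels))
  den2 <- denoiseRun(run2, cfg)
  expect_lt(max(abs(signalValues(den2)[, 1L])), 1e-10)
})

test_that("task removal suppresses the evoked waveform in the residuals", {
  sc <- smallCohort(seed = 78L)
  run <- sc$cohort$taskA[[1L]]
  evoked <- edgets:::.convolve_hrf(
    edgets:::.boxcar(run@design, "incongruent"), 2, nFrames(run@parcels)) -
    edgets:::.convolve_hrf(
      edgets:::.boxcar(run@design, "congruent"), 2, nFrames(run@parcels))
  den <- denoiseRun(run, pipelineConfig(removeTask = TRUE))
  cors <- abs(cor(evoked, signalValues(den)))
  expect_lt(median(cors), 0.05)
  # keeping task effects leaves the waveform detectable
  denKeep <- denoiseRun(run, pipelineConfig(removeTask = FALSE))
  corsKeep <- abs(cor(evoked, signalValues(denKeep)))
  expect_gt(max(corsKeep), max(cors))
})

test_that("activation GLM recovers a planted amplitude difference", {
  set.seed(111)
  n <- 280L
  td <- makeTaskDesign(n)
  conf <- makeConfounds(n, seed = 112L)
  conf$global_signal <- rnorm(n)  # independent of the planted signal
  delta <- 1.2
  evoked <- edgets:::.convolve_hrf(edgets:::.boxcar(td, "incongruent"),
                                   2, n) * delta
  Y <- matrix(rnorm(n * 20L), n, 20L)
  Y[, 7L] <- Y[, 7L] + evoked
  run <- subjectRun(parcelSeries(Y, tr = 2), design = td, confounds = conf)
  res <- runActivationGLM(run)
  se <- abs(res$map@effect[7L] / res$map@t[7L])
  expect_lt(abs(res$map@effect[7L] - delta), 3 * se)
  expect_gt(abs(res$map@effect[7L]), median(abs(res$map@effect[-7L])))
})

test_that("node GLM type-I rate is nominal on pure noise", {
  set.seed(113)
  n <- 280L
  td <- makeTaskDesign(n)
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    conf <- makeConfounds(n, seed = 113L + s)
    run <- subjectRun(parcelSeries(matrix(rnorm(n * 40L), n, 40L), tr = 2),
                      design = td, confounds = conf)
    res <- runActivationGLM(run)
    crit <- qt(0.975, res$map@dof)
    hits <- hits + sum(abs(res$map@t) > crit)
    total <- total + 40L
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})

test_that("rest edge GLM intercept equals (T-1)/T times Pearson r", {
  sc <- smallCohort(seed = 79L)
  run <- sc$cohort$rest[[1L]]
  cfg <- pipelineConfig(prewhiten = FALSE)
  eg <- runEdgeGLM(run, cfg)
  Z <- standardizeSeries(signalValues(denoiseRun(run, cfg)))
  Tn <- nrow(Z)
  R <- cor(Z)
  pr <- edgePairs(eg$edges)
  ref <- (Tn - 1) / Tn * R[pr]
  expect_equal(eg$intercept@effect, ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("edge GLM ranks planted covariance edges above null edges", {
  sc <- smallCohort(nSubjects = 8L, seed = 80L)
  betas <- t(vapply(sc$cohort$taskA, function(run)
    runEdgeGLM(run)$contrast@effect,
    numeric(16L * 15L / 2L)))
  g <- oneSampleMap(betas, correction = "none")
  planted <- sc$cohort$truth$deltaEdges$taskA
  wt <- wilcox.test(g@t[planted], g@t[-planted], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("a condition absent from the run is a labeled design error", {
  sc <- smallCohort(seed = 81L)
  run <- sc$cohort$taskA[[1L]]
  b <- taskBlocks(run@design)
  oneCond <- taskDesign(b[b$condition == "congruent", ],
                        nFrames = nFrames(run@parcels), tr = 2)
  run@design <- oneCond
  expect_error(runEdgeGLM(run), "absent|rank|collinear")
})

test_that("gPPI output is symmetric and concordant with the edge GLM", {
  sc <- smallCohort(nSubjects = 3L, seed = 82L)
  gp <- runGPPI(sc$cohort$taskA[[1L]])
  M <- gppiMatrix(gp)
  expect_identical(M, t(M))
  expect_equal(nrow(gp$skipped), 0L)
  # concordance with the edge-GLM contrast on modulated data (avg of 3)
  gAvg <- gp$contrast
  eAvg <- runEdgeGLM(sc$cohort$taskA[[1L]])$contrast@effect
  for (s in 2:3) {
    gAvg <- gAvg + runGPPI(sc$cohort$taskA[[s]])$contrast
    eAvg <- eAvg + runEdgeGLM(sc$cohort$taskA[[s]])$contrast@effect
  }
  ct <- cor.test(gAvg, eAvg, method = "spearman", exact = FALSE,
                 alternative = "greater")
  expect_lt(ct$p.value, 0.01)
})

test_that("gPPI interaction contrast is centered under no modulation", {
  sc <- smallCohort(nSubjects = 6L, deltaMagnitude = 0, seed = 83L)
  cons <- vapply(sc$cohort$taskA, function(run) mean(runGPPI(run)$contrast),
                 numeric(1L))
  mcse <- sd(cons) / sqrt(length(cons))
  expect_lt(abs(mean(cons)), 3 * mcse + 1e-3)
})

test_that("pipelines are deterministic and sensitive to the GSR toggle", {
  sc1 <- smallCohort(seed = 84L)
  sc2 <- smallCohort(seed = 84L)
  expect_identical(signalValues(sc1$cohort$taskA[[1L]]@parcels),
                   signalValues(sc2$cohort$taskA[[1L]]@parcels))
  e1 <- runEdgeGLM(sc1$cohort$taskA[[1L]])
  e2 <- runEdgeGLM(sc2$cohort$taskA[[1L]])
  expect_identical(e1$contrast@effect, e2$contrast@effect)
  eNoGsr <- runEdgeGLM(sc1$cohort$taskA[[1L]], pipelineConfig(gsr = FALSE))
  expect_false(identical(e1$contrast@effect, eNoGsr$contrast@effect))
})
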