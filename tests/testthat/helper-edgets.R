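# Shared fixtures, all generated in code.

# white-noise confound table with the canonical fMRIPrep column names
makeConfounds <- function(n, seed = 99L) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * 9L), n, 9L))
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                 "white_matter", "csf", "global_signal")
  df
}

# two-condition block design: incongruent first, 56-s blocks, 14-s fixation
makeTaskDesign <- function(nFrames = 280L, tr = 2) {
  onsets <- 14 + (0:7) * 70
  taskDesign(data.frame(
    condition = rep(c("incongruent", "congruent"), 4L),
    onset = onsets, duration = rep(56, 8L)), nFrames = nFrames, tr = tr)
}

# the reference double-gamma kernel, written out independently of the
# package internals: gamma(shape 6, scale 1) minus gamma(16, 1)/6,
# normalized to unit sum on the TR grid over the 32-s support
refHrfKernel <- function(t, tr = 2) {
  raw <- function(u) ifelse(u < 0, 0,
    dgamma(u, shape = 6, scale = 1) - dgamma(u, shape = 16, scale = 1) / 6)
  t0 <- seq(0, 32, by = tr)
  raw(t) / sum(raw(t0))
}

# memoised dissociation cohort + full comparison, shared by the heavier
# acceptance checks (n = 20 subjects, P = 40 regions, T = 280 frames)
.fixture_env <- new.env(parent = emptyenv())

fixtureCohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohortConfig(seed = 2024L)
    .fixture_env$config <- cfg
    .fixture_env$cohort <- suppressWarnings(generateCohort(cfg))
  }
  list(config = .fixture_env$config, cohort = .fixture_env$cohort)
}

fixtureComparison <- function() {
  if (is.null(.fixture_env$cmp)) {
    fx <- fixtureCohort()
    .fixture_env$cmp <- compareTasks(fx$cohort)
  }
  .fixture_env$cmp
}
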