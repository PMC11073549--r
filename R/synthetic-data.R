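## Synthetic multi-subject block-design BOLD cohorts with known ground
## truth: modular intrinsic covariance, condition-dependent covariance
## modulation, HRF-convolved evoked means, AR(1) temporal noise and
## nuisance confounds. The generator writes the same objects the pipeline
## consumes, so end-to-end recovery tests exercise the real estimation
## path.

#' Cohort generator configuration
#'
#' Study conditions emulated by default: 280-frame task runs at TR = 2 s
#' with four congruent and four incongruent blocks of 52-60 s separated by
#' 10-17-s fixation periods (incongruent block first), a 150-frame (5-min)
#' rest run, a modular intrinsic covariance over `nSystems` systems, an
#' AR(1) noise coefficient of 0.4, HRF-convolved evoked mean responses,
#' and condition-specific covariance increments on a planted edge set.
#'
#' In dissociation mode (`dissociation = TRUE`, the default) the two tasks
#' share identical evoked amplitude vectors but carry disjoint planted
#' covariance-modulation edge sets: activation patterns agree between
#' tasks while network modulation does not.
#'
#' @param nSubjects number of subjects (default 20)
#' @param nRegions number of regions (default 40)
#' @param nSystems number of intrinsic systems (default 4)
#' @param tr repetition time in seconds (default 2)
#' @param taskFrames frames per task run (default 280)
#' @param restFrames frames per rest run (default 150; 5 min at TR 2)
#' @param nBlocks blocks per condition (default 4)
#' @param blockRange block duration range in seconds (default c(52, 60))
#' @param fixationRange fixation duration range in seconds (default
#'   c(10, 17))
#' @param firstCondition condition of the first block (default
#'   "incongruent", matching yoked administration)
#' @param withinCor,betweenCor intrinsic correlation within / between
#'   systems (defaults 0.35, 0.05)
#' @param deltaMagnitude covariance increment on planted edges during the
#'   modulated condition, correlation scale (default 0.3)
#' @param nDeltaEdges number of planted edges per task (default 40)
#' @param deltaCondition the modulated condition (default "incongruent")
#' @param amplitudeSd sd of the per-region baseline evoked amplitude,
#'   in noise-sd units (default 1)
#' @param contrastSd sd of the per-region incongruent-minus-congruent
#'   amplitude difference (default 0.5)
#' @param rho AR(1) coefficient of the noise (default 0.4)
#' @param confoundAmplitude leakage scale of the nuisance series into the
#'   regional signals (default 0.1)
#' @param hrfGated gate the covariance modulation by the HRF-convolved
#'   (instead of raw) condition boxcar (default FALSE)
#' @param dissociation see above (default TRUE)
#' @param seed base RNG seed for the cohort (default 1)
#' @return validated configuration list
#' @export
cohortConfig <- function(nSubjects = 20L, nRegions = 40L, nSystems = 4L,
                         tr = 2, taskFrames = 280L, restFrames = 150L,
                         nBlocks = 4L, blockRange = c(52, 60),
                         fixationRange = c(10, 17),
                         firstCondition = "incongruent",
                         withinCor = 0.35, betweenCor = 0.05,
                         deltaMagnitude = 0.3, nDeltaEdges = 40L,
                         deltaCondition = "incongruent",
                         amplitudeSd = 1, contrastSd = 0.5,
                         rho = 0.4, confoundAmplitude = 0.1,
                         hrfGated = FALSE, dissociation = TRUE,
                         seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects),
              nRegions = as.integer(nRegions),
              nSystems = as.integer(nSystems), tr = tr,
              taskFrames = as.integer(taskFrames),
              restFrames = as.integer(restFrames),
              nBlocks = as.integer(nBlocks), blockRange = blockRange,
              fixationRange = fixationRange,
              firstCondition = firstCondition,
              withinCor = withinCor, betweenCor = betweenCor,
              deltaMagnitude = deltaMagnitude,
              nDeltaEdges = as.integer(nDeltaEdges),
              deltaCondition = deltaCondition,
              amplitudeSd = amplitudeSd, contrastSd = contrastSd,
              rho = rho, confoundAmplitude = confoundAmplitude,
              hrfGated = hrfGated, dissociation = dissociation,
              seed = as.integer(seed))
  stopifnot(cfg$nSubjects >= 1L, cfg$nRegions >= 3L,
            cfg$nSystems >= 1L, cfg$tr > 0,
            cfg$taskFrames >= 2L, cfg$restFrames >= 2L,
            length(blockRange) == 2L, diff(blockRange) >= 0,
            length(fixationRange) == 2L, diff(fixationRange) >= 0,
            abs(cfg$rho) < 1,
            cfg$nDeltaEdges * (if (cfg$dissociation) 2L else 1L) <=
              cfg$nRegions * (cfg$nRegions - 1) / 2)
  minTotal <- cfg$nBlocks * 2 * (blockRange[1L] + fixationRange[1L])
  if (minTotal > cfg$taskFrames * cfg$tr)
    stop("shortest possible schedule exceeds the run length")
  cfg
}

#' Generate a block-design task schedule
#'
#' Alternating fixation/condition schedule: `nBlocks` congruent and
#' `nBlocks` incongruent blocks, each preceded by a fixation period, with
#' durations drawn uniformly from the configured ranges. Draws are
#' rejected until the schedule fits inside the run; fixation periods are
#' not modelled as blocks.
#'
#' @param config a [cohortConfig()] list
#' @param seed RNG seed
#' @return a [TaskDesign-class]
#' @export
generateTaskDesign <- function(config, seed = config$seed) {
  set.seed(seed)
  runLen <- config$taskFrames * config$tr
  nb <- config$nBlocks * 2L
  for (try in seq_len(1000L)) {
    durs <- stats::runif(nb, config$blockRange[1L], config$blockRange[2L])
    fixs <- stats::runif(nb, config$fixationRange[1L],
                         config$fixationRange[2L])
    if (sum(durs) + sum(fixs) <= runLen) break
    if (try == 1000L) stop("could not fit a schedule inside the run; ",
                           "check the duration ranges")
  }
  conds <- rep(c(config$firstCondition,
                 setdiff(c("congruent", "incongruent"),
                         config$firstCondition)), config$nBlocks)
  onsets <- cumsum(fixs + c(0, durs[-nb]))
  taskDesign(data.frame(condition = conds, onset = onsets,
                        duration = durs),
             nFrames = config$taskFrames, tr = config$tr)
}

## modular intrinsic correlation matrix; systems assigned contiguously
.intrinsic_sigma <- function(config) {
  p <- config$nRegions
  sysAssign <- sort(rep_len(seq_len(config$nSystems), p))
  S <- matrix(config$betweenCor, p, p)
  for (s in seq_len(config$nSystems)) {
    idx <- which(sysAssign == s)
    S[idx, idx] <- config$withinCor
  }
  diag(S) <- 1
  list(sigma = S, systems = paste0("sys", sysAssign))
}

## nearest-PSD repair by eigenvalue clipping at 1e-6
.psd_clip <- function(S, label = "covariance") {
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < 1e-6) {
    warning(label, " clipped to positive definiteness")
    vals <- pmax(eg$values, 1e-6)
    S <- eg$vectors %*% (vals * t(eg$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

## symmetric increment matrix from an edge set
.delta_matrix <- function(p, pairs, magnitude) {
  D <- matrix(0, p, p)
  D[pairs] <- magnitude
  D[pairs[, 2:1, drop = FALSE]] <- magnitude
  D
}

## per-frame condition gate: raw boxcar or HRF-convolved (clipped to [0,1])
.condition_gate <- function(design, condition, hrfGated) {
  if (is.null(design)) return(numeric(0))
  if (!hrfGated) return(.boxcar(design, condition))
  g <- .convolve_hrf(.boxcar(design, condition), design@tr,
                     design@nFrames)
  pmin(pmax(g, 0), 1)
}

## simulate one run: AR(1)-colored Gaussian noise with state-dependent
## innovation covariance, plus evoked means and confound leakage
.simulate_run <- function(config, truth, design, subjectId, runId) {
  nT <- if (is.null(design)) config$restFrames else config$taskFrames
  p <- config$nRegions
  sig <- list(fix = truth$sigma)
  gates <- NULL
  if (!is.null(design)) {
    gates <- cbind(
      congruent = .condition_gate(design, "congruent", config$hrfGated),
      incongruent = .condition_gate(design, "incongruent",
                                    config$hrfGated))
    gates <- round(gates, 2L)   # bounded set of innovation covariances
  }
  chols <- new.env(parent = emptyenv())
  getChol <- function(wc, wi) {
    key <- paste(wc, wi, sep = "|")
    if (is.null(chols[[key]])) {
      S <- truth$sigma + wc * truth$deltaCong[[runId]] +
        wi * truth$deltaInc[[runId]]
      chols[[key]] <- chol(.psd_clip(S, paste("state", key)))
    }
    chols[[key]]
  }
  rho <- config$rho
  U <- matrix(0, nT, p)
  z <- matrix(stats::rnorm(nT * p), nT, p)
  for (t in seq_len(nT)) {
    ch <- if (is.null(gates)) getChol(0, 0)
          else getChol(gates[t, "congruent"], gates[t, "incongruent"])
    e <- drop(z[t, ] %*% ch)
    U[t, ] <- if (t == 1L) e else rho * U[t - 1L, ] + sqrt(1 - rho^2) * e
  }
  X <- U
  if (!is.null(design)) {
    convC <- .convolve_hrf(.boxcar(design, "congruent"), config$tr, nT)
    convI <- .convolve_hrf(.boxcar(design, "incongruent"), config$tr, nT)
    X <- X + outer(convC, truth$ampCong[[runId]]) +
      outer(convI, truth$ampInc[[runId]])
  }
  ## nuisance series and their leakage into the regional signals
  motion <- apply(matrix(stats::rnorm(nT * 6L, sd = 0.02), nT, 6L),
                  2L, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  arSeries <- function() {
    stats::filter(stats::rnorm(nT), 0.5, method = "recursive") *
      sqrt(1 - 0.5^2)
  }
  wm <- as.numeric(arSeries()); csf <- as.numeric(arSeries())
  ca <- config$confoundAmplitude
  X <- X + motion %*% truth$motionLoad * ca +
    outer(wm, truth$wmLoad) * ca + outer(csf, truth$csfLoad) * ca
  conf <- data.frame(motion, white_matter = wm, csf = csf,
                     global_signal = rowMeans(X))
  subjectRun(parcelSeries(X, tr = config$tr,
                          regionIds = paste0("r", seq_len(p)),
                          systems = truth$systems),
             design = design, confounds = conf,
             subjectId = subjectId, runId = runId)
}

## draw the cohort-level ground truth (shared across subjects)
.draw_truth <- function(config) {
  p <- config$nRegions
  intr <- .intrinsic_sigma(config)
  sigma <- .psd_clip(intr$sigma, "intrinsic covariance")
  idx <- edgeIndex(p)
  allE <- nrow(idx@pairs)
  pick <- sample.int(allE, config$nDeltaEdges *
                       (if (config$dissociation) 2L else 1L))
  setA <- sort(pick[seq_len(config$nDeltaEdges)])
  setB <- if (config$dissociation)
    sort(pick[config$nDeltaEdges + seq_len(config$nDeltaEdges)]) else setA
  zeroD <- matrix(0, p, p)
  dA <- .delta_matrix(p, idx@pairs[setA, , drop = FALSE],
                      config$deltaMagnitude)
  dB <- .delta_matrix(p, idx@pairs[setB, , drop = FALSE],
                      config$deltaMagnitude)
  base <- stats::rnorm(p, sd = config$amplitudeSd)
  contrast <- stats::rnorm(p, sd = config$contrastSd)
  ampC <- base
  ampI <- base + contrast
  onInc <- config$deltaCondition == "incongruent"
  list(sigma = sigma, systems = intr$systems, index = idx,
       deltaEdges = list(taskA = setA, taskB = setB),
       deltaCong = list(taskA = if (onInc) zeroD else dA,
                        taskB = if (onInc) zeroD else dB,
                        rest = zeroD),
       deltaInc = list(taskA = if (onInc) dA else zeroD,
                       taskB = if (onInc) dB else zeroD,
                       rest = zeroD),
       ampCong = list(taskA = ampC, taskB = ampC, rest = numeric(p)),
       ampInc = list(taskA = ampI, taskB = ampI, rest = numeric(p)),
       amplitudeContrast = contrast,
       motionLoad = matrix(stats::rnorm(6L * p), 6L, p),
       wmLoad = stats::rnorm(p), csfLoad = stats::rnorm(p),
       rho = config$rho, seed = config$seed)
}

#' Generate a synthetic cohort
#'
#' Draws the cohort-level ground truth (intrinsic covariance, planted
#' covariance increments, evoked amplitudes, confound loadings), one task
#' schedule per task (shared across subjects, as in a fixed paradigm), and
#' per-subject task-A, task-B and rest runs. The returned `truth` is
#' sufficient to regenerate the cohort bit-exactly from the same config.
#'
#' @param config a [cohortConfig()] list
#' @return list with `taskA`, `taskB`, `rest` (lists of
#'   [SubjectRun-class]), `designs` (per-task [TaskDesign-class]) and
#'   `truth` (ground-truth list: `sigma`, `deltaEdges`, per-run delta
#'   matrices and amplitude vectors, confound loadings, `rho`, `seed`)
#' @export
generateCohort <- function(config = cohortConfig()) {
  set.seed(config$seed)
  truth <- .draw_truth(config)
  designA <- generateTaskDesign(config, seed = config$seed + 1L)
  designB <- generateTaskDesign(config, seed = config$seed + 2L)
  set.seed(config$seed + 3L)
  taskA <- list(); taskB <- list(); rest <- list()
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("sub-%02d", s)
    taskA[[sid]] <- .simulate_run(config, truth, designA, sid, "taskA")
    taskB[[sid]] <- .simulate_run(config, truth, designB, sid, "taskB")
    rest[[sid]] <- .simulate_run(config, truth, NULL, sid, "rest")
  }
  list(taskA = taskA, taskB = taskB, rest = rest,
       designs = list(taskA = designA, taskB = designB), truth = truth)
}

#' Generate a single rest run
#'
#' Task-free acquisition: intrinsic covariance and AR(1) noise only, with
#' the usual confound series. 150 frames at TR = 2 s under the default
#' configuration (a 5-minute scan).
#'
#' @param config a [cohortConfig()] list
#' @param subjectId subject identifier
#' @param seed RNG seed
#' @return a [SubjectRun-class]
#' @export
generateRestRun <- function(config = cohortConfig(), subjectId = "sub-01",
                            seed = config$seed) {
  set.seed(seed)
  truth <- .draw_truth(config)
  .simulate_run(config, truth, NULL, subjectId, "rest")
}

#' Block-alternation fundamental frequency
#'
#' The fundamental frequency (Hz) of the block on/off pattern of a task
#' schedule: number of blocks divided by the run duration. A synthetic
#' run's RSS cofluctuation amplitude is expected to carry spectral power
#' at this frequency.
#'
#' @param design a [TaskDesign-class]
#' @return frequency in Hz
#' @export
blockFundamental <- function(design) {
  nrow(design@blocks) / (design@nFrames * design@tr)
}

#' Ranking AUC of planted versus null elements
#'
#' Mann-Whitney area under the curve: the probability that a randomly
#' chosen planted element outranks a randomly chosen null element in the
#' score vector (average over ties).
#'
#' @param scores numeric score per element (e.g. group contrast t)
#' @param planted integer indices or logical mask of planted elements
#' @return AUC in `[0, 1]`
#' @export
recoveryAUC <- function(scores, planted) {
  lab <- logical(length(scores))
  lab[planted] <- TRUE
  r <- rank(scores)
  n1 <- sum(lab); n0 <- sum(!lab)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
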