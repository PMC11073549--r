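## Between-task and between-subject similarity analyses: Spearman and Dice
## on statistical maps, subject- and edge-subsampling curves, region-wise
## profile similarity, subject-level beta-map similarity, Mantel tests with
## subsampled confidence intervals, SNR and activation filters.

#' Spearman correlation between two maps
#'
#' Pearson correlation of average ranks (ties handled by mid-ranks). Errors
#' on a constant input, where the correlation is undefined.
#'
#' @param a,b numeric vectors of equal length (>= 3)
#' @return Spearman's rho
#' @export
spearmanMap <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant input vector")
  stats::cor(a, b, method = "spearman")
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty (two identically null maps are maximally similar).
#'
#' @param maskA,maskB logical (or 0/1) vectors of equal length
#' @return DSC in `[0, 1]`
#' @export
diceCoefficient <- function(maskA, maskB) {
  a <- as.logical(maskA); b <- as.logical(maskB)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Between-task similarity as a function of sample size
#'
#' For each n in `nGrid`, draws n subjects without replacement (the same
#' draw for both tasks), recomputes the group t maps, and records the
#' Spearman correlation between tasks plus Dice coefficients of the
#' significance masks over a grid of alpha thresholds. Each n is repeated
#' `nRepeats` times; means and standard deviations are returned.
#'
#' @param mapsA,mapsB subjects x elements matrices of subject-level effects
#'   for the two tasks (same subject rows)
#' @param nGrid subject counts to evaluate (each >= 3)
#' @param nRepeats repeats per n (default 10)
#' @param alphas alpha grid for the Dice masks
#' @param correction mask correction, `"holm"` default
#' @param seed RNG seed
#' @return data.frame with columns `n`, `rhoMean`, `rhoSd`, and
#'   `dice<alpha>Mean`/`Sd` per alpha
#' @export
similarityVsN <- function(mapsA, mapsB, nGrid, nRepeats = 10L,
                          alphas = 0.05, correction = "holm", seed = 1L) {
  A <- as.matrix(mapsA); B <- as.matrix(mapsB)
  stopifnot(all(dim(A) == dim(B)))
  ns <- nrow(A)
  if (any(nGrid < 3L)) stop("each n must be >= 3")
  if (any(nGrid > ns)) stop("n exceeds the number of subjects")
  set.seed(seed)
  rows <- lapply(nGrid, function(n) {
    rhos <- numeric(nRepeats)
    dsc <- matrix(0, nRepeats, length(alphas))
    for (r in seq_len(nRepeats)) {
      idx <- sample.int(ns, n)
      ga <- oneSampleMap(A[idx, , drop = FALSE], correction = correction)
      gb <- oneSampleMap(B[idx, , drop = FALSE], correction = correction)
      rhos[r] <- spearmanMap(ga@t, gb@t)
      for (ai in seq_along(alphas)) {
        ma <- switch(correction,
                     holm = holmMask(ga@p, alphas[ai]),
                     bh = bhMask(ga@p, alphas[ai]),
                     none = ga@p <= alphas[ai])
        mb <- switch(correction,
                     holm = holmMask(gb@p, alphas[ai]),
                     bh = bhMask(gb@p, alphas[ai]),
                     none = gb@p <= alphas[ai])
        dsc[r, ai] <- diceCoefficient(ma, mb)
      }
    }
    out <- data.frame(n = n, rhoMean = mean(rhos), rhoSd = stats::sd(rhos))
    for (ai in seq_along(alphas)) {
      out[[paste0("dice", alphas[ai], "Mean")]] <- mean(dsc[, ai])
      out[[paste0("dice", alphas[ai], "Sd")]] <- stats::sd(dsc[, ai])
    }
    out
  })
  do.call(rbind, rows)
}

#' Edge-subsampling similarity distribution
#'
#' Distribution of Spearman correlations between two edge maps over
#' `nReps` uniformly drawn k-subsets of edges (without replacement within
#' each subset). Used to show that a full-profile similarity is not an
#' artifact of the number of features correlated.
#'
#' @param mapA,mapB numeric edge maps of equal length
#' @param k subset size (<= number of edges)
#' @param nReps number of subsamples (default 10000)
#' @param seed RNG seed
#' @return numeric vector of `nReps` Spearman values
#' @export
edgeSubsampleSimilarity <- function(mapA, mapB, k, nReps = 10000L,
                                    seed = 1L) {
  stopifnot(length(mapA) == length(mapB), k <= length(mapA), k >= 3L)
  set.seed(seed)
  vapply(seq_len(nReps), function(r) {
    idx <- sample.int(length(mapA), k)
    spearmanMap(mapA[idx], mapB[idx])
  }, numeric(1L))
}

#' Region-wise profile similarity between two edge maps
#'
#' For each region, extracts its whole-brain profile (the region's row of
#' the symmetric edge-statistic matrix, diagonal excluded; length P - 1)
#' from both maps and computes their Spearman correlation.
#'
#' @param mapA,mapB numeric edge vectors over the canonical [edgeIndex()]
#' @param index the shared [EdgeIndex-class]
#' @return numeric vector of per-region rho values (length P)
#' @export
regionwiseSimilarity <- function(mapA, mapB, index) {
  p <- index@nRegions
  toMat <- function(v) {
    M <- matrix(NA_real_, p, p)
    M[index@pairs] <- v
    M[index@pairs[, 2:1, drop = FALSE]] <- v
    M
  }
  MA <- toMat(mapA); MB <- toMat(mapB)
  vapply(seq_len(p), function(r)
    spearmanMap(MA[r, -r], MB[r, -r]), numeric(1L))
}

#' Subject-level between-task beta-map similarity
#'
#' Per subject, the Spearman correlation between the two tasks'
#' condition-contrast beta maps, computed separately for the activation
#' (node) and network (edge) maps; beta rather than t maps are compared
#' because subject-level degrees of freedom differ across nodes and edges
#' under temporal autocorrelation. Across subjects, a paired t test
#' compares the activation and network similarity distributions, with
#' Cohen's d = mean(differences) / sd(differences).
#'
#' @param activationA,activationB subjects x regions beta matrices for
#'   tasks A and B
#' @param networkA,networkB subjects x edges beta matrices
#' @return list with `activationRho`, `networkRho` (per-subject vectors),
#'   their means, `pairedT`, `p`, `cohensD`, `df`
#' @export
subjectLevelSimilarity <- function(activationA, activationB,
                                   networkA, networkB) {
  aA <- as.matrix(activationA); aB <- as.matrix(activationB)
  nA <- as.matrix(networkA); nB <- as.matrix(networkB)
  ns <- nrow(aA)
  stopifnot(nrow(aB) == ns, nrow(nA) == ns, nrow(nB) == ns)
  actRho <- vapply(seq_len(ns), function(s)
    spearmanMap(aA[s, ], aB[s, ]), numeric(1L))
  netRho <- vapply(seq_len(ns), function(s)
    spearmanMap(nA[s, ], nB[s, ]), numeric(1L))
  d <- actRho - netRho
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero variance of paired differences; t undefined")
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pp <- if (mean(d) == 0) 1 else 0
    cd <- NA_real_
  } else {
    tt <- mean(d) / (sdd / sqrt(ns))
    pp <- 2 * stats::pt(-abs(tt), df = ns - 1L)
    cd <- mean(d) / sdd
  }
  list(activationRho = actRho, networkRho = netRho,
       meanActivationRho = mean(actRho), meanNetworkRho = mean(netRho),
       pairedT = tt, p = pp, cohensD = cd, df = ns - 1L)
}

#' Subject distance matrix from stat maps
#'
#' Pairwise subject distances `d_ij = 1 - rho_ij` where rho is the
#' Spearman correlation between subjects' maps.
#'
#' @param maps subjects x elements matrix
#' @return symmetric subjects x subjects distance matrix, zero diagonal
#' @export
subjectDistances <- function(maps) {
  M <- as.matrix(maps)
  R <- stats::cor(t(M), method = "spearman")
  D <- 1 - R
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Mantel test with subsampled confidence interval
#'
#' Pearson correlation between the upper-triangular entries of two subject
#' distance matrices, with a permutation p value (simultaneous row/column
#' relabeling of one matrix, via [vegan::mantel()]) and a confidence
#' interval from the empirical distribution of r over subject subsamples
#' of size `ceiling(ratio * n)` drawn without replacement (2.5/97.5
#' percentiles).
#'
#' @param distA,distB symmetric subjects x subjects distance matrices
#' @param nPerm number of permutations (>= 99)
#' @param nResample number of subsamples for the CI
#' @param ratio subsampling ratio (default 0.135)
#' @param seed RNG seed
#' @return list with `r`, `p`, `ci` (length-2), `nPerm`, `nResample`
#' @export
mantelTest <- function(distA, distB, nPerm = 999L, nResample = 1000L,
                       ratio = 0.135, seed = 1L) {
  A <- as.matrix(distA); B <- as.matrix(distB)
  n <- nrow(A)
  if (n < 4L) stop("Mantel test needs at least 4 subjects")
  stopifnot(all(dim(B) == c(n, n)), nPerm >= 99L)
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                      method = "pearson", permutations = nPerm)
  k <- max(4L, ceiling(ratio * n))
  rs <- vapply(seq_len(nResample), function(rep) {
    idx <- sample.int(n, k)
    ut <- upper.tri(A[idx, idx])
    stats::cor(A[idx, idx][ut], B[idx, idx][ut])
  }, numeric(1L))
  list(r = as.numeric(mt$statistic), p = as.numeric(mt$signif),
       ci = stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE),
       nPerm = nPerm, nResample = nResample, subsampleSize = k)
}

#' Group-level SNR (Cohen's d) filter
#'
#' Per element, the group mean of the subject-level condition contrast
#' divided by its across-subject standard deviation (a group-level Cohen's
#' d). The median over elements is reported per task, and the retained set
#' contains the elements whose SNR strictly exceeds `threshold` in every
#' supplied task. Elements with zero across-subject sd are excluded with a
#' message.
#'
#' @param subjectBetas a subjects x elements matrix, or a named list of
#'   such matrices (one per task)
#' @param threshold retention threshold (default 0.5)
#' @return list with `snr` (matrix tasks x elements), `median` (per task),
#'   `retained` (integer element indices)
#' @export
snrFilter <- function(subjectBetas, threshold = 0.5) {
  if (!is.list(subjectBetas)) subjectBetas <- list(task = subjectBetas)
  snr <- t(vapply(subjectBetas, function(M) {
    M <- as.matrix(M)
    if (nrow(M) < 3L) stop("SNR needs at least 3 subjects")
    mu <- colMeans(M)
    sdv <- apply(M, 2L, stats::sd)
    out <- rep(NA_real_, ncol(M))
    if (any(sdv == 0))
      message(sum(sdv == 0), " element(s) with zero sd excluded from SNR")
    out[sdv > 0] <- mu[sdv > 0] / sdv[sdv > 0]
    out
  }, numeric(ncol(as.matrix(subjectBetas[[1L]])))))
  keep <- apply(snr, 2L, function(v) all(is.finite(v) & v > threshold))
  list(snr = snr,
       median = apply(snr, 1L, stats::median, na.rm = TRUE),
       retained = which(keep))
}

#' Activation-strength region filter
#'
#' Retains the regions whose absolute group-level Cohen's d exceeds
#' `dThreshold` in every supplied task.
#'
#' @param subjectBetas named list of subjects x regions beta matrices
#' @param dThreshold absolute Cohen's d threshold (default 0.8)
#' @return integer vector of retained region indices
#' @export
activationFilter <- function(subjectBetas, dThreshold = 0.8) {
  if (!is.list(subjectBetas)) subjectBetas <- list(task = subjectBetas)
  ds <- lapply(subjectBetas, function(M) {
    M <- as.matrix(M)
    sdv <- apply(M, 2L, stats::sd)
    ifelse(sdv > 0, abs(colMeans(M)) / sdv, Inf)
  })
  keep <- Reduce(`&`, lapply(ds, function(v) v > dThreshold))
  which(keep)
}
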