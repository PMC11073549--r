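## Group-level inference: one-sample and paired t maps, Holm-Bonferroni and
## Benjamini-Hochberg correction, t -> r conversion, top-fraction sign test
## and system-level summaries of significant edges.

## vectorized one-sample t across the subject dimension (rows = subjects)
.group_t <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sdv <- apply(M, 2L, stats::sd)
  se <- sdv / sqrt(n)
  tt <- numeric(ncol(M)); pp <- numeric(ncol(M))
  ok <- se > 0
  tt[ok] <- mu[ok] / se[ok]
  pp[ok] <- 2 * stats::pt(-abs(tt[ok]), df = n - 1L)
  if (any(!ok)) {
    tt[!ok] <- sign(mu[!ok]) * Inf
    tt[!ok & mu == 0] <- 0
    pp[!ok] <- ifelse(mu[!ok] == 0, 1, 0)
  }
  list(mean = mu, t = tt, p = pp, n = n)
}

#' One-sample group map
#'
#' Classical one-sample t test of the subject-level effects against zero,
#' per element, with multiplicity correction of the two-sided p values.
#' Elements with zero across-subject variance get the +/-Inf t sentinel
#' (t = 0, p = 1 when the mean is also zero).
#'
#' @param subjectMaps subjects x elements numeric matrix
#' @param correction `"holm"` (default), `"bh"` or `"none"`
#' @param alpha significance level for the mask
#' @return a [GroupMap-class]
#' @export
oneSampleMap <- function(subjectMaps, correction = c("holm", "bh", "none"),
                         alpha = 0.05) {
  correction <- match.arg(correction)
  M <- as.matrix(subjectMaps)
  if (nrow(M) < 3L) stop("group inference needs at least 3 subjects")
  if (any(!is.finite(M))) stop("subject maps must not contain missing values")
  g <- .group_t(M)
  mask <- switch(correction,
                 holm = holmMask(g$p, alpha),
                 bh = bhMask(g$p, alpha),
                 none = g$p <= alpha)
  els <- colnames(M)
  if (is.null(els)) els <- paste0("el", seq_len(ncol(M)))
  new("GroupMap", elements = els, effect = g$mean, t = g$t, p = g$p,
      dof = g$n - 1, nSubjects = as.integer(g$n), mask = mask,
      correction = correction, alpha = alpha)
}

#' Paired group map
#'
#' One-sample t test on the per-subject differences `mapsA - mapsB`
#' (element-wise), i.e. a paired t test between the two conditions.
#'
#' @param mapsA,mapsB subjects x elements matrices with identical subject
#'   rows (checked via row names when present)
#' @inheritParams oneSampleMap
#' @return a [GroupMap-class]
#' @export
pairedMap <- function(mapsA, mapsB, correction = c("holm", "bh", "none"),
                      alpha = 0.05) {
  A <- as.matrix(mapsA); B <- as.matrix(mapsB)
  if (!all(dim(A) == dim(B))) stop("paired maps must have equal dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("paired maps must contain the same subjects in the same order")
  oneSampleMap(A - B, correction = match.arg(correction), alpha = alpha)
}

#' Holm-Bonferroni rejection mask
#'
#' Step-down family-wise error control at level `alpha`
#' (via [stats::p.adjust()]).
#'
#' @param p vector of p values in `[0, 1]`
#' @param alpha level
#' @return logical rejection mask
#' @export
holmMask <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false-discovery-rate control at level `alpha`.
#'
#' @inheritParams holmMask
#' @return logical rejection mask
#' @export
bhMask <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "BH") <= alpha
}

#' Convert group t statistics to correlations
#'
#' Signed transformation `r = sign(t) * sqrt(t^2 / (t^2 + N - 1))` with N
#' the number of subjects; |r| < 1 for finite t.
#'
#' @param t t statistics (vector)
#' @param nSubjects number of subjects N (>= 2)
#' @return signed correlations of the same length
#' @export
tToR <- function(t, nSubjects) {
  stopifnot(nSubjects >= 2)
  r <- sign(t) * sqrt(t^2 / (t^2 + nSubjects - 1))
  r[t == 0] <- 0
  r[is.infinite(t)] <- sign(t[is.infinite(t)])
  r
}

#' Sign composition of top-|t| edges in two maps
#'
#' Selects, in each map independently, the `floor(fraction * E)` elements
#' with the largest absolute t statistic (ties broken by element index),
#' cross-tabulates their positive/negative counts (zero t excluded from
#' classification, with a message), and reports the sample odds ratio
#' `(a d) / (b c)` with Fisher's exact (hypergeometric) p value. Zero cells
#' get a 0.5 continuity correction for the odds ratio, flagged in the
#' output.
#'
#' @param tA,tB t-statistic vectors of equal length
#' @param fraction fraction of elements selected, in (0, 1]; default 0.01
#' @return list with `table` (2 x 2 counts, rows = maps, cols = pos/neg),
#'   `oddsRatio`, `p`, `continuity` (logical), `k` (elements selected)
#' @export
topFractionSignTest <- function(tA, tB, fraction = 0.01) {
  stopifnot(length(tA) == length(tB), fraction > 0, fraction <= 1)
  E <- length(tA)
  k <- floor(fraction * E)
  if (k < 1L) stop("fraction selects no elements")
  top <- function(tv) {
    ord <- order(-abs(tv), seq_along(tv))
    sel <- tv[ord[seq_len(k)]]
    nz <- sum(sel == 0)
    if (nz) message(nz, " zero-t element(s) excluded from sign counts")
    c(pos = sum(sel > 0), neg = sum(sel < 0))
  }
  tab <- rbind(mapA = top(tA), mapB = top(tB))
  cont <- any(tab == 0)
  tc <- if (cont) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, oddsRatio = as.numeric(or), p = p,
       continuity = cont, k = k)
}

#' System-level summaries of significant edges
#'
#' Per region, the degree (number of significant incident edges); per
#' ordered system pair, the count of significant edges normalized by the
#' total number of possible edges between (or within) those systems.
#'
#' @param map a [GroupMap-class] over edges (uses its `mask`), or a logical
#'   mask vector
#' @param index the [EdgeIndex-class] matching the map
#' @param systems character vector of system labels, one per region
#' @return list with `degree` (per-region counts), `counts` and
#'   `normalized` (system x system matrices; upper triangle + diagonal
#'   populated, symmetric)
#' @export
systemSummaries <- function(map, index, systems) {
  mask <- if (is(map, "GroupMap")) map@mask else as.logical(map)
  p <- index@nRegions
  if (length(systems) != p) stop("need one system label per region")
  if (anyNA(systems)) stop("unlabeled region(s) present")
  if (length(mask) != nrow(index@pairs))
    stop("mask length must equal the number of edges")
  pr <- index@pairs
  degree <- tabulate(c(pr[mask, 1L], pr[mask, 2L]), nbins = p)
  names(degree) <- paste0("r", seq_len(p))
  sys <- sort(unique(systems))
  s1 <- factor(systems[pr[, 1L]], levels = sys)
  s2 <- factor(systems[pr[, 2L]], levels = sys)
  ## order each edge's pair of systems for a symmetric tabulation
  lo <- ifelse(as.integer(s1) <= as.integer(s2),
               as.integer(s1), as.integer(s2))
  hi <- ifelse(as.integer(s1) <= as.integer(s2),
               as.integer(s2), as.integer(s1))
  tot <- matrix(0, length(sys), length(sys), dimnames = list(sys, sys))
  cnt <- tot
  for (e in seq_len(nrow(pr))) {
    tot[lo[e], hi[e]] <- tot[lo[e], hi[e]] + 1
    if (mask[e]) cnt[lo[e], hi[e]] <- cnt[lo[e], hi[e]] + 1
  }
  norm <- ifelse(tot > 0, cnt / tot, 0)
  sym <- function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  list(degree = degree, counts = sym(cnt), totals = sym(tot),
       normalized = sym(norm))
}
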