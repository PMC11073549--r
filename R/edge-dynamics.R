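## Edge (cofluctuation) time series: standardization, element-wise products
## over the canonical upper-triangular pair ordering, RSS amplitude and its
## periodogram.

#' Standardize a series (z-score, denominator T - 1)
#'
#' Centers to mean 0 and scales to unit sample standard deviation
#' (denominator T - 1). This convention makes the Pearson decomposition
#' exact: summing an edge series and dividing by T - 1 returns the parents'
#' correlation coefficient.
#'
#' @param x numeric vector (>= 2 frames) or frames x regions matrix (each
#'   column standardized)
#' @return object of the same shape
#' @export
standardizeSeries <- function(x) {
  if (is.matrix(x)) return(apply(x, 2L, standardizeSeries))
  if (length(x) < 2L) stop("standardization needs at least 2 frames")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate series: zero sample variance")
  (x - mean(x)) / s
}

#' Build the edge (cofluctuation) time series
#'
#' For every region pair (i, j) with i < j, in canonical [edgeIndex()]
#' order, the edge series is the element-wise product z_i(t) * z_j(t) of
#' the standardized parent series. Inputs are checked to be standardized
#' (mean 0, sd 1 with denominator T - 1) to a tolerance.
#'
#' @param Z frames x regions matrix of standardized series, or a
#'   [ParcelSeries-class] holding one
#' @param tr repetition time (taken from a ParcelSeries input)
#' @param tol tolerance on the standardization check
#' @return an [EdgeSeries-class]
#' @export
edgeSeries <- function(Z, tr = NULL, tol = 1e-6) {
  if (is(Z, "ParcelSeries")) { tr <- Z@tr; Z <- Z@values }
  Z <- as.matrix(Z)
  if (is.null(tr)) tr <- 1
  mu <- colMeans(Z)
  sdv <- apply(Z, 2L, stats::sd)
  if (any(abs(mu) > tol) || any(abs(sdv - 1) > tol))
    stop("input series are not standardized (mean 0, sd 1); ",
         "apply standardizeSeries() first")
  idx <- edgeIndex(ncol(Z))
  E <- Z[, idx@pairs[, 1L], drop = FALSE] * Z[, idx@pairs[, 2L], drop = FALSE]
  colnames(E) <- edgeNames(idx, colnames(Z))
  new("EdgeSeries", values = E, index = idx, tr = as.numeric(tr))
}

#' Edge column names "i_j"
#' @param index an [EdgeIndex-class]
#' @param regionIds optional region id vector; defaults to 1..P
#' @return character vector of edge names
#' @export
edgeNames <- function(index, regionIds = NULL) {
  if (is.null(regionIds)) regionIds <- as.character(seq_len(index@nRegions))
  paste(regionIds[index@pairs[, 1L]], regionIds[index@pairs[, 2L]],
        sep = "_")
}

#' Root-sum-of-squares cofluctuation amplitude
#'
#' Per frame, the square root of the sum of squared edge values: a global
#' instantaneous cofluctuation amplitude.
#'
#' @param E an [EdgeSeries-class] or frames x edges matrix
#' @return numeric vector, one non-negative value per frame
#' @export
edgeRSS <- function(E) {
  M <- if (is(E, "EdgeSeries")) E@values else as.matrix(E)
  if (ncol(M) < 1L) stop("edgeRSS needs at least one edge")
  sqrt(rowSums(M^2))
}

#' Periodogram of a series
#'
#' Plain (untapered, unsmoothed) periodogram of the demeaned series, with
#' frequencies in Hz up to the Nyquist frequency 1 / (2 * tr). A Welch-style
#' smoothed option is available via `spans`.
#'
#' @param x numeric series (>= 4 frames)
#' @param tr sampling interval in seconds
#' @param spans optional smoothing spans passed to [stats::spec.pgram()]
#' @return list with `freq` (Hz) and `power`
#' @export
seriesPeriodogram <- function(x, tr, spans = NULL) {
  if (length(x) < 4L) stop("periodogram needs at least 4 frames")
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = 1 / tr),
                          taper = 0, detrend = FALSE, demean = TRUE,
                          fast = FALSE, plot = FALSE, spans = spans)
  list(freq = as.numeric(sp$freq), power = as.numeric(sp$spec))
}
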