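## Subject-level estimators wiring regressors + GLM core + edge dynamics:
## confound denoising, node activation GLM, edge (cofluctuation) GLM, and
## the generalized psychophysiological interaction (gPPI) comparator.

#' Pipeline configuration
#'
#' The robustness toggles of the analysis, defaulting to the main pipeline:
#' FIR task removal before edge formation, double-gamma HRF regressors,
#' global-signal regression on, no extra standardization inside the GLM,
#' AR(1) prewhitening on.
#'
#' @param removeTask regress the 12-lag-per-condition FIR task block out of
#'   the parcel series before building edges (`TRUE`) or keep task effects
#'   (`FALSE`)
#' @param hrf `"double-gamma"` or `"boxcar"` task regressors
#' @param gsr include the global signal in the nuisance set
#' @param standardize z-score response and design inside the GLMs
#' @param prewhiten AR(1) prewhitening of both sides of each GLM
#' @param nLags FIR lags per condition in the denoise design
#' @param cutoff cosine drift cutoff (seconds)
#' @param mapping confound column mapping, see [confoundMapping()]
#' @return a named list of settings
#' @export
pipelineConfig <- function(removeTask = TRUE,
                           hrf = c("double-gamma", "boxcar"),
                           gsr = TRUE, standardize = FALSE,
                           prewhiten = TRUE, nLags = 12L, cutoff = 187,
                           mapping = confoundMapping()) {
  list(removeTask = removeTask, hrf = match.arg(hrf), gsr = gsr,
       standardize = standardize, prewhiten = prewhiten,
       nLags = as.integer(nLags), cutoff = cutoff, mapping = mapping)
}

#' Confound (and task) denoising of a subject run
#'
#' Regresses every parcel series, in a single step, on the denoise design
#' (FIR task block when `removeTask`, 24 expanded motion parameters, white
#' matter, CSF, global signal when `gsr`, cosine drift, intercept) and
#' returns the residuals. Single-step regression avoids reintroducing
#' artifacts that sequential residualization can cause.
#'
#' @param run a [SubjectRun-class]
#' @param config a [pipelineConfig()] list
#' @return a [ParcelSeries-class] of residuals
#' @export
denoiseRun <- function(run, config = pipelineConfig()) {
  X <- denoiseDesign(run@design, run@confounds,
                     nFrames = nFrames(run@parcels),
                     tr = repTime(run@parcels),
                     removeTask = config$removeTask, gsr = config$gsr,
                     nLags = config$nLags, cutoff = config$cutoff,
                     mapping = config$mapping)
  q <- .check_rank(X@values)
  Y <- run@parcels@values
  res <- Y - X@values %*% qr.coef(q, Y)
  parcelSeries(res, tr = run@parcels@tr, regionIds = run@parcels@regionIds,
               systems = run@parcels@systems)
}

#' Node-level activation GLM
#'
#' Fits each parcel series on the activation design (HRF triplets per
#' condition plus the full nuisance set and intercept) with AR(1)
#' prewhitening, and returns the contrast between the two conditions' main
#' HRF regressors (by default `incongruent - congruent`).
#'
#' @param run a task [SubjectRun-class]
#' @param config a [pipelineConfig()] list
#' @param contrast named numeric vector of condition weights, default
#'   `c(incongruent = 1, congruent = -1)`
#' @return list with `map` (a [StatMap-class] over regions) and `fit`
#'   (the [GLMFit-class])
#' @export
runActivationGLM <- function(run, config = pipelineConfig(),
                             contrast = c(incongruent = 1, congruent = -1)) {
  if (isRestRun(run)) stop("activation GLM requires a task run")
  X <- activationDesign(run@design, run@confounds, gsr = config$gsr,
                        hrf = config$hrf, cutoff = config$cutoff,
                        mapping = config$mapping)
  fit <- tryCatch(
    glmFit(run@parcels@values, X, prewhiten = config$prewhiten,
           standardize = config$standardize),
    error = function(e) stop("activation GLM failed for subject ",
                             run@subjectId, ": ", conditionMessage(e)))
  w <- contrastWeights(X)
  w[names(contrast)] <- contrast
  map <- glmContrast(fit, w)
  map@elements <- run@parcels@regionIds
  list(map = map, fit = fit)
}

#' Edge-level (cofluctuation) GLM
#'
#' Denoises the run, standardizes the residual parcel series, forms the
#' edge time series, and fits each edge on the edge design (intercept +
#' HRF triplets per condition; intercept only for rest runs) with AR(1)
#' prewhitening. Returns per-edge stat maps for the intercept (intrinsic
#' correlation), each condition's main effect, and the between-condition
#' contrast.
#'
#' @param run a [SubjectRun-class] (task or rest)
#' @param config a [pipelineConfig()] list
#' @param conditions the two condition labels contrasted, in
#'   `c(positive, negative)` order; default `incongruent - congruent`
#' @return list with [StatMap-class] entries `intercept` and, for task
#'   runs, one per condition plus `contrast`; also `fit` and `edges`
#'   (the [EdgeSeries-class])
#' @export
runEdgeGLM <- function(run, config = pipelineConfig(),
                       conditions = c("incongruent", "congruent")) {
  den <- denoiseRun(run, config)
  Z <- standardizeSeries(den@values)
  E <- edgeSeries(Z, tr = den@tr)
  X <- edgeDesign(run@design, nFrames = nFrames(den), hrf = config$hrf)
  fit <- tryCatch(
    glmFit(E@values, X, prewhiten = config$prewhiten,
           standardize = config$standardize),
    error = function(e) stop("edge GLM failed for subject ",
                             run@subjectId, ": ", conditionMessage(e)))
  out <- list(
    intercept = glmContrast(fit, contrastWeights(X, intercept = 1)))
  if (!isRestRun(run)) {
    present <- designConditions(run@design)
    miss <- setdiff(conditions, present)
    if (length(miss))
      stop("condition absent from run (all-zero task columns): ",
           paste(miss, collapse = ", "))
    for (cnd in conditions) {
      w <- structure(1, names = cnd)
      out[[cnd]] <- glmContrast(fit, do.call(contrastWeights,
                                             c(list(X), as.list(w))))
    }
    cw <- contrastWeights(X)
    cw[conditions[1L]] <- 1
    cw[conditions[2L]] <- -1
    out$contrast <- glmContrast(fit, cw)
  }
  out$fit <- fit
  out$edges <- E
  out
}

#' Generalized psychophysiological interaction (gPPI)
#'
#' For every ordered region pair (seed i -> target j), regresses the raw
#' target series x_j on an intercept, the seed series x_i (background
#' coupling), the task block (HRF triplets for both conditions), the PPI
#' interaction terms (element-wise product of the observed seed series with
#' each condition's main HRF regressor), and the covariate block (24 motion
#' parameters, white matter, CSF, global signal when `gsr`, cosine drift).
#' The per-pair statistic is the difference of the two conditions'
#' interaction coefficients; the directed matrix is then symmetrized by
#' averaging its upper and lower triangles.
#'
#' @param run a task [SubjectRun-class]
#' @param config a [pipelineConfig()] list
#' @param conditions the two condition labels, `c(positive, negative)`
#' @return list with `contrast` (symmetrized per-edge effect vector over
#'   the canonical [edgeIndex()]), `directed` (regions x regions matrix of
#'   directed seed->target effects, NA diagonal), `skipped` (data.frame of
#'   pairs dropped for rank deficiency), and `index` (the [EdgeIndex-class])
#' @export
runGPPI <- function(run, config = pipelineConfig(),
                    conditions = c("incongruent", "congruent")) {
  if (isRestRun(run)) stop("gPPI requires a task run")
  Y <- run@parcels@values
  p <- ncol(Y)
  cp <- .confound_parts(run@confounds, config$mapping)
  trip <- lapply(conditions, hrfTriplet, design = run@design,
                 hrf = config$hrf)
  mains <- do.call(cbind, lapply(trip, function(m) m[, 1L, drop = FALSE]))
  ders <- do.call(cbind, lapply(trip, function(m) m[, 2:3, drop = FALSE]))
  Cov <- cbind(expandMotion(cp$motion), wm = cp$wm[, 1L], csf = cp$csf[, 1L])
  if (config$gsr) Cov <- cbind(Cov, global = cp$global[, 1L])
  Cov <- cbind(Cov, cosineBasis(nrow(Y), run@parcels@tr, config$cutoff))
  directed <- matrix(NA_real_, p, p,
                     dimnames = list(run@parcels@regionIds,
                                     run@parcels@regionIds))
  skipped <- list()
  for (i in seq_len(p)) {
    xi <- Y[, i]
    inter <- mains * xi
    colnames(inter) <- paste0("ppi_", conditions)
    X <- cbind(intercept = 1, seed = xi, mains, ders, inter, Cov)
    q <- qr(X)
    if (q$rank < ncol(X)) {
      for (j in seq_len(p)[-i])
        skipped[[length(skipped) + 1L]] <-
          data.frame(seed = i, target = j,
                     reason = "rank-deficient design")
      next
    }
    targets <- seq_len(p)[-i]
    fit <- glmFit(Y[, targets, drop = FALSE], X,
                  prewhiten = config$prewhiten,
                  standardize = config$standardize)
    cw <- structure(numeric(ncol(X)), names = colnames(X))
    cw[paste0("ppi_", conditions[1L])] <- 1
    cw[paste0("ppi_", conditions[2L])] <- -1
    sm <- glmContrast(fit, cw)
    directed[i, targets] <- sm@effect
  }
  idx <- edgeIndex(p)
  up <- directed[idx@pairs]
  lo <- directed[idx@pairs[, 2:1, drop = FALSE]]
  sym <- (up + lo) / 2
  names(sym) <- edgeNames(idx, run@parcels@regionIds)
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(seed = integer(), target = integer(),
                             reason = character())
  list(contrast = sym, directed = directed, skipped = skipped, index = idx)
}

#' Symmetrized gPPI matrix
#'
#' Expands the per-edge symmetrized gPPI contrast vector into a symmetric
#' regions x regions matrix (zero diagonal).
#'
#' @param gppi the result of [runGPPI()]
#' @return symmetric numeric matrix
#' @export
gppiMatrix <- function(gppi) {
  p <- gppi$index@nRegions
  M <- matrix(0, p, p)
  M[gppi$index@pairs] <- gppi$contrast
  M[gppi$index@pairs[, 2:1, drop = FALSE]] <- gppi$contrast
  M
}
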