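#' @importFrom stats sd cor var
NULL

## ---------------------------------------------------------------------------
## TaskDesign
## ---------------------------------------------------------------------------

#' TaskDesign: a block-design task schedule
#'
#' Ordered, non-overlapping condition blocks (onset and duration in seconds)
#' for a single run, together with the run length in frames and the
#' repetition time (TR). Conditions are arbitrary labels; a conflict-task
#' run typically carries `"congruent"` and `"incongruent"` blocks separated
#' by unmodelled fixation periods.
#'
#' @slot blocks data.frame with columns `condition` (character),
#'   `onset` (seconds), `duration` (seconds), sorted by onset
#' @slot nFrames integer, number of acquired frames
#' @slot tr numeric, repetition time in seconds
#' @export
setClass("TaskDesign",
  representation(blocks = "data.frame", nFrames = "integer", tr = "numeric"))

setValidity("TaskDesign", function(object) {
  b <- object@blocks
  msg <- character()
  need <- c("condition", "onset", "duration")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns", paste(need, collapse = ", ")))
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (length(object@nFrames) != 1L || object@nFrames < 2L)
    msg <- c(msg, "nFrames must be >= 2")
  if (nrow(b) > 0L) {
    if (is.unsorted(b$onset)) msg <- c(msg, "blocks must be sorted by onset")
    if (any(b$duration <= 0)) msg <- c(msg, "block durations must be positive")
    if (any(b$onset < 0)) msg <- c(msg, "block onsets must be non-negative")
    ends <- b$onset + b$duration
    if (nrow(b) > 1L && any(b$onset[-1L] < ends[-nrow(b)] - 1e-9))
      msg <- c(msg, "blocks must be pairwise non-overlapping")
    if (length(msg) == 0L &&
        any(ends > object@nFrames * object@tr + 1e-9))
      msg <- c(msg, "every block must fit inside the run")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TaskDesign
#'
#' @param blocks data.frame with columns `condition`, `onset`, `duration`
#'   (seconds); rows are sorted by onset internally
#' @param nFrames number of frames in the run
#' @param tr repetition time in seconds
#' @return a [TaskDesign-class] object
#' @examples
#' td <- taskDesign(data.frame(condition = c("congruent", "incongruent"),
#'                             onset = c(10, 80), duration = c(56, 56)),
#'                  nFrames = 280, tr = 2)
#' @export
taskDesign <- function(blocks, nFrames, tr) {
  blocks <- as.data.frame(blocks)
  blocks$condition <- as.character(blocks$condition)
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  rownames(blocks) <- NULL
  new("TaskDesign", blocks = blocks, nFrames = as.integer(nFrames),
      tr = as.numeric(tr))
}

#' Conditions present in a TaskDesign
#' @param design a [TaskDesign-class]
#' @return character vector of unique condition labels, in onset order
#' @export
designConditions <- function(design) unique(design@blocks$condition)

#' @rdname edgets-accessors
#' @export
setMethod("taskBlocks", "TaskDesign", function(x, ...) x@blocks)

#' @rdname edgets-accessors
#' @export
setMethod("nFrames", "TaskDesign", function(x, ...) x@nFrames)

#' @rdname edgets-accessors
#' @export
setMethod("repTime", "TaskDesign", function(x, ...) x@tr)

setMethod("show", "TaskDesign", function(object) {
  cat(sprintf("TaskDesign: %d block(s), %d frames, TR = %g s\n",
              nrow(object@blocks), object@nFrames, object@tr))
  tab <- table(object@blocks$condition)
  if (length(tab))
    cat("  blocks per condition:",
        paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ParcelSeries
## ---------------------------------------------------------------------------

#' ParcelSeries: parcellated BOLD signals
#'
#' A frames x regions matrix of region-averaged BOLD time series with its
#' TR, region identifiers and (optional) intrinsic-system labels.
#'
#' @slot values numeric matrix, frames x regions
#' @slot tr repetition time in seconds
#' @slot regionIds character, one id per region (column names of `values`)
#' @slot systems character, intrinsic system label per region (may be empty)
#' @export
setClass("ParcelSeries",
  representation(values = "matrix", tr = "numeric",
                 regionIds = "character", systems = "character"))

setValidity("ParcelSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  p <- ncol(object@values)
  if (length(object@regionIds) != p)
    msg <- c(msg, "regionIds length must equal the number of regions")
  if (anyDuplicated(object@regionIds))
    msg <- c(msg, "regionIds must be unique")
  if (length(object@systems) && length(object@systems) != p)
    msg <- c(msg, "systems must be empty or one label per region")
  if (length(msg)) msg else TRUE
})

#' Construct a ParcelSeries
#'
#' @param values frames x regions numeric matrix
#' @param tr repetition time in seconds
#' @param regionIds region identifiers; defaults to column names or `r1..rP`
#' @param systems optional intrinsic-system label per region
#' @return a [ParcelSeries-class]
#' @export
parcelSeries <- function(values, tr, regionIds = NULL, systems = character()) {
  values <- as.matrix(values)
  if (is.null(regionIds))
    regionIds <- if (!is.null(colnames(values))) colnames(values)
                 else paste0("r", seq_len(ncol(values)))
  colnames(values) <- regionIds
  new("ParcelSeries", values = values, tr = as.numeric(tr),
      regionIds = as.character(regionIds), systems = as.character(systems))
}

#' @rdname edgets-accessors
#' @export
setMethod("signalValues", "ParcelSeries", function(x, ...) x@values)

#' @rdname edgets-accessors
#' @export
setMethod("repTime", "ParcelSeries", function(x, ...) x@tr)

#' @rdname edgets-accessors
#' @export
setMethod("nFrames", "ParcelSeries", function(x, ...) nrow(x@values))

#' @rdname edgets-accessors
#' @export
setMethod("nRegions", "ParcelSeries", function(x, ...) ncol(x@values))

#' @rdname edgets-accessors
#' @export
setMethod("regionIds", "ParcelSeries", function(x, ...) x@regionIds)

#' @rdname edgets-accessors
#' @export
setMethod("systemLabels", "ParcelSeries", function(x, ...) x@systems)

setMethod("show", "ParcelSeries", function(object) {
  cat(sprintf("ParcelSeries: %d frames x %d regions, TR = %g s\n",
              nrow(object@values), ncol(object@values), object@tr))
  if (length(object@systems))
    cat("  systems:", paste(unique(object@systems), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DesignMatrix
## ---------------------------------------------------------------------------

#' DesignMatrix: a GLM design with column roles
#'
#' A frames x columns design matrix whose columns carry unique names and a
#' role tag (`intercept`, `task_main`, `task_derivative`, `fir`, `motion`,
#' `tissue`, `global`, `cosine`).
#'
#' @slot values numeric matrix
#' @slot roles character role tag per column
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", roles = "character"))

.design_roles <- c("intercept", "task_main", "task_derivative", "fir",
                   "motion", "tissue", "global", "cosine")

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (is.null(colnames(object@values)) ||
      anyDuplicated(colnames(object@values)))
    msg <- c(msg, "columns must have unique names")
  if (length(object@roles) != ncol(object@values))
    msg <- c(msg, "one role per column required")
  if (!all(object@roles %in% .design_roles))
    msg <- c(msg, paste("roles must be in:",
                        paste(.design_roles, collapse = ", ")))
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  ok0 <- object@roles %in% c("task_main", "task_derivative", "fir")
  zero <- apply(object@values, 2L, function(v) all(v == 0))
  if (any(zero & !ok0))
    msg <- c(msg, "non-task columns must not be all zero")
  if (length(msg)) msg else TRUE
})

designMatrix <- function(values, roles) {
  new("DesignMatrix", values = as.matrix(values), roles = as.character(roles))
}

#' @rdname edgets-accessors
#' @export
setMethod("signalValues", "DesignMatrix", function(x, ...) x@values)

#' Column roles of a DesignMatrix
#' @param x a [DesignMatrix-class]
#' @return character vector of role tags, named by column
#' @export
designRoles <- function(x) {
  stopifnot(is(x, "DesignMatrix"))
  structure(x@roles, names = colnames(x@values))
}

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d frames x %d columns\n",
              nrow(object@values), ncol(object@values)))
  tab <- table(factor(object@roles, levels = .design_roles))
  tab <- tab[tab > 0]
  cat("  roles:",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## EdgeIndex / EdgeSeries
## ---------------------------------------------------------------------------

#' EdgeIndex: canonical upper-triangular edge ordering
#'
#' Bijection between edge positions `1..P(P-1)/2` and region pairs
#' `(i, j)` with `i < j`, ordered row-major over the upper triangle:
#' (1,2), (1,3), ..., (1,P), (2,3), ...
#'
#' @slot nRegions integer
#' @slot pairs integer matrix, edges x 2, columns `i`, `j`
#' @export
setClass("EdgeIndex",
  representation(nRegions = "integer", pairs = "matrix"))

setValidity("EdgeIndex", function(object) {
  p <- object@nRegions
  e <- p * (p - 1L) / 2L
  if (nrow(object@pairs) != e)
    return("pairs must have P(P-1)/2 rows")
  if (!all(object@pairs[, 1L] < object@pairs[, 2L]))
    return("pairs must satisfy i < j")
  TRUE
})

#' Construct the canonical EdgeIndex for P regions
#' @param nRegions number of regions (>= 2)
#' @return an [EdgeIndex-class]
#' @examples
#' edgeIndex(268)  # 35778 edges
#' @export
edgeIndex <- function(nRegions) {
  p <- as.integer(nRegions)
  stopifnot(p >= 2L)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  new("EdgeIndex", nRegions = p,
      pairs = cbind(i = i, j = j, deparse.level = 0L))
}

#' Edge position <-> region pair maps
#'
#' `pairToPos` maps a pair (i, j), i < j, to its position in the canonical
#' row-major upper-triangle ordering; `posToPair` is its inverse.
#'
#' @param index an [EdgeIndex-class]
#' @param i,j region indices with i < j (vectors allowed)
#' @param pos edge positions (vector allowed)
#' @return integer positions / a 2-column matrix of pairs
#' @export
pairToPos <- function(index, i, j) {
  p <- index@nRegions
  stopifnot(all(i >= 1L), all(j <= p), all(i < j))
  as.integer((i - 1) * (2 * p - i) / 2 + (j - i))
}

#' @rdname pairToPos
#' @export
posToPair <- function(index, pos) {
  stopifnot(all(pos >= 1L), all(pos <= nrow(index@pairs)))
  index@pairs[pos, , drop = FALSE]
}

#' @rdname edgets-accessors
#' @export
setMethod("nRegions", "EdgeIndex", function(x, ...) x@nRegions)

#' @rdname edgets-accessors
#' @export
setMethod("edgePairs", "EdgeIndex", function(x, ...) x@pairs)

#' @rdname edgets-accessors
#' @export
setMethod("nEdges", "EdgeIndex", function(x, ...) nrow(x@pairs))

setMethod("show", "EdgeIndex", function(object) {
  cat(sprintf("EdgeIndex: %d regions, %d edges (i < j, row-major)\n",
              object@nRegions, nrow(object@pairs)))
})

#' EdgeSeries: cofluctuation (edge) time series
#'
#' Frames x edges matrix whose column for edge (i, j) is the element-wise
#' product of the standardized parent series z_i and z_j. Summing a column
#' and dividing by T - 1 recovers the parents' Pearson correlation, so each
#' column is a temporal decomposition of one functional connection.
#'
#' @slot values numeric matrix, frames x edges
#' @slot index an [EdgeIndex-class]
#' @slot tr repetition time in seconds
#' @export
setClass("EdgeSeries",
  representation(values = "matrix", index = "EdgeIndex", tr = "numeric"))

setValidity("EdgeSeries", function(object) {
  msg <- character()
  if (ncol(object@values) != nrow(object@index@pairs))
    msg <- c(msg, "one column per edge required")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname edgets-accessors
#' @export
setMethod("signalValues", "EdgeSeries", function(x, ...) x@values)

#' @rdname edgets-accessors
#' @export
setMethod("repTime", "EdgeSeries", function(x, ...) x@tr)

#' @rdname edgets-accessors
#' @export
setMethod("nFrames", "EdgeSeries", function(x, ...) nrow(x@values))

#' @rdname edgets-accessors
#' @export
setMethod("nEdges", "EdgeSeries", function(x, ...) ncol(x@values))

#' @rdname edgets-accessors
#' @export
setMethod("edgePairs", "EdgeSeries", function(x, ...) x@index@pairs)

setMethod("show", "EdgeSeries", function(object) {
  cat(sprintf("EdgeSeries: %d frames x %d edges (%d regions), TR = %g s\n",
              nrow(object@values), ncol(object@values),
              object@index@nRegions, object@tr))
})

## ---------------------------------------------------------------------------
## GLMFit
## ---------------------------------------------------------------------------

#' GLMFit: a mass-univariate OLS fit
#'
#' Coefficients, residual variances and AR(1) coefficients for a set of
#' target series regressed on a common design (per-target whitened design
#' when prewhitening is on).
#'
#' @slot coefficients regressors x targets matrix
#' @slot sigma2 residual variance per target (RSS / dof)
#' @slot dof residual degrees of freedom (frames - design rank)
#' @slot rho AR(1) coefficient per target (0 when prewhitening disabled)
#' @slot covUnscaled regressors x regressors x targets array of
#'   (X'X)^-1 for the (whitened) design
#' @slot rank design rank
#' @export
setClass("GLMFit",
  representation(coefficients = "matrix", sigma2 = "numeric",
                 dof = "numeric", rho = "numeric",
                 covUnscaled = "array", rank = "integer"))

setValidity("GLMFit", function(object) {
  msg <- character()
  m <- ncol(object@coefficients)
  if (length(object@sigma2) != m || length(object@rho) != m)
    msg <- c(msg, "sigma2 and rho must have one entry per target")
  if (any(object@sigma2 < 0)) msg <- c(msg, "sigma2 must be non-negative")
  if (object@dof <= 0) msg <- c(msg, "dof must be positive")
  if (any(abs(object@rho) >= 1)) msg <- c(msg, "|rho| must be < 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d regressors x %d targets, dof = %g\n",
              nrow(object@coefficients), ncol(object@coefficients),
              object@dof))
  if (any(object@rho != 0))
    cat(sprintf("  AR(1) prewhitened, median rho = %.3f\n",
                stats::median(object@rho)))
})

#' @describeIn GLMFit-class extract the coefficient matrix
#' @param object a GLMFit
#' @export
setMethod("coef", "GLMFit", function(object) object@coefficients)

## ---------------------------------------------------------------------------
## StatMap / GroupMap
## ---------------------------------------------------------------------------

#' StatMap: per-element contrast statistics
#'
#' Effect estimates, t statistics and two-sided p values for one contrast
#' over a set of elements (nodes or edges), at subject level.
#'
#' @slot elements element identifiers
#' @slot effect contrast estimate per element
#' @slot t t statistic per element
#' @slot p two-sided p value per element
#' @slot dof degrees of freedom
#' @export
setClass("StatMap",
  representation(elements = "character", effect = "numeric",
                 t = "numeric", p = "numeric", dof = "numeric"))

setValidity("StatMap", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (length(object@effect) != n || length(object@t) != n ||
      length(object@p) != n)
    msg <- c(msg, "effect, t, p must match elements in length")
  pp <- object@p[is.finite(object@p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1)))
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

statMap <- function(elements, effect, t, p, dof) {
  new("StatMap", elements = as.character(elements),
      effect = as.numeric(effect), t = as.numeric(t),
      p = as.numeric(p), dof = as.numeric(dof))
}

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: %d elements, dof = %g\n",
              length(object@elements), object@dof))
})

#' GroupMap: group-level contrast statistics
#'
#' One-sample (or paired-difference) t statistics across subjects, with a
#' multiplicity-corrected significance mask. Degrees of freedom are
#' N - 1 with N the number of subjects.
#'
#' @slot nSubjects number of subjects
#' @slot mask logical significance indicator per element
#' @slot correction one of `"holm"`, `"bh"`, `"none"`
#' @slot alpha significance level used for `mask`
#' @export
setClass("GroupMap", contains = "StatMap",
  representation(nSubjects = "integer", mask = "logical",
                 correction = "character", alpha = "numeric"))

setValidity("GroupMap", function(object) {
  msg <- character()
  if (length(object@mask) != length(object@elements))
    msg <- c(msg, "mask must match elements in length")
  if (!object@correction %in% c("holm", "bh", "none"))
    msg <- c(msg, "correction must be holm, bh or none")
  if (object@dof != object@nSubjects - 1L)
    msg <- c(msg, "group dof must equal nSubjects - 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroupMap", function(object) {
  cat(sprintf(
    "GroupMap: %d elements, N = %d subjects, %d significant (%s, alpha = %g)\n",
    length(object@elements), object@nSubjects, sum(object@mask),
    object@correction, object@alpha))
})

## ---------------------------------------------------------------------------
## SubjectRun
## ---------------------------------------------------------------------------

#' SubjectRun: one acquisition for one subject
#'
#' Parcellated BOLD series plus the task schedule (or `NULL` for rest) and
#' the confound table (6 motion columns, white matter, CSF, global signal).
#'
#' @slot parcels a [ParcelSeries-class]
#' @slot design a [TaskDesign-class] or `NULL` (rest run)
#' @slot confounds data.frame, one row per frame
#' @slot subjectId,runId identifiers
#' @export
setClass("SubjectRun",
  representation(parcels = "ParcelSeries", design = "ANY",
                 confounds = "data.frame",
                 subjectId = "character", runId = "character"))

setValidity("SubjectRun", function(object) {
  msg <- character()
  tf <- nrow(object@parcels@values)
  if (nrow(object@confounds) != tf)
    msg <- c(msg, "confounds must have one row per frame")
  if (!is.null(object@design)) {
    if (!is(object@design, "TaskDesign"))
      return("design must be a TaskDesign or NULL")
    if (object@design@nFrames != tf)
      msg <- c(msg, "design nFrames must match the parcel series")
    if (abs(object@design@tr - object@parcels@tr) > 1e-9)
      msg <- c(msg, "design TR must match the parcel series")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectRun
#' @param parcels a [ParcelSeries-class]
#' @param design a [TaskDesign-class], or `NULL` for a rest run
#' @param confounds data.frame of nuisance series (one row per frame)
#' @param subjectId,runId identifiers
#' @return a [SubjectRun-class]
#' @export
subjectRun <- function(parcels, design = NULL, confounds,
                       subjectId = "sub-01", runId = "run-01") {
  new("SubjectRun", parcels = parcels, design = design,
      confounds = as.data.frame(confounds),
      subjectId = as.character(subjectId), runId = as.character(runId))
}

#' Is a run a rest (task-free) acquisition?
#' @param run a [SubjectRun-class]
#' @export
isRestRun <- function(run) is.null(run@design)

setMethod("show", "SubjectRun", function(object) {
  cat(sprintf("SubjectRun %s/%s: %s, %d frames x %d regions\n",
              object@subjectId, object@runId,
              if (is.null(object@design)) "rest" else "task",
              nrow(object@parcels@values), ncol(object@parcels@values)))
})
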