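## Regressor construction: HRF triplets, FIR basis, cosine drift, expanded
## motion, and the three design presets (denoise, node activation, edge GLM).

## Canonical double-gamma constants, SPM convention: response gamma with
## shape 6, undershoot gamma with shape 16, both rate 1 (seconds), undershoot
## ratio 1/6; kernel support 32 s. The dispersion derivative perturbs the
## width parameter d (gamma shape p/d, scale d) by .HRF$d_step.
.HRF <- list(p_resp = 6, p_under = 16, ratio = 6, span = 32,
             t_step = 1, d_step = 0.01)

#' Canonical double-gamma HRF kernel
#'
#' Evaluates the gamma-difference hemodynamic response kernel at times `t`
#' (seconds): a response gamma density (shape 6, scale 1) minus a delayed
#' undershoot gamma (shape 16, scale 1) divided by 6. `dispersion`
#' rescales the widths (shape p/dispersion, scale dispersion). The kernel is
#' normalized so that a sampled version sums to 1 over its 32-s support at
#' the given `tr`, making a sustained block's convolved plateau equal 1 and
#' GLM effects interpretable in signal units.
#'
#' @param t times in seconds (>= 0 contribute; negative times give 0)
#' @param tr repetition time used for the unit-sum normalization
#' @param dispersion width scaling, default 1
#' @return numeric vector of kernel values at `t`
#' @export
hrfKernel <- function(t, tr = 2, dispersion = 1) {
  raw <- function(u, d) {
    v <- numeric(length(u))
    ok <- u >= 0
    v[ok] <- stats::dgamma(u[ok], shape = .HRF$p_resp / d, scale = d) -
      stats::dgamma(u[ok], shape = .HRF$p_under / d, scale = d) / .HRF$ratio
    v
  }
  grid <- seq(0, .HRF$span, by = tr)
  norm <- sum(raw(grid, 1))   # reference normalization, dispersion = 1
  raw(t, dispersion) / norm
}

## condition boxcar at frame resolution: frame f (0-based) is inside a block
## iff f * tr lies in [onset, onset + duration)
.boxcar <- function(design, condition) {
  b <- design@blocks[design@blocks$condition == condition, , drop = FALSE]
  tt <- (seq_len(design@nFrames) - 1) * design@tr
  x <- numeric(design@nFrames)
  for (k in seq_len(nrow(b)))
    x[tt >= b$onset[k] & tt < b$onset[k] + b$duration[k]] <- 1
  x
}

## causal discrete convolution truncated to n frames, optional oversampling
.convolve_hrf <- function(stim, tr, n, dispersion = 1, oversample = 1L) {
  if (oversample > 1L) {
    trf <- tr / oversample
    sf <- rep(stim, each = oversample)
    kf <- hrfKernel(seq(0, .HRF$span, by = trf), tr = trf,
                    dispersion = dispersion)
    conv <- stats::convolve(sf, rev(kf), type = "open")[seq_along(sf)]
    conv[seq(1L, by = oversample, length.out = n)]
  } else {
    k <- hrfKernel(seq(0, .HRF$span, by = tr), tr = tr,
                   dispersion = dispersion)
    stats::convolve(stim, rev(k), type = "open")[seq_len(n)]
  }
}

#' HRF regressor triplet for one condition
#'
#' Convolves the condition's boxcar with the canonical double-gamma kernel
#' and returns the main regressor together with its temporal-derivative and
#' dispersion-derivative columns (finite differences in onset time and in
#' the width parameter). With `hrf = "boxcar"` the raw frame-resolution
#' boxcar is returned instead (robustness variant; the derivative columns
#' are then backward time differences of the boxcar and zeros).
#'
#' @param design a [TaskDesign-class]
#' @param condition condition label; must occur in the design or be listed
#'   in `knownConditions`
#' @param hrf `"double-gamma"` (default) or `"boxcar"`
#' @param oversample integer oversampling factor for the convolution grid
#' @param knownConditions labels accepted even if absent from this run
#'   (their columns are all zero)
#' @return frames x 3 matrix with columns `<condition>`,
#'   `<condition>_tderiv`, `<condition>_dderiv`
#' @export
hrfTriplet <- function(design, condition, hrf = c("double-gamma", "boxcar"),
                       oversample = 1L, knownConditions = character()) {
  hrf <- match.arg(hrf)
  known <- union(designConditions(design), knownConditions)
  if (!condition %in% known)
    stop("unknown condition label: ", condition)
  n <- design@nFrames; tr <- design@tr
  stim <- .boxcar(design, condition)
  if (hrf == "boxcar") {
    main <- stim
    tder <- c(0, diff(stim))
    dder <- numeric(n)
  } else {
    main <- .convolve_hrf(stim, tr, n, oversample = oversample)
    ## temporal derivative: (h(t) - h(t - step)) / step pushed through the
    ## convolution, i.e. convolve with the time-shifted kernel
    ts <- .HRF$t_step
    klag <- hrfKernel(seq(0, .HRF$span, by = tr) - ts, tr = tr)
    lagged <- stats::convolve(stim, rev(klag), type = "open")[seq_len(n)]
    tder <- (main - lagged) / ts
    dd <- .HRF$d_step
    dder <- (main -
      .convolve_hrf(stim, tr, n, dispersion = 1 + dd,
                    oversample = oversample)) / dd
  }
  out <- cbind(main, tder, dder)
  colnames(out) <- paste0(condition, c("", "_tderiv", "_dderiv"))
  out
}

#' Finite impulse response (FIR) task basis
#'
#' For each condition, `nLags` columns of lagged frame-resolution stimulus
#' indicators: column k (k = 0..nLags-1) is the condition boxcar delayed by
#' k frames, truncated at the run end. With TR = 2 s, the default 12 lags
#' span about 24 s of post-stimulus response.
#'
#' @param design a [TaskDesign-class]
#' @param nLags number of lags per condition (>= 1)
#' @param conditions conditions to include; defaults to all in the design
#' @return frames x (nLags * conditions) matrix, columns
#'   `<condition>_fir<k>`
#' @export
firBasis <- function(design, nLags = 12L, conditions = NULL) {
  nLags <- as.integer(nLags)
  stopifnot(nLags >= 1L)
  n <- design@nFrames
  if (nLags * design@tr > n * design@tr)
    stop("nLags * tr exceeds the run length")
  if (is.null(conditions)) conditions <- designConditions(design)
  cols <- lapply(conditions, function(cnd) {
    stim <- .boxcar(design, cnd)
    sapply(seq_len(nLags) - 1L, function(k)
      c(numeric(k), stim)[seq_len(n)])
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(conditions, function(cnd)
    paste0(cnd, "_fir", seq_len(nLags) - 1L), character(nLags)))
  out
}

#' Discrete-cosine drift basis
#'
#' Discrete cosine transform columns for harmonics k >= 1 whose period
#' `2 * nFrames * tr / k` strictly exceeds `cutoff` seconds, each column
#' normalized to unit Euclidean norm. For a 280-frame run at TR = 2 s and a
#' 187-s cutoff this yields 5 columns.
#'
#' @param nFrames number of frames (>= 2)
#' @param tr repetition time in seconds
#' @param cutoff high-pass period cutoff in seconds
#' @return frames x K matrix (possibly zero columns), columns `cosine<k>`
#' @export
cosineBasis <- function(nFrames, tr, cutoff) {
  stopifnot(nFrames >= 2L, tr > 0, cutoff > 0)
  kmax <- floor(2 * nFrames * tr / cutoff)
  ks <- seq_len(max(kmax, 0L))
  ks <- ks[2 * nFrames * tr / ks > cutoff]   # strict inequality
  tt <- seq_len(nFrames) - 0.5
  out <- sapply(ks, function(k) {
    v <- cos(pi * k * tt / nFrames)
    v / sqrt(sum(v^2))
  })
  out <- matrix(out, nrow = nFrames)
  colnames(out) <- if (length(ks)) paste0("cosine", ks) else character()
  out
}

#' Expanded 24-parameter motion set
#'
#' From 6 rigid-body motion series (3 translations, 3 rotations) builds the
#' standard 24-parameter expansion: the 6 originals, their backward-
#' difference derivatives (first frame set to 0), and the squares of all 12,
#' in that fixed order.
#'
#' @param motion frames x 6 numeric matrix or data.frame
#' @return frames x 24 matrix, columns `<name>`, `<name>_d`, `<name>_sq`,
#'   `<name>_d_sq`
#' @export
expandMotion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have exactly 6 columns, got ", ncol(motion))
  if (nrow(motion) < 2L) stop("motion needs at least 2 frames")
  nm <- colnames(motion)
  if (is.null(nm)) nm <- paste0("mot", 1:6)
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(nm, paste0(nm, "_d"), paste0(nm, "_sq"),
                     paste0(nm, "_d_sq"))
  out
}

#' Assemble a DesignMatrix from column blocks
#'
#' Horizontally concatenates named column blocks, tagging each block with a
#' role, and optionally appends an intercept column.
#'
#' @param parts named list of frames x k matrices; names must be role tags
#'   (`task_main`, `task_derivative`, `fir`, `motion`, `tissue`, `global`,
#'   `cosine`); a part may repeat via list names like `tissue.wm`
#' @param includeIntercept append an all-ones `intercept` column (default
#'   TRUE)
#' @return a [DesignMatrix-class]
#' @export
buildDesign <- function(parts = list(), includeIntercept = TRUE) {
  mats <- list(); roles <- character()
  nf <- NULL
  for (nm in names(parts)) {
    if (is.null(parts[[nm]])) next
    m <- as.matrix(parts[[nm]])
    if (ncol(m) == 0L) next
    role <- sub("\\..*$", "", nm)
    if (!role %in% .design_roles)
      stop("unknown design role: ", role)
    if (is.null(nf)) nf <- nrow(m)
    if (nrow(m) != nf) stop("frame count mismatch in design part ", nm)
    mats[[length(mats) + 1L]] <- m
    roles <- c(roles, rep(role, ncol(m)))
  }
  if (includeIntercept) {
    if (is.null(nf)) stop("cannot infer frame count for an intercept-only ",
                          "design; supply at least one part or use ",
                          "interceptDesign(nFrames)")
    mats[[length(mats) + 1L]] <- matrix(1, nf, 1,
                                        dimnames = list(NULL, "intercept"))
    roles <- c(roles, "intercept")
  }
  X <- do.call(cbind, mats)
  if (anyDuplicated(colnames(X)))
    stop("duplicate design column names: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  designMatrix(X, roles)
}

#' Intercept-only design
#' @param nFrames number of frames
#' @return a [DesignMatrix-class] with a single all-ones column
#' @export
interceptDesign <- function(nFrames) {
  designMatrix(matrix(1, nFrames, 1, dimnames = list(NULL, "intercept")),
               "intercept")
}

## split a confound table into motion / tissue / global parts using a
## column-name mapping (fMRIPrep dialect by default)
.confound_parts <- function(confounds, mapping = confoundMapping()) {
  cn <- names(confounds)
  pick <- function(keys) {
    hit <- vapply(keys, function(k) {
      w <- which(cn %in% k)
      if (length(w)) w[1L] else NA_integer_
    }, integer(1L))
    if (any(is.na(hit)))
      stop("confound columns not found: ",
           paste(unlist(keys[is.na(hit)]), collapse = ", "))
    as.matrix(confounds[, hit, drop = FALSE])
  }
  list(motion = pick(mapping$motion),
       wm = pick(mapping["wm"]), csf = pick(mapping["csf"]),
       global = pick(mapping["global"]))
}

#' Confound column-name mapping
#'
#' Accepted column names for the confound table, fMRIPrep dialect by
#' default. Each entry may list alternative names; the first present wins.
#'
#' @param motion list of 6 acceptable-name vectors for the motion columns
#' @param wm,csf,global acceptable-name vectors for tissue/global columns
#' @return a named list usable as the `mapping` argument of the design
#'   preset builders and [readConfounds()]
#' @export
confoundMapping <- function(
    motion = list("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z"),
    wm = "white_matter", csf = "csf", global = "global_signal") {
  list(motion = motion, wm = wm, csf = csf, global = global)
}

#' Design presets: denoise, node activation, edge GLM
#'
#' The three design-matrix flavors of the pipeline.
#'
#' `denoiseDesign`: FIR task block (12 lags per condition by default,
#' omitted when `removeTask = FALSE` or for rest runs) + 24 expanded motion
#' parameters + white matter + CSF + global signal (droppable via
#' `gsr = FALSE`) + cosine drift (187-s cutoff) + intercept. For a
#' 280-frame task run with two conditions: 24 + 24 + 1 + 1 + 1 + 5 + 1 = 57
#' columns.
#'
#' `activationDesign`: HRF triplets per condition + the same covariates +
#' intercept.
#'
#' `edgeDesign`: intercept + HRF triplets per condition (7 columns for two
#' conditions); intercept-only for rest runs.
#'
#' @param design a [TaskDesign-class], or `NULL` for rest
#' @param confounds confound data.frame (motion 6, wm, csf, global)
#' @param nFrames,tr frame count and repetition time (taken from `design`
#'   when given)
#' @param removeTask include the FIR task block in the denoise design
#' @param gsr include the global-signal column
#' @param hrf `"double-gamma"` or `"boxcar"` task regressors
#' @param nLags FIR lags per condition
#' @param cutoff cosine drift cutoff in seconds
#' @param mapping confound column-name mapping, see [confoundMapping()]
#' @return a [DesignMatrix-class]
#' @name designPresets
NULL

#' @rdname designPresets
#' @export
denoiseDesign <- function(design, confounds, nFrames = NULL, tr = NULL,
                          removeTask = TRUE, gsr = TRUE, nLags = 12L,
                          cutoff = 187, mapping = confoundMapping()) {
  if (!is.null(design)) { nFrames <- design@nFrames; tr <- design@tr }
  cp <- .confound_parts(confounds, mapping)
  parts <- list()
  if (!is.null(design) && removeTask)
    parts$fir <- firBasis(design, nLags = nLags)
  parts$motion <- expandMotion(cp$motion)
  parts$tissue.wm <- cp$wm
  parts$tissue.csf <- cp$csf
  if (gsr) parts$global <- cp$global
  parts$cosine <- cosineBasis(nFrames, tr, cutoff)
  buildDesign(parts, includeIntercept = TRUE)
}

#' @rdname designPresets
#' @export
activationDesign <- function(design, confounds, gsr = TRUE,
                             hrf = "double-gamma", cutoff = 187,
                             mapping = confoundMapping()) {
  cp <- .confound_parts(confounds, mapping)
  trip <- lapply(designConditions(design), hrfTriplet, design = design,
                 hrf = hrf)
  mains <- do.call(cbind, lapply(trip, function(m) m[, 1L, drop = FALSE]))
  ders <- do.call(cbind, lapply(trip, function(m) m[, 2:3, drop = FALSE]))
  buildDesign(list(task_main = mains, task_derivative = ders,
                   motion = expandMotion(cp$motion),
                   tissue.wm = cp$wm, tissue.csf = cp$csf,
                   global = if (gsr) cp$global else NULL,
                   cosine = cosineBasis(design@nFrames, design@tr, cutoff)),
              includeIntercept = TRUE)
}

#' @rdname designPresets
#' @export
edgeDesign <- function(design, nFrames = NULL, hrf = "double-gamma") {
  if (is.null(design)) return(interceptDesign(nFrames))
  trip <- lapply(designConditions(design), hrfTriplet, design = design,
                 hrf = hrf)
  mains <- do.call(cbind, lapply(trip, function(m) m[, 1L, drop = FALSE]))
  ders <- do.call(cbind, lapply(trip, function(m) m[, 2:3, drop = FALSE]))
  buildDesign(list(task_main = mains, task_derivative = ders),
              includeIntercept = TRUE)
}
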