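## Readers and writers for the standard tabular formats (BIDS-style
## events.tsv, fMRIPrep-style confounds TSV, parcel TSV), parcel extraction
## from volumetric images, cohort serialization and provenance sidecars.

#' Read a BIDS-style events table into a TaskDesign
#'
#' Expects tab-separated columns `onset`, `duration`, `trial_type`
#' (seconds). Trial types can be renamed via `conditionMap` (e.g. mapping
#' acquisition-specific labels onto `congruent` / `incongruent`); unmapped
#' trial types are dropped with a message (fixation rows are typically
#' unmodelled).
#'
#' @param path events.tsv path
#' @param nFrames,tr run geometry (not stored in the events file)
#' @param conditionMap optional named character vector `old = new`
#' @return a [TaskDesign-class]
#' @export
readEvents <- function(path, nFrames, tr, conditionMap = NULL) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  .check_na(ev[need], path)
  if (!is.null(conditionMap)) {
    keep <- ev$trial_type %in% names(conditionMap)
    if (any(!keep))
      message(sum(!keep), " event row(s) with unmapped trial_type dropped")
    ev <- ev[keep, , drop = FALSE]
    ev$trial_type <- unname(conditionMap[ev$trial_type])
  }
  taskDesign(data.frame(condition = ev$trial_type, onset = ev$onset,
                        duration = ev$duration),
             nFrames = nFrames, tr = tr)
}

.check_na <- function(df, path) {
  bad <- which(rowSums(is.na(df)) > 0)
  if (length(bad))
    stop("missing values in ", path, " at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
}

#' Read a confound table
#'
#' Tab-separated table with the six motion columns plus white matter, CSF
#' and global signal, resolved through a [confoundMapping()] (alternative
#' column dialects are accepted by extending the mapping). Extra columns
#' are kept.
#'
#' @param path confounds TSV path
#' @param mapping a [confoundMapping()]
#' @return data.frame with canonical column names `trans_x..rot_z`,
#'   `white_matter`, `csf`, `global_signal` (plus any extras)
#' @export
readConfounds <- function(path, mapping = confoundMapping()) {
  cf <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  canonical <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  resolve <- function(keys, canon) {
    hit <- intersect(unlist(keys), names(cf))
    if (!length(hit))
      stop("confounds file missing column: ",
           paste(unlist(keys), collapse = " / "))
    names(cf)[names(cf) == hit[1L]] <<- canon
  }
  for (k in seq_along(mapping$motion))
    resolve(mapping$motion[[k]], canonical[k])
  resolve(mapping$wm, "white_matter")
  resolve(mapping$csf, "csf")
  resolve(mapping$global, "global_signal")
  .check_na(cf[c(canonical, "white_matter", "csf", "global_signal")], path)
  cf
}

#' Read / write a parcel series table
#'
#' Tab-separated frames x regions table with region ids as the header. TR
#' is supplied by the caller (or a JSON sidecar written by
#' [writeParcels()]).
#'
#' @param path parcel TSV path
#' @param tr repetition time; if `NULL`, read from the `<path>.json`
#'   sidecar
#' @param systems optional system labels (read from the sidecar when
#'   present)
#' @return a [ParcelSeries-class]
#' @export
readParcels <- function(path, tr = NULL, systems = character()) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  .check_na(tab, path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(tr)) tr <- meta$tr
    if (!length(systems) && !is.null(meta$systems))
      systems <- meta$systems
  }
  if (is.null(tr)) stop("TR not given and no sidecar found for ", path)
  parcelSeries(as.matrix(tab), tr = tr, regionIds = names(tab),
               systems = systems)
}

#' @rdname readParcels
#' @param parcels a [ParcelSeries-class]
#' @export
writeParcels <- function(parcels, path) {
  df <- as.data.frame(parcels@values)
  names(df) <- parcels@regionIds
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(tr = parcels@tr, systems = parcels@systems),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a TaskDesign as a BIDS-style events.tsv
#' @param design a [TaskDesign-class]
#' @param path output path
#' @export
writeEvents <- function(design, path) {
  b <- design@blocks
  utils::write.table(
    data.frame(onset = b$onset, duration = b$duration,
               trial_type = b$condition),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a confound table
#' @param confounds data.frame of confound series
#' @param path output path
#' @export
writeConfounds <- function(confounds, path) {
  utils::write.table(confounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk in pipeline input formats
#'
#' One directory per subject with parcel TSVs (+ JSON sidecars carrying TR
#' and system labels), events.tsv per task run and confounds TSVs, plus a
#' cohort-level `truth.json` (planted edge sets, amplitude vectors, rho,
#' seed) and a `manifest.json` listing every written file. Manifest paths
#' are relative to `dir`, so identical cohorts produce identical trees
#' wherever they are written.
#'
#' @param cohort result of [generateCohort()]
#' @param dir output directory (created)
#' @return the manifest (invisibly), as a nested list
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (runName in c("taskA", "taskB", "rest")) {
    for (sid in names(cohort[[runName]])) {
      run <- cohort[[runName]][[sid]]
      sd <- file.path(dir, sid)
      dir.create(sd, showWarnings = FALSE)
      pp <- file.path(sid, paste0(runName, "_parcels.tsv"))
      cp <- file.path(sid, paste0(runName, "_confounds.tsv"))
      writeParcels(run@parcels, file.path(dir, pp))
      writeConfounds(run@confounds, file.path(dir, cp))
      entry <- list(parcels = pp, confounds = cp)
      if (!is.null(run@design)) {
        ep <- file.path(sid, paste0(runName, "_events.tsv"))
        writeEvents(run@design, file.path(dir, ep))
        entry$events <- ep
      }
      manifest[[sid]][[runName]] <- entry
    }
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(deltaEdges = truth$deltaEdges,
         amplitudeCongruent = truth$ampCong$taskA,
         amplitudeIncongruent = truth$ampInc$taskA,
         rho = truth$rho, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Load a SubjectRun from files on disk
#'
#' @param parcelsPath parcel TSV (sidecar supplies TR when `tr` is `NULL`)
#' @param confoundsPath confounds TSV
#' @param eventsPath events.tsv, or `NULL` for a rest run
#' @param tr repetition time override
#' @param subjectId,runId identifiers
#' @param conditionMap trial-type mapping for [readEvents()]
#' @param mapping confound column mapping
#' @return a [SubjectRun-class]
#' @export
readSubjectRun <- function(parcelsPath, confoundsPath, eventsPath = NULL,
                           tr = NULL, subjectId = "sub-01",
                           runId = "run-01", conditionMap = NULL,
                           mapping = confoundMapping()) {
  parcels <- readParcels(parcelsPath, tr = tr)
  confounds <- readConfounds(confoundsPath, mapping = mapping)
  design <- if (!is.null(eventsPath))
    readEvents(eventsPath, nFrames = nFrames(parcels),
               tr = repTime(parcels), conditionMap = conditionMap)
  subjectRun(parcels, design = design, confounds = confounds,
             subjectId = subjectId, runId = runId)
}

#' Extract parcel-average series from a 4D volume
#'
#' Per frame and atlas label, the arithmetic mean over that label's
#' voxels; labels are ascending, 0 is background. Paths are read with the
#' RNifti package (a suggested dependency); in-memory arrays are accepted
#' directly.
#'
#' @param image 4D numeric array (x, y, z, frames) or NIfTI path
#' @param atlas 3D integer label array or NIfTI path, same grid
#' @param tr repetition time of the output series
#' @return a [ParcelSeries-class], one column per label
#' @export
parcellate <- function(image, atlas, tr) {
  loadVol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI paths requires the RNifti package")
      as.array(RNifti::readNifti(x))
    } else as.array(x)
  }
  img <- loadVol(image); atl <- loadVol(atlas)
  if (length(dim(img)) == 3L) dim(img) <- c(dim(img), 1L)
  if (!all(dim(img)[1:3] == dim(atl)))
    stop("image and atlas grids differ")
  labels <- sort(unique(as.integer(atl[atl > 0])))
  if (!length(labels)) stop("atlas contains no labels >= 1")
  nT <- dim(img)[4L]
  flat <- matrix(img, ncol = nT)
  lab <- as.integer(atl)
  out <- sapply(labels, function(l) {
    vox <- which(lab == l)
    if (!length(vox)) stop("empty atlas label: ", l)
    colMeans(flat[vox, , drop = FALSE])
  })
  out <- matrix(out, nrow = nT)
  parcelSeries(out, tr = tr, regionIds = as.character(labels))
}

#' Write a StatMap / GroupMap as TSV
#'
#' Node maps get columns `element, effect, t, p, dof`; group maps add
#' `p_adjusted`-style mask, and `r` (the t -> correlation transform).
#'
#' @param map a [StatMap-class] or [GroupMap-class]
#' @param path output path
#' @export
writeStatMap <- function(map, path) {
  df <- data.frame(element = map@elements, effect = map@effect,
                   t = map@t, p = map@p, dof = map@dof)
  if (is(map, "GroupMap")) {
    df$significant <- map@mask
    df$r <- tToR(map@t, map@nSubjects)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Provenance sidecar
#'
#' Writes `<path>.json` echoing the pipeline configuration, seed and
#' package version, sufficient to reproduce the output.
#'
#' @param path the output file the sidecar describes
#' @param config a [pipelineConfig()] or [cohortConfig()] list
#' @param seed the seed used
#' @export
writeProvenance <- function(path, config, seed = NA_integer_) {
  cfg <- config
  cfg$mapping <- NULL
  jsonlite::write_json(
    list(config = cfg, seed = seed,
         package = as.character(utils::packageVersion("edgets"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
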