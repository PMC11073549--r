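## End-to-end cohort orchestration: subject-level node and edge estimation
## for two tasks, group maps, and the between-task similarity comparison.

#' Subject-level beta maps for a list of runs
#'
#' Runs the activation (node) GLM and the edge (cofluctuation) GLM for
#' every subject and collects the condition-contrast beta and t maps.
#'
#' @param runs list of task [SubjectRun-class] objects
#' @param config a [pipelineConfig()] list
#' @return list with matrices `activationBeta`, `activationT`,
#'   `networkBeta`, `networkT` (subjects x elements) and `index`
#'   (the [EdgeIndex-class])
#' @export
fitSubjects <- function(runs, config = pipelineConfig()) {
  ns <- length(runs)
  actB <- NULL; actT <- NULL; netB <- NULL; netT <- NULL; idx <- NULL
  for (s in seq_len(ns)) {
    ag <- runActivationGLM(runs[[s]], config)
    eg <- runEdgeGLM(runs[[s]], config)
    if (is.null(actB)) {
      actB <- matrix(0, ns, length(ag$map@effect),
                     dimnames = list(names(runs), ag$map@elements))
      actT <- actB
      netB <- matrix(0, ns, length(eg$contrast@effect),
                     dimnames = list(names(runs), eg$contrast@elements))
      netT <- netB
      idx <- eg$edges@index
    }
    actB[s, ] <- ag$map@effect; actT[s, ] <- ag$map@t
    netB[s, ] <- eg$contrast@effect; netT[s, ] <- eg$contrast@t
  }
  list(activationBeta = actB, activationT = actT,
       networkBeta = netB, networkT = netT, index = idx)
}

#' Between-task activation/network similarity comparison
#'
#' The full comparison for a two-task cohort: subject-level node and edge
#' contrast maps per task, group-level one-sample maps (Holm-corrected),
#' Spearman correlations and Dice coefficients between the tasks' group
#' maps at both the activation and network levels, and the subject-level
#' beta-map similarity with its paired t test.
#'
#' @param cohort a [generateCohort()] result, or any list with `taskA` and
#'   `taskB` lists of task [SubjectRun-class] objects
#' @param config a [pipelineConfig()] list
#' @param alpha significance level for the Dice masks (default 0.05)
#' @return list with `fits` (per-task [fitSubjects()] output), `group`
#'   (per-task, per-level [GroupMap-class] objects), `groupActivationRho`,
#'   `groupNetworkRho`, `activationDice`, `networkDice`, and `subject`
#'   (the [subjectLevelSimilarity()] result)
#' @export
compareTasks <- function(cohort, config = pipelineConfig(), alpha = 0.05) {
  fa <- fitSubjects(cohort$taskA, config)
  fb <- fitSubjects(cohort$taskB, config)
  ga <- list(activation = oneSampleMap(fa$activationBeta, "holm", alpha),
             network = oneSampleMap(fa$networkBeta, "holm", alpha))
  gb <- list(activation = oneSampleMap(fb$activationBeta, "holm", alpha),
             network = oneSampleMap(fb$networkBeta, "holm", alpha))
  subj <- subjectLevelSimilarity(fa$activationBeta, fb$activationBeta,
                                 fa$networkBeta, fb$networkBeta)
  list(fits = list(taskA = fa, taskB = fb),
       group = list(taskA = ga, taskB = gb),
       groupActivationRho = spearmanMap(ga$activation@t, gb$activation@t),
       groupNetworkRho = spearmanMap(ga$network@t, gb$network@t),
       activationDice = diceCoefficient(ga$activation@mask,
                                        gb$activation@mask),
       networkDice = diceCoefficient(ga$network@mask, gb$network@mask),
       subject = subj)
}
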