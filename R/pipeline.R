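#' Derive a child seed from a master seed
#'
#' Deterministic integer hash of the master seed plus a string tag, kept
#' below 2^31 so it is always a valid [set.seed()] argument. Hierarchical
#' seeding (master -> subject -> stage) makes any single subject
#' independently re-simulable.
#'
#' @param master integer master seed.
#' @param ... tags (strings or numbers) identifying the stream.
#' @return a positive integer seed.
#' @export
deriveSeed <- function(master, ...) {
  tags <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Pipeline configuration
#'
#' Bundles the stage configurations of a full simulated experiment. The
#' defaults are a desk-scale profile: 12 subjects and 2 runs per
#' session, with the per-run structure (200 trials over 10 levels)
#' intact. `nPerm = 200` keeps the permutation FWE step fast; raise it
#' for finer p-values.
#'
#' @param nSubjects simulated cohort size.
#' @param nRuns runs per session.
#' @param nPerm sign-flip permutations for the group analysis.
#' @param delta injected P170 percept modulation, microvolts.
#' @param noiseSd per-trial channel noise SD, microvolts.
#' @param subjectScaleSd between-subject SD of the component amplitude
#'   scaling factor (mean 1).
#' @param detectionNoiseSd staircase criterion noise, mA.
#' @param masterSeed master seed for all stages.
#' @param cohort a [cohortSpec()] (its `n` is overridden by
#'   `nSubjects`).
#' @param session a [sessionConfig()] (its `nRuns` is overridden).
#' @param preproc a [preprocConfig()].
#' @param outDir optional output directory for tables; NULL disables
#'   file output.
#' @export
pipelineConfig <- function(nSubjects = 12L, nRuns = 2L, nPerm = 200L,
                           delta = 2, noiseSd = 8, subjectScaleSd = 0.2,
                           detectionNoiseSd = 0.05, masterSeed = 1L,
                           cohort = cohortSpec(), session = sessionConfig(),
                           preproc = preprocConfig(), outDir = NULL) {
  cohort$n <- as.integer(nSubjects)
  session$nRuns <- as.integer(nRuns)
  structure(list(nSubjects = as.integer(nSubjects), nRuns = as.integer(nRuns),
                 nPerm = as.integer(nPerm), delta = delta, noiseSd = noiseSd,
                 subjectScaleSd = subjectScaleSd,
                 detectionNoiseSd = detectionNoiseSd,
                 masterSeed = as.integer(masterSeed), cohort = cohort,
                 session = session, preproc = preproc, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; nested
#' blocks `cohort` and `session` mirror [cohortSpec()] and
#' [sessionConfig()]. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohortSpec, c(y$cohort, list()))
  session <- do.call(sessionConfig, c(y$session, list()))
  args <- y[setdiff(names(y), c("cohort", "session"))]
  do.call(pipelineConfig,
          c(args, list(cohort = cohort, session = session)))
}

#' Calibrate one observer
#'
#' The full calibration chain: detection staircase (doubled intensity),
#' initial threshold staircase, 15-ISI psychometric session, logistic
#' fit, 10-level design and trial allocation. The initial staircase
#' estimate is floored at 3 ms so the calibration grid (which must
#' start at 2 ms below its centre) is always constructible.
#'
#' @param obs an [Observer-class].
#' @param detectionNoiseSd staircase criterion noise, mA.
#' @return list `detection`, `intensity`, `initialStdt`, `fit`,
#'   `design` (an [ISIDesign-class]).
#' @export
calibrateObserver <- function(obs, detectionNoiseSd = 0.05) {
  det <- runDetectionStaircase(obs, noiseSd = detectionNoiseSd)
  intensity <- stimulusIntensity(det$estimate)
  # adaptive descending start: when the ascending series stop above the
  # descending start (observer range exceeds it), the experimenter
  # restarts the descending series higher
  ds <- 120
  for (attempt in 1:5) {
    st <- runStdtStaircase(obs, descendingStart = ds)
    ascMean <- mean(st$stops[c(TRUE, FALSE)])
    if (ascMean < ds - 5) break
    ds <- ds * 2
  }
  stdt0 <- max(st$estimate, 3)
  isis <- calibrationIsis(stdt0)
  counts <- runCalibrationSession(obs, isis)
  fit <- fitLogistic(counts)
  levels <- designIsiLevels(fit)
  design <- ISIDesign(levels, allocateTrials(levels))
  list(detection = det, intensity = intensity, initialStdt = stdt0,
       fit = fit, design = design)
}

#' Run the full simulated experiment
#'
#' Composes all stages in experiment order: cohort sampling,
#' per-observer calibration, matching-task sessions, behavioural
#' Bayes-factor statistics (reaction-time difference, percept-report
#' dissociation), near-threshold trial selection, synthetic epoched EEG
#' with the percept-dependent P170 modulation, preprocessing (artifact
#' rejection, low-pass, baseline), scalp-volume interpolation,
#' first-level contrasts and the group-level cluster analysis with the
#' threshold covariate.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `"ExperimentResult"`: `config`, `observers`,
#'   `calibrations`, `behavior` (felt-two %, BF results, STDT stats),
#'   `stdtTrials` counts, `group` (the [clusterFwe()] result),
#'   `stdts`, `excluded`.
#' @export
runFullExperiment <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  seedOf <- function(...) deriveSeed(config$masterSeed, ...)
  set.seed(seedOf("cohort"))
  observers <- sampleCohort(config$cohort)
  layout <- standardLayout64()
  components <- defaultComponents(config$delta)
  calibrations <- list(); sessions <- list(); contrasts <- list()
  feltTwo <- numeric(0); rtOne <- numeric(0); rtTwo <- numeric(0)
  dissocBF <- list(); stdts <- numeric(0); nStdtTrials <- integer(0)
  driftCov <- numeric(0)
  excluded <- character(0)
  for (obs in observers) {
    set.seed(seedOf(obs@id, "calibration"))
    cal <- tryCatch(calibrateObserver(obs, config$detectionNoiseSd),
                    error = function(e) e)
    if (inherits(cal, "error")) {
      excluded <- c(excluded, obs@id)
      next
    }
    set.seed(seedOf(obs@id, "session"))
    skel <- buildSession(cal$design, config$session)
    trials <- simulateSession(obs, skel, config$session)
    live <- trials[!trials$missed, ]
    feltTwo <- c(feltTwo, 100 * mean(live$percept == "two"))
    rtOne <- c(rtOne, mean(live$rt[live$percept == "one"]))
    rtTwo <- c(rtTwo, mean(live$rt[live$percept == "two"]))
    dissocBF[[obs@id]] <- contingencyBF01(dissociationTable(trials))
    runFits <- lapply(split(trials, trials$run), function(tr) {
      agg <- aggregate(cbind(nTwo = percept == "two") ~ isi_ms, tr,
                       FUN = sum)
      agg$nTrials <- aggregate(percept ~ isi_ms, tr, FUN = length)$percept
      names(agg)[1] <- "isi"
      fitLogistic(agg)
    })
    stdtTr <- selectStdtTrials(trials, runFits)
    stdts <- c(stdts, cal$fit@t50)
    nStdtTrials <- c(nStdtTrials, nrow(stdtTr))
    driftCov <- c(driftCov, mean(stdtTr$isi_level))
    set.seed(seedOf(obs@id, "eeg"))
    subjScale <- rnorm(1, 1, config$subjectScaleSd)
    scaled <- lapply(components, function(cp) {
      cp$ampOne <- cp$ampOne * subjScale
      cp$ampTwo <- cp$ampTwo * subjScale
      cp
    })
    epochs <- simulateSubjectEpochs(stdtTr, scaled, layout,
                                    noiseSd = config$noiseSd)
    rej <- rejectArtifacts(epochs, config$preproc)
    cleaned <- baselineCorrect(lowpassEpochs(rej$epochs, config$preproc),
                               config$preproc$baselineWindowS)
    vols <- scalpInterpolate(cleaned)
    contrasts[[obs@id]] <- firstLevel(vols, cleaned@trialMeta$percept)
    calibrations[[obs@id]] <- cal
    sessions[[obs@id]] <- trials
  }
  if (length(contrasts) < 8)
    stop("too few analysable subjects (", length(contrasts), ")")
  rtBF <- jzsPairedBF(rtTwo - rtOne)
  groupVols <- bindContrasts(contrasts)
  set.seed(seedOf("group"))
  group <- clusterFwe(groupVols, covariate = stdts, nPerm = config$nPerm)
  behavior <- list(
    feltTwoPct = feltTwo, meanFeltTwoPct = mean(feltTwo),
    stdtMean = mean(stdts), stdtMedian = median(stdts),
    rtBF = rtBF, dissociationBF = dissocBF,
    nStdtTrials = nStdtTrials)
  res <- list(config = config, observers = observers,
              calibrations = calibrations, behavior = behavior,
              group = group, volumes = groupVols, stdts = stdts,
              driftCovariate = driftCov, excluded = excluded)
  class(res) <- "ExperimentResult"
  if (!is.null(config$outDir)) writeExperimentOutputs(res, config$outDir)
  res
}

writeExperimentOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeObserverTable(res$observers, file.path(outDir, "observers.tsv"))
  writeFitTable(lapply(res$calibrations, `[[`, "fit"),
                file.path(outDir, "fits.tsv"))
  writeClusterTable(res$group, file.path(outDir, "clusters.tsv"),
                    layout = standardLayout64())
  writeBFResults(c(list(rt = res$behavior$rtBF), res$behavior$dissociationBF),
                 file.path(outDir, "behavior_bf.json"))
  invisible(outDir)
}

#' Human-readable experiment report
#'
#' Markdown summary mirroring the usual results structure: behaviour
#' (felt-two percentage, threshold distribution, Bayes factors), then
#' the group cluster table.
#'
#' @param res an `"ExperimentResult"` from [runFullExperiment()].
#' @return character scalar (markdown).
#' @export
pipelineReport <- function(res) {
  b <- res$behavior
  lines <- c(
    "# Simulated experiment report", "",
    "## Behaviour",
    sprintf("- Felt-as-two: %.2f%% of trials (cohort mean over %d subjects)",
            b$meanFeltTwoPct, length(b$feltTwoPct)),
    sprintf("- STDT: mean %.2f ms, median %.2f ms", b$stdtMean, b$stdtMedian),
    sprintf("- Near-threshold trials per subject: %.0f (mean)",
            mean(b$nStdtTrials)),
    sprintf("- Reaction-time difference (two - one): BF10 = %.3g (%s)",
            b$rtBF$bf10, b$rtBF$category),
    sprintf("- Percept-report dissociation: BF01 range %.2f - %.2f (%s)",
            min(vapply(b$dissociationBF, `[[`, 1, "bf01")),
            max(vapply(b$dissociationBF, `[[`, 1, "bf01")),
            paste(unique(vapply(b$dissociationBF, `[[`, "", "category")),
                  collapse = ", ")),
    "", "## Group-level cluster analysis")
  cl <- res$group$clusters
  if (nrow(cl) == 0) {
    lines <- c(lines, "No significant cluster.")
  } else {
    lines <- c(lines,
      sprintf("- Cluster %d: k = %d voxels, %0.0f-%0.0f ms, peak t = %.2f at %.0f ms, p_FWE(cluster) = %.3f, p_FWE(peak) = %.3f",
              cl$cluster_id, cl$k_voxels, cl$time_min_ms, cl$time_max_ms,
              cl$t_peak, cl$peak_time_ms, cl$p_fwe_cluster, cl$p_fwe_peak))
  }
  paste(lines, collapse = "\n")
}

#' Simulate cohort-level matching-task behaviour
#'
#' Samples a cohort, runs each observer through the full behavioural
#' chain (detection and threshold staircases, 15-ISI calibration
#' session, logistic fit, individually calibrated 10-level design,
#' matching-task session) and summarizes behaviour. Observers whose
#' fitted design would collapse are excluded, mirroring the
#' experiment's exclusion rule.
#'
#' @param spec a [cohortSpec()].
#' @param session a [sessionConfig()].
#' @param masterSeed master seed.
#' @param detectionNoiseSd staircase criterion noise, mA.
#' @return list: `perObserver` data.frame (`observer_id, t50, fit_t50,
#'   felt_two_pct, n_trials`), `meanFeltTwoPct`, `stdtMean`,
#'   `stdtMedian`, `excluded`.
#' @export
simulateCohortBehavior <- function(spec = cohortSpec(),
                                   session = sessionConfig(),
                                   masterSeed = 1L,
                                   detectionNoiseSd = 0.05) {
  set.seed(deriveSeed(masterSeed, "cohort"))
  observers <- sampleCohort(spec)
  rows <- list(); excluded <- character(0)
  for (obs in observers) {
    set.seed(deriveSeed(masterSeed, obs@id, "behavior"))
    cal <- tryCatch(calibrateObserver(obs, detectionNoiseSd),
                    error = function(e) e)
    if (inherits(cal, "error")) {
      excluded <- c(excluded, obs@id)
      next
    }
    skel <- buildSession(cal$design, session)
    trials <- simulateSession(obs, skel, session)
    live <- trials[!trials$missed, ]
    rows[[obs@id]] <- data.frame(
      observer_id = obs@id, t50 = obs@t50, fit_t50 = cal$fit@t50,
      felt_two_pct = 100 * mean(live$percept == "two"),
      n_trials = nrow(trials))
  }
  per <- do.call(rbind, rows)
  list(perObserver = per, meanFeltTwoPct = mean(per$felt_two_pct),
       stdtMean = mean(per$fit_t50), stdtMedian = median(per$fit_t50),
       excluded = excluded)
}

#' Fast group-level simulation of one experiment
#'
#' Simulates a group study at the subject-contrast level (see
#' [simulateSubjectContrast()]) and runs the cluster analysis: used for
#' family-wise-error calibration under the global null (`delta = 0`)
#' and for power analysis of the injected P170 modulation.
#'
#' @param nSubjects subjects.
#' @param delta injected modulation, microvolts.
#' @param nPerCond trials per condition per subject.
#' @param nPerm permutations.
#' @param noiseSd per-trial channel noise SD.
#' @param subjectScaleSd between-subject amplitude SD.
#' @param layout a [ChannelLayout-class].
#' @param covariate optional per-subject covariate (defaults to random
#'   thresholds, exercising the covariate path).
#' @return the [clusterFwe()] result, plus `volumes` and the
#'   ground-truth `deltaField`.
#' @export
simulateGroupStudy <- function(nSubjects = 12L, delta = 2, nPerCond = 90L,
                               nPerm = 200L, noiseSd = 8,
                               subjectScaleSd = 0.2,
                               layout = standardLayout64(),
                               covariate = NULL) {
  components <- defaultComponents(delta)
  win <- epochWindow(512)
  mats <- lapply(seq_len(nSubjects), function(i)
    simulateSubjectContrast(nPerCond = nPerCond,
                            subjectScale = rnorm(1, 1, subjectScaleSd),
                            components = components, layout = layout,
                            noiseSd = noiseSd))
  vols <- channelsToVolumes(mats, layout, win$times)
  if (is.null(covariate))
    covariate <- rlnorm(nSubjects, log(30.38), 0.89)
  res <- clusterFwe(vols, covariate = covariate, nPerm = nPerm)
  res$volumes <- vols
  res$deltaField <- attr(mats[[1]], "deltaField")
  res
}
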