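#' Match truth of a percept-cue combination
#'
#' The visual cue announces "two" (white disk) or "one" (dark disk); the
#' trial is a match when the percept agrees with the cue:
#' (two, white) and (one, dark) are matches, the other two combinations
#' mismatches. Because the cue is drawn independently of the stimulus,
#' the overt match/mismatch report is decoupled from the percept.
#'
#' @param percept `"one"` or `"two"` (vectorized).
#' @param cue `"white"` (announces two) or `"dark"` (announces one).
#' @return `"match"` or `"mismatch"`.
#' @examples
#' evaluateMatch("two", "white")   # match
#' evaluateMatch("two", "dark")    # mismatch
#' @export
evaluateMatch <- function(percept, cue) {
  if (!all(percept %in% c("one", "two"))) stop("invalid percept")
  if (!all(cue %in% c("white", "dark"))) stop("invalid cue")
  ifelse((percept == "two") == (cue == "white"), "match", "mismatch")
}

#' Session configuration for the matching task
#'
#' @param nRuns runs per session (default 7; 6 reproduces the shorter
#'   sessions).
#' @param itiRange inter-trial interval range, seconds.
#' @param missRate probability of a missed (too slow) trial.
#' @param reportErrorRate probability that the overt report flips
#'   (default 0: participants passed a high-accuracy screen).
#' @param rtMeanlog,rtSdlog log-normal reaction-time parameters per
#'   percept, named `one` and `two`; equal by default (no reaction-time
#'   difference between percepts).
#' @export
sessionConfig <- function(nRuns = 7L, itiRange = c(0.7, 1.3),
                          missRate = 0.021, reportErrorRate = 0,
                          rtMeanlog = c(one = -1.183, two = -1.183),
                          rtSdlog = c(one = 0.154, two = 0.154)) {
  structure(list(nRuns = as.integer(nRuns), itiRange = itiRange,
                 missRate = missRate, reportErrorRate = reportErrorRate,
                 rtMeanlog = rtMeanlog, rtSdlog = rtSdlog),
            class = "SessionConfig")
}

#' Build the randomized trial skeletons of a session
#'
#' Each run presents exactly the design's per-level trial counts in
#' randomized order; cues are drawn 50/50 independently of the ISI and
#' the response side is counterbalanced within runs.
#'
#' @param design an [ISIDesign-class].
#' @param cfg a [sessionConfig()].
#' @return data.frame of trial skeletons with onset times.
#' @export
buildSession <- function(design, cfg = sessionConfig()) {
  stopifnot(is(design, "ISIDesign"))
  runs <- lapply(seq_len(cfg$nRuns), function(r) {
    lev <- sample(rep(seq_len(10L), design@countsPerRun))
    n <- length(lev)
    side <- sample(rep(c("left", "right"), length.out = n))
    iti <- runif(n, cfg$itiRange[1], cfg$itiRange[2])
    data.frame(run = r, trial_index = seq_len(n), isi_level = lev,
               isi_ms = design@levels[lev],
               cue = sample(c("white", "dark"), n, replace = TRUE),
               response_side = side, onset = cumsum(iti) - iti[1])
  })
  do.call(rbind, runs)
}

#' Simulate matching-task responses for a session
#'
#' Draws the percept from the observer's psychometric function at each
#' trial's ISI, evaluates the match truth against the cue, and produces
#' the overt report (equal to the truth except for an optional symmetric
#' report-error rate), a percept-conditional log-normal reaction time,
#' and a missed flag. Missed trials carry no report and no valid
#' reaction time.
#'
#' @param obs an [Observer-class].
#' @param skeletons trial skeletons from [buildSession()].
#' @param cfg a [sessionConfig()].
#' @return data.frame of trial records.
#' @export
simulateSession <- function(obs, skeletons, cfg = sessionConfig()) {
  n <- nrow(skeletons)
  percept <- simulateDiscrimination(skeletons$isi_ms, obs)
  truth <- evaluateMatch(percept, skeletons$cue)
  report <- truth
  if (cfg$reportErrorRate > 0) {
    flip <- runif(n) < cfg$reportErrorRate
    report[flip] <- ifelse(truth[flip] == "match", "mismatch", "match")
  }
  rt <- exp(rnorm(n, cfg$rtMeanlog[percept], cfg$rtSdlog[percept]))
  missed <- runif(n) < cfg$missRate
  report[missed] <- NA_character_
  rt[missed] <- NA_real_
  out <- skeletons
  out$percept <- percept
  out$match_truth <- truth
  out$report <- report
  out$rt <- rt
  out$missed <- missed
  out
}

#' Select near-threshold ("STDT") trials
#'
#' For each run, keeps the non-missed trials of the single ISI level
#' whose ISI lies closest to that run's fitted threshold; ties are broken
#' toward the lower level. Restricting to one level per run holds the
#' physical stimulus constant within the percept contrast.
#'
#' @param trials trial records with `run`, `isi_level`, `isi_ms`,
#'   `missed` columns.
#' @param runFits named or ordered list of [PsychometricFit-class]
#'   objects, one per run present in `trials`.
#' @return the selected subset of `trials`.
#' @export
selectStdtTrials <- function(trials, runFits) {
  runs <- sort(unique(trials$run))
  if (is.null(names(runFits))) names(runFits) <- as.character(runs)
  picked <- lapply(runs, function(r) {
    f <- runFits[[as.character(r)]]
    if (is.null(f)) stop("missing psychometric fit for run ", r)
    tr <- trials[trials$run == r & !trials$missed, ]
    lev <- sort(unique(tr$isi_level))
    isiByLevel <- vapply(lev, function(l) tr$isi_ms[tr$isi_level == l][1],
                         numeric(1))
    dist <- abs(isiByLevel - f@t50)
    best <- lev[which.min(dist)]   # which.min takes the first = lower level
    tr[tr$isi_level == best, ]
  })
  do.call(rbind, picked)
}

#' Percept-by-report contingency table
#'
#' 2x2 counts of percept (one/two) against overt report
#' (match/mismatch), missed trials excluded. Under 50/50 cue
#' randomization independent of the stimulus, percept and report are
#' independent by construction; the downstream Bayesian test of
#' association quantifies the evidence for that independence.
#'
#' @param trials trial records.
#' @return 2x2 integer matrix, rows percept, columns report.
#' @export
dissociationTable <- function(trials) {
  tr <- trials[!trials$missed & !is.na(trials$report), ]
  if (nrow(tr) == 0) stop("no non-missed trials")
  table(factor(tr$percept, c("one", "two")),
        factor(tr$report, c("match", "mismatch")))
}

#' Write a session's events as a BIDS-like TSV
#'
#' @param trials trial records from [simulateSession()].
#' @param path output file.
#' @param duration stimulus duration column value, seconds.
#' @export
writeEventsTsv <- function(trials, path, duration = 0.0004) {
  cols <- c("onset", "duration", "run", "trial_index", "isi_level", "isi_ms",
            "cue", "percept", "match_truth", "report", "response_side",
            "rt", "missed")
  tab <- trials
  tab$duration <- duration + tab$isi_ms / 1000
  tab <- tab[, intersect(cols, names(tab))]
  tab[is.na(tab)] <- "n/a"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
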