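#' Staircase configuration
#'
#' Parameters of the single-pulse intensity staircase: start at
#' `startIntensity`, ascend in `initialStep` increments until the pulse is
#' felt, then halve the step and reverse direction at every response
#' change, for `nUp` ascending and `nDown` descending progressions in
#' total.
#'
#' @param startIntensity starting intensity, mA (default 1).
#' @param initialStep first step size, mA (default 0.1).
#' @param nUp,nDown number of ascending / descending progressions
#'   (defaults 3 each).
#' @param maxSteps safety cap on total steps (default 200).
#' @export
staircaseConfig <- function(startIntensity = 1.0, initialStep = 0.1,
                            nUp = 3L, nDown = 3L, maxSteps = 200L) {
  if (initialStep <= 0) stop("initialStep must be positive")
  if (nUp < 1 || nDown < 1) stop("progression counts must be >= 1")
  structure(list(startIntensity = startIntensity, initialStep = initialStep,
                 nUp = as.integer(nUp), nDown = as.integer(nDown),
                 maxSteps = as.integer(maxSteps)),
            class = "StaircaseConfig")
}

#' Run the detection-intensity staircase
#'
#' Alternating ascending/descending runs starting ascending from
#' `cfg$startIntensity`. Each ascending run increases the intensity by
#' the current step until the observer reports feeling the pulse; each
#' descending run decreases it until the pulse is no longer felt. The
#' first response change ends the progression (its intensity is the
#' reversal value), the step is halved and the direction flips. The
#' threshold estimate is the arithmetic mean of all reversal values.
#'
#' @param obs an [Observer-class].
#' @param cfg a [staircaseConfig()].
#' @param noiseSd detection criterion noise passed to
#'   [simulateDetection()]; 0 gives a deterministic staircase.
#' @return list with `estimate` (mA), `reversals`, and `trace`
#'   (data.frame of `intensity`, `felt`, `direction`).
#' @examples
#' st <- runDetectionStaircase(Observer(40, 8, detThreshold = 2.33))
#' st$estimate   # 2.3390625
#' @export
runDetectionStaircase <- function(obs, cfg = staircaseConfig(), noiseSd = 0) {
  stopifnot(is(obs, "Observer"))
  value <- cfg$startIntensity
  step <- cfg$initialStep
  ascending <- TRUE
  reversals <- numeric(0)
  upLeft <- cfg$nUp; downLeft <- cfg$nDown
  vals <- numeric(0); resp <- logical(0); dirs <- character(0)
  nsteps <- 0L
  while (upLeft > 0L || downLeft > 0L) {
    value <- value + if (ascending) step else -step
    felt <- simulateDetection(value, obs, noiseSd)
    nsteps <- nsteps + 1L
    vals <- c(vals, value); resp <- c(resp, felt)
    dirs <- c(dirs, if (ascending) "up" else "down")
    if (nsteps > cfg$maxSteps)
      stop("staircase failure: no response change within ", cfg$maxSteps,
           " steps")
    if ((ascending && felt) || (!ascending && !felt)) {
      reversals <- c(reversals, value)
      if (ascending) upLeft <- upLeft - 1L else downLeft <- downLeft - 1L
      step <- step / 2
      ascending <- !ascending
    }
  }
  list(estimate = mean(reversals), reversals = reversals,
       trace = data.frame(intensity = vals, felt = resp, direction = dirs))
}

#' Stimulation intensity from the detection-threshold estimate
#'
#' The main-experiment intensity is twice the individual detection
#' threshold, so that no pulse can be missed for being too weak.
#'
#' @param estimate detection-threshold estimate, mA; > 0.
#' @export
stimulusIntensity <- function(estimate) {
  if (any(estimate <= 0)) stop("estimate must be positive")
  2 * estimate
}

#' Run the initial discrimination-threshold (STDT) staircase
#'
#' Three ascending and three descending ISI series, interleaved
#' A, D, A, D, A, D. An ascending series starts at `ascendingStart` and
#' increases the ISI by `step` until the percept first switches to "two";
#' a descending series starts at `descendingStart` and decreases until
#' the percept first switches to "one". The initial threshold estimate is
#' the mean of the six stopping ISIs.
#'
#' @param obs an [Observer-class].
#' @param ascendingStart,descendingStart series starting ISIs, ms
#'   (defaults 2 and 120).
#' @param step series step, ms (default 5).
#' @param nSeries series per direction (default 3).
#' @param maxSteps safety cap per series.
#' @return list with `estimate` (ms) and `stops` (the six stopping ISIs,
#'   in presentation order).
#' @export
runStdtStaircase <- function(obs, ascendingStart = 2, descendingStart = 120,
                             step = 5, nSeries = 3L, maxSteps = 200L) {
  stopifnot(is(obs, "Observer"))
  if (ascendingStart >= descendingStart)
    stop("ascendingStart must be below descendingStart")
  if (step <= 0) stop("step must be positive")
  oneSeries <- function(start, dir) {
    isi <- start
    for (i in seq_len(maxSteps)) {
      percept <- simulateDiscrimination(max(isi, 0), obs)
      if (dir > 0 && percept == "two") return(isi)
      if (dir < 0 && percept == "one") return(isi)
      isi <- isi + dir * step
      if (isi < 0) isi <- 0
    }
    stop("staircase failure: no percept switch within ", maxSteps, " steps")
  }
  stops <- numeric(2 * nSeries)
  for (k in seq_len(nSeries)) {
    stops[2 * k - 1] <- oneSeries(ascendingStart, +1)
    stops[2 * k] <- oneSeries(descendingStart, -1)
  }
  list(estimate = mean(stops), stops = stops)
}

#' The 15 calibration ISIs
#'
#' Fifteen linearly spaced ISIs with the initial threshold estimate as
#' the central (8th) value and 2 ms as the lowest; the top value is thus
#' `2 * initialStdt - 2` and the spacing `(initialStdt - 2) / 7`.
#'
#' @param initialStdt initial discrimination-threshold estimate, ms;
#'   must exceed 2.
#' @return numeric(15).
#' @examples
#' calibrationIsis(44)   # 2, 8, ..., 86
#' @export
calibrationIsis <- function(initialStdt) {
  if (initialStdt <= 2)
    stop("initialStdt must exceed 2 ms; re-run the staircase")
  seq(2, 2 * initialStdt - 2, length.out = 15)
}

#' Run the psychometric estimation session
#'
#' Presents each calibration ISI `reps` times (default 20, i.e. 300
#' trials over the 15 ISIs) and counts "felt as two" responses.
#'
#' @param obs an [Observer-class].
#' @param isis ISI values, ms.
#' @param reps repetitions per ISI.
#' @return data.frame `isi, nTwo, nTrials`.
#' @export
runCalibrationSession <- function(obs, isis, reps = 20L) {
  if (reps < 1) stop("reps must be >= 1")
  p <- psychometricP(isis, obs)
  data.frame(isi = isis, nTwo = rbinom(length(isis), reps, p),
             nTrials = rep(as.integer(reps), length(isis)))
}

#' Fit the two-parameter logistic psychometric function
#'
#' Maximum-likelihood fit of threshold and scale to per-ISI binomial
#' counts (no lapse term). The 1% and 99% thresholds follow from the
#' fitted parameters as `t50 -/+ scale * log(99)`; the reported `mse` is
#' the post-fit mean squared error between observed and fitted
#' proportions (a diagnostic, not the fitting criterion).
#'
#' @param counts data.frame with columns `isi`, `nTwo`, `nTrials` (as
#'   from [runCalibrationSession()]).
#' @return a [PsychometricFit-class].
#' @examples
#' obs <- Observer(40, 8)
#' counts <- data.frame(isi = calibrationIsis(40), nTrials = 20)
#' counts$nTwo <- round(20 * psychometricP(counts$isi, obs))
#' fitLogistic(counts)
#' @export
fitLogistic <- function(counts) {
  stopifnot(all(c("isi", "nTwo", "nTrials") %in% names(counts)))
  counts <- counts[counts$nTrials > 0, ]
  if (length(unique(counts$isi)) < 2)
    stop("need >= 2 distinct ISIs")
  if (all(counts$nTwo == 0) || all(counts$nTwo == counts$nTrials))
    stop("non-identifiable fit: all responses identical")
  isi <- counts$isi; k <- counts$nTwo; n <- counts$nTrials
  prop <- k / n
  # moment-style start: 50% crossing by interpolation, scale from the span
  t50Start <- tryCatch(approx(prop + 1e-9 * seq_along(prop), isi,
                              xout = 0.5, ties = "ordered")$y,
                       error = function(e) NA_real_)
  if (!is.finite(t50Start)) t50Start <- sum(isi * n * prop) / sum(n * prop)
  if (!is.finite(t50Start)) t50Start <- median(isi)
  scaleStart <- max(diff(range(isi)) / 10, 1e-2)
  negll <- function(par) {
    p <- plogis((isi - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  # the scale is box-bounded: with flat (or perfectly separated)
  # responses the unbounded MLE diverges to Inf (or 0); the bounds pin
  # such degenerate fits at a usable value without touching regular ones
  fit <- optim(c(t50Start, log(scaleStart)), negll, method = "L-BFGS-B",
               lower = c(-1e4, log(0.5)), upper = c(1e4, log(1e3)),
               control = list(maxit = 500, factr = 1e4))
  t50 <- fit$par[1]; sc <- exp(fit$par[2])
  mse <- mean((prop - plogis((isi - t50) / sc))^2)
  PsychometricFit(t50 = t50, scale = sc, mse = mse, nTrials = sum(n))
}

#' Main-experiment ISI levels from a psychometric fit
#'
#' Ten equally spaced ISIs spanning the fitted 1%..99% thresholds. When
#' the fitted `t01` falls below 1 ms (a pathology arising from imperfect
#' calibration responses), the minimum level is set to 1 ms, the maximum
#' is reduced by the same amount `delta = 1 - t01`, and the levels are
#' shifted symmetrically toward the threshold: the midpoint of the levels
#' is the fitted `t50` in both branches.
#'
#' @param fit a [PsychometricFit-class] with `t50 > 1`.
#' @return numeric(10) of ISI levels, ms.
#' @export
designIsiLevels <- function(fit) {
  stopifnot(is(fit, "PsychometricFit"))
  if (fit@t50 <= 1) stop("fit t50 must exceed 1 ms")
  lo <- fit@t01; hi <- fit@t99
  if (lo < 1) {
    # t99 - (1 - t01) == 2*t50 - 1 exactly; the right-hand form is
    # numerically stable when the fitted scale (hence |t01|) is large
    lo <- 1
    hi <- 2 * fit@t50 - 1
    if (hi <= 1)
      stop("design collapses (t99 - delta <= 1 ms); observer would be excluded")
  }
  seq(lo, hi, length.out = 10)
}

#' Per-run trial allocation over the 10 ISI levels
#'
#' The canonical symmetric, unimodal allocation of 200 trials per run:
#' the outer levels (1 and 10) carry 8 trials each and the central levels
#' (5 and 6) 32 each; the remaining 120 trials are distributed over
#' levels 2-4 and 7-9 proportionally to a normal density centred between
#' levels 5 and 6, whose width is pinned by the two anchor counts, with
#' largest-remainder rounding so each side sums to 60.
#'
#' @param levels the 10 ISI levels (only their count is used; allocation
#'   is positional).
#' @param runTrials trials per run (default 200).
#' @return integer(10) summing to `runTrials`; with the defaults,
#'   `c(8, 13, 20, 27, 32, 32, 27, 20, 13, 8)`.
#' @export
allocateTrials <- function(levels = NULL, runTrials = 200L) {
  if (!is.null(levels) && length(levels) != 10L)
    stop("expected 10 levels")
  anchorOuter <- 8; anchorInner <- 32
  centre <- 5.5
  dOuter <- 1 - centre; dInner <- 5 - centre
  # exact two-anchor fit: ratio pins sigma
  sigma2 <- (dOuter^2 - dInner^2) / (2 * log(anchorInner / anchorOuter))
  side <- (runTrials - 2 * anchorOuter - 2 * anchorInner) / 2
  d <- (2:4) - centre
  dens <- exp(-d^2 / (2 * sigma2))
  target <- side * dens / sum(dens)
  fl <- floor(target)
  rem <- side - sum(fl)
  ord <- order(target - fl, decreasing = TRUE)
  fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  half <- c(anchorOuter, fl, anchorInner)
  as.integer(c(half, rev(half)))
}

#' Write per-observer fit and design tables
#'
#' @param fits named list of [PsychometricFit-class] objects.
#' @param path output TSV.
#' @return the table, invisibly.
#' @export
writeFitTable <- function(fits, path) {
  tab <- data.frame(
    observer_id = names(fits),
    t50 = vapply(fits, function(f) f@t50, numeric(1)),
    scale = vapply(fits, function(f) f@scale, numeric(1)),
    t01 = vapply(fits, function(f) f@t01, numeric(1)),
    t99 = vapply(fits, function(f) f@t99, numeric(1)),
    mse = vapply(fits, function(f) f@mse, numeric(1)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname writeFitTable
#' @param design an [ISIDesign-class].
#' @export
writeDesignTable <- function(design, path) {
  tab <- data.frame(level = 1:10, isi_ms = design@levels,
                    trials_per_run = design@countsPerRun)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
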