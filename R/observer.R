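#' Psychometric function of an observer
#'
#' Probability that a double pulse with interstimulus interval `isi` is
#' felt as two pulses:
#' `p = lapse/2 + (1 - lapse) / (1 + exp(-(isi - t50)/scale))`.
#' With `lapse = 0` this is the plain two-parameter logistic with
#' `p(t50) = 0.5`.
#'
#' @param isi interstimulus interval(s), ms; must be finite and >= 0.
#' @param obs an [Observer-class].
#' @return probability of a "felt as two" response, same length as `isi`.
#' @examples
#' obs <- Observer(t50 = 40.51, scale = 8.28)
#' psychometricP(c(2.45, 40.51, 78.56), obs)
#' @export
psychometricP <- function(isi, obs) {
  stopifnot(is(obs, "Observer"))
  if (!all(is.finite(isi)) || any(isi < 0))
    stop("isi must be finite and non-negative")
  obs@lapse / 2 + (1 - obs@lapse) * plogis((isi - obs@t50) / obs@scale)
}

#' Slope of the psychometric function at threshold
#'
#' The derivative of [psychometricP()] at `isi = t50`, i.e.
#' `(1 - lapse) / (4 * scale)` per ms. This is the "slope at threshold"
#' parameterization often quoted alongside the threshold itself.
#'
#' @param obs an [Observer-class].
#' @export
psychometricSlope <- function(obs) (1 - obs@lapse) / (4 * obs@scale)

#' Simulate a single temporal-discrimination response
#'
#' Bernoulli draw from the observer's psychometric function. Uses R's
#' global random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param isi interstimulus interval(s), ms.
#' @param obs an [Observer-class].
#' @return character vector, `"one"` or `"two"` per ISI.
#' @export
simulateDiscrimination <- function(isi, obs) {
  p <- psychometricP(isi, obs)
  ifelse(runif(length(p)) < p, "two", "one")
}

#' Simulate a single-pulse detection response
#'
#' With `noiseSd = 0` the response is deterministic: felt if and only if
#' `intensity >= detThreshold` (the boundary counts as felt). With
#' `noiseSd > 0` the pulse is felt with probability
#' `pnorm((intensity - detThreshold) / noiseSd)`.
#'
#' @param intensity stimulus intensity, mA; >= 0.
#' @param obs an [Observer-class].
#' @param noiseSd standard deviation of the internal criterion noise, mA.
#' @return logical vector: TRUE when the pulse is felt.
#' @export
simulateDetection <- function(intensity, obs, noiseSd = 0) {
  stopifnot(is(obs, "Observer"))
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  # inclusive boundary with a tolerance absorbing step-accumulation error
  if (noiseSd == 0) return(intensity >= obs@detThreshold - 1e-9)
  runif(length(intensity)) < pnorm((intensity - obs@detThreshold) / noiseSd)
}

#' Cohort specification
#'
#' Population parameters for sampling a cohort of simulated observers.
#' Thresholds are log-normal (positive support and the right skew seen in
#' population data: mean above median); the log-normal shape parameter is
#' pinned by the median/mean pair via `sigma^2 = 2 * log(mean / median)`.
#'
#' @param n number of observers.
#' @param t50Median,t50Mean population median and mean of the
#'   discrimination threshold, ms (defaults: 30.38 / 45.19).
#' @param scaleMedian population median of the logistic scale, ms
#'   (default 8.28, the value implied by the population 1%/99% thresholds:
#'   `(78.56 - 2.45) / (2 * log(99))`).
#' @param scaleSigma log-normal sigma for the scale (default 0.4).
#' @param lapse shared lapse probability (default 0).
#' @param detMean,detSd detection-threshold population mean and SD, mA
#'   (defaults 2.425 / 0.46, i.e. half the reported doubled stimulation
#'   intensity 4.85 +/- 0.92 mA).
#' @return a list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n = 34L, t50Median = 30.38, t50Mean = 45.19,
                       scaleMedian = 8.28, scaleSigma = 0.4, lapse = 0,
                       detMean = 2.425, detSd = 0.46) {
  if (n < 1) stop("n must be >= 1")
  if (t50Mean < t50Median)
    stop("t50Mean must be >= t50Median (log-normal sigma would be imaginary)")
  if (t50Median <= 0) stop("t50Median must be positive")
  structure(list(n = as.integer(n), t50Median = t50Median, t50Mean = t50Mean,
                 scaleMedian = scaleMedian, scaleSigma = scaleSigma,
                 lapse = lapse, detMean = detMean, detSd = detSd),
            class = "CohortSpec")
}

#' Sample a cohort of observers
#'
#' Draws `spec$n` observers. `t50` is log-normal with the spec's median
#' and mean (`sigma = sqrt(2 * log(mean / median))`, `mu = log(median)`);
#' the scale is log-normal around its median; detection thresholds are
#' normal, truncated at 0.5 mA.
#'
#' @param spec a [cohortSpec()].
#' @return list of [Observer-class] objects.
#' @examples
#' set.seed(1)
#' cohort <- sampleCohort(cohortSpec(n = 5))
#' @export
sampleCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  sigma <- sqrt(2 * log(spec$t50Mean / spec$t50Median))
  t50 <- rlnorm(spec$n, meanlog = log(spec$t50Median), sdlog = sigma)
  sc <- rlnorm(spec$n, meanlog = log(spec$scaleMedian), sdlog = spec$scaleSigma)
  det <- pmax(0.5, rnorm(spec$n, spec$detMean, spec$detSd))
  lapply(seq_len(spec$n), function(i)
    Observer(t50 = t50[i], scale = sc[i], lapse = spec$lapse,
             detThreshold = det[i], id = sprintf("obs%02d", i)))
}

#' Write a cohort table
#'
#' TSV with columns `observer_id, t50_ms, scale_ms, lapse,
#' det_threshold_mA`.
#'
#' @param cohort list of [Observer-class] objects.
#' @param path output file.
#' @return the table, invisibly.
#' @export
writeObserverTable <- function(cohort, path) {
  tab <- data.frame(
    observer_id = vapply(cohort, function(o) o@id, character(1)),
    t50_ms = vapply(cohort, function(o) o@t50, numeric(1)),
    scale_ms = vapply(cohort, function(o) o@scale, numeric(1)),
    lapse = vapply(cohort, function(o) o@lapse, numeric(1)),
    det_threshold_mA = vapply(cohort, function(o) o@detThreshold, numeric(1)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
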