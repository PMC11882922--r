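#' @import methods
#' @importFrom stats aggregate approx dcauchy dnorm dt integrate lm
#'   median optim pbinom plogis pnorm pt qnorm qt quantile rbinom
#'   rlnorm rnorm runif sd setNames fft mvfft rgamma var coef rbeta
#' @importFrom utils head tail write.table read.table
NULL

#' Psychophysical observer
#'
#' An `Observer` holds the latent parameters that generate behaviour in a
#' somatosensory temporal discrimination experiment: the discrimination
#' threshold `t50` (the interstimulus interval, in ms, at which a double
#' pulse is felt as two pulses on half of trials), the logistic scale `s`
#' (ms; the slope of the psychometric function at `t50` is
#' `(1 - lapse) / (4 s)` per ms), a lapse probability, and a detection
#' threshold for single-pulse intensity (mA).
#'
#' @slot t50 numeric(1), discrimination threshold in ms; > 0.
#' @slot scale numeric(1), logistic scale in ms; > 0.
#' @slot lapse numeric(1), lapse probability in `[0, 0.5)`; the default 0
#'   reproduces the plain two-parameter logistic.
#' @slot detThreshold numeric(1), detection threshold in mA; > 0.
#' @slot id character(1) label.
#' @exportClass Observer
setClass("Observer",
  representation(t50 = "numeric", scale = "numeric", lapse = "numeric",
                 detThreshold = "numeric", id = "character"),
  prototype(lapse = 0, detThreshold = 2.4, id = "obs"))

setValidity("Observer", function(object) {
  msg <- character()
  if (length(object@t50) != 1L || !is.finite(object@t50) || object@t50 <= 0)
    msg <- c(msg, "t50 must be a single positive finite number (ms)")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive finite number (ms)")
  if (length(object@lapse) != 1L || !is.finite(object@lapse) ||
      object@lapse < 0 || object@lapse >= 0.5)
    msg <- c(msg, "lapse must lie in [0, 0.5)")
  if (length(object@detThreshold) != 1L || !is.finite(object@detThreshold) ||
      object@detThreshold <= 0)
    msg <- c(msg, "detThreshold must be a single positive finite number (mA)")
  if (length(msg)) msg else TRUE
})

#' Construct an observer
#'
#' @param t50 discrimination threshold (STDT), ms.
#' @param scale logistic scale, ms.
#' @param lapse lapse probability, default 0.
#' @param detThreshold single-pulse detection threshold, mA.
#' @param id label.
#' @return an [Observer-class] object.
#' @examples
#' obs <- Observer(t50 = 40.51, scale = 8.28)
#' psychometricP(40.51, obs)   # 0.5 at threshold
#' @export
Observer <- function(t50, scale, lapse = 0, detThreshold = 2.4, id = "obs") {
  new("Observer", t50 = as.numeric(t50), scale = as.numeric(scale),
      lapse = as.numeric(lapse), detThreshold = as.numeric(detThreshold),
      id = as.character(id))
}

setMethod("show", "Observer", function(object) {
  cat("Observer <", object@id, ">\n", sep = "")
  cat(sprintf("  t50 (STDT): %.2f ms   scale: %.2f ms   slope@t50: %.4f /ms\n",
              object@t50, object@scale, psychometricSlope(object)))
  cat(sprintf("  lapse: %.3f   detection threshold: %.3f mA\n",
              object@lapse, object@detThreshold))
})

#' Fitted two-parameter logistic psychometric function
#'
#' Holds the maximum-likelihood threshold and scale together with the
#' derived 1%/50%/99% discrimination thresholds and the post-fit mean
#' squared error of observed vs fitted per-ISI proportions. The identity
#' `t99 - t50 == t50 - t01 == scale * log(99)` is structural.
#'
#' @slot t50,scale numeric(1), fitted parameters (ms).
#' @slot t01,t99 numeric(1), derived thresholds (ms); `t01` may be negative.
#' @slot mse numeric(1), mean squared error of per-ISI proportions.
#' @slot nTrials integer(1), number of trials behind the fit.
#' @slot identifiable logical(1), FALSE when the responses carried no
#'   information (all identical).
#' @exportClass PsychometricFit
setClass("PsychometricFit",
  representation(t50 = "numeric", scale = "numeric", t01 = "numeric",
                 t99 = "numeric", mse = "numeric", nTrials = "integer",
                 identifiable = "logical"))

setValidity("PsychometricFit", function(object) {
  msg <- character()
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (abs((object@t50 - object@t01) - object@scale * log(99)) > 1e-6)
    msg <- c(msg, "t01 must equal t50 - scale*log(99)")
  if (abs((object@t99 - object@t50) - object@scale * log(99)) > 1e-6)
    msg <- c(msg, "t99 must equal t50 + scale*log(99)")
  if (object@mse < 0) msg <- c(msg, "mse must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname PsychometricFit-class
#' @param t50,scale fitted logistic parameters (ms).
#' @param mse post-fit mean squared error.
#' @param nTrials trial count.
#' @param identifiable logical flag.
#' @export
PsychometricFit <- function(t50, scale, mse = 0, nTrials = 0L,
                            identifiable = TRUE) {
  new("PsychometricFit", t50 = as.numeric(t50), scale = as.numeric(scale),
      t01 = t50 - scale * log(99), t99 = t50 + scale * log(99),
      mse = as.numeric(mse), nTrials = as.integer(nTrials),
      identifiable = identifiable)
}

setMethod("show", "PsychometricFit", function(object) {
  cat("PsychometricFit\n")
  cat(sprintf("  T01 %.2f | T50 %.2f | T99 %.2f ms  (scale %.2f ms)\n",
              object@t01, object@t50, object@t99, object@scale))
  cat(sprintf("  mse %.5f over %d trials%s\n", object@mse, object@nTrials,
              if (object@identifiable) "" else "  [NON-IDENTIFIABLE]"))
})

#' Individually calibrated 10-level ISI design
#'
#' Ten strictly increasing, equally spaced interstimulus intervals whose
#' midpoint is the observer's fitted discrimination threshold, together
#' with the per-run trial allocation (unimodal, symmetric, 200 trials).
#'
#' @slot levels numeric(10), ISI values in ms.
#' @slot countsPerRun integer(10), trials per level per run; sums to
#'   `runTrials`.
#' @slot runTrials integer(1), trials per run (200).
#' @exportClass ISIDesign
setClass("ISIDesign",
  representation(levels = "numeric", countsPerRun = "integer",
                 runTrials = "integer"))

setValidity("ISIDesign", function(object) {
  msg <- character()
  lv <- object@levels
  if (length(lv) != 10L) msg <- c(msg, "levels must have length 10")
  if (any(diff(lv) <= 0)) msg <- c(msg, "levels must be strictly increasing")
  if (length(lv) == 10L &&
      max(abs(diff(lv) - (lv[10] - lv[1]) / 9)) > 1e-8 * max(1, abs(lv[10])))
    msg <- c(msg, "levels must be equally spaced")
  if (lv[1] < 1 - 1e-9) msg <- c(msg, "minimum ISI level must be >= 1 ms")
  ct <- object@countsPerRun
  if (length(ct) != 10L) msg <- c(msg, "countsPerRun must have length 10")
  if (any(ct < 0L)) msg <- c(msg, "counts must be non-negative")
  if (sum(ct) != object@runTrials)
    msg <- c(msg, "counts must sum to runTrials")
  if (!identical(as.integer(ct), as.integer(rev(ct))))
    msg <- c(msg, "counts must be symmetric")
  if (any(diff(ct[1:5]) < 0L))
    msg <- c(msg, "counts must be unimodal (non-decreasing to the centre)")
  if (length(msg)) msg else TRUE
})

#' @rdname ISIDesign-class
#' @param levels 10 equally spaced ISI values (ms).
#' @param countsPerRun 10 trial counts summing to `runTrials`.
#' @param runTrials trials per run.
#' @export
ISIDesign <- function(levels, countsPerRun, runTrials = 200L) {
  new("ISIDesign", levels = as.numeric(levels),
      countsPerRun = as.integer(countsPerRun),
      runTrials = as.integer(runTrials))
}

setMethod("show", "ISIDesign", function(object) {
  cat("ISIDesign: 10 levels,", object@runTrials, "trials/run\n")
  print(data.frame(level = 1:10, isi_ms = round(object@levels, 2),
                   trials = object@countsPerRun), row.names = FALSE)
})

#' Electrode layout
#'
#' Channel names and 2-D scalp positions (azimuthal projection into the
#' unit disk). EOG channels are carried along but flagged so that scalp
#' operations (average reference, interpolation) can exclude them.
#'
#' @slot names character vector of channel labels (unique).
#' @slot pos2d numeric matrix, one row per channel, columns x (right) and
#'   y (anterior), unit-disk coordinates.
#' @slot type character vector, "eeg" or "eog" per channel.
#' @exportClass ChannelLayout
setClass("ChannelLayout",
  representation(names = "character", pos2d = "matrix", type = "character"))

setValidity("ChannelLayout", function(object) {
  msg <- character()
  if (anyDuplicated(object@names)) msg <- c(msg, "channel names must be unique")
  if (nrow(object@pos2d) != length(object@names) || ncol(object@pos2d) != 2L)
    msg <- c(msg, "pos2d must be an n x 2 matrix matching names")
  if (length(object@type) != length(object@names) ||
      !all(object@type %in% c("eeg", "eog")))
    msg <- c(msg, "type must be 'eeg' or 'eog' per channel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChannelLayout", function(object) {
  cat("ChannelLayout:", sum(object@type == "eeg"), "scalp +",
      sum(object@type == "eog"), "EOG channels\n")
})

#' @rdname ChannelLayout-class
#' @param object,layout a `ChannelLayout`.
#' @export
channelNames <- function(layout) layout@names

#' @rdname ChannelLayout-class
#' @export
scalpChannels <- function(layout) layout@names[layout@type == "eeg"]

#' @rdname ChannelLayout-class
#' @export
channelPositions <- function(layout) {
  structure(layout@pos2d, dimnames = list(layout@names, c("x", "y")))
}

#' Epoched EEG data
#'
#' A channels x samples x trials array at a stated sampling rate, with the
#' layout and per-trial metadata attached.
#'
#' @slot data numeric array, channels x samples x trials, in microvolts.
#' @slot sfreq sampling rate, Hz.
#' @slot times numeric vector of sample times in seconds relative to
#'   stimulus onset (length = dim(data)[2]).
#' @slot layout a [ChannelLayout-class].
#' @slot trialMeta data.frame with one row per trial.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", sfreq = "numeric", times = "numeric",
                 layout = "ChannelLayout", trialMeta = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (length(d) == 3L) {
    if (d[1] != length(object@layout@names))
      msg <- c(msg, "first dimension must match the layout")
    if (d[2] != length(object@times))
      msg <- c(msg, "second dimension must match times")
    if (nrow(object@trialMeta) > 0 && d[3] != nrow(object@trialMeta))
      msg <- c(msg, "third dimension must match trialMeta rows")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname EpochSet-class
#' @param data channels x samples x trials array (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param times sample times in seconds.
#' @param layout a [ChannelLayout-class].
#' @param trialMeta per-trial data.frame.
#' @export
EpochSet <- function(data, sfreq, times, layout, trialMeta = data.frame()) {
  dimnames(data) <- list(layout@names, NULL, NULL)
  new("EpochSet", data = data, sfreq = sfreq, times = times, layout = layout,
      trialMeta = trialMeta)
}

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  window %.0f..%.0f ms\n", 1000 * min(object@times),
              1000 * max(object@times)))
})

#' @rdname EpochSet-class
#' @param epochs an `EpochSet`.
#' @export
epochData <- function(epochs) epochs@data

#' @rdname EpochSet-class
#' @export
epochTimes <- function(epochs) epochs@times

#' @rdname EpochSet-class
#' @export
samplingRate <- function(epochs) epochs@sfreq

#' @rdname EpochSet-class
#' @export
trialMeta <- function(epochs) epochs@trialMeta

#' Scalp-space volumes
#'
#' Per-trial (or per-subject) spatiotemporal images: channel data linearly
#' interpolated onto a 32 x 32 grid covering the unit-disk scalp
#' projection, for each time sample. Grid cells outside the electrode
#' convex hull are masked. Internally the data are stored flattened as a
#' (maskedCells * nTimes) x nVolumes matrix; helpers map between flat
#' voxel indices and (x, y, time).
#'
#' @slot gridX,gridY numeric(32), grid coordinates.
#' @slot mask logical(1024), TRUE for in-hull cells (column-major over the
#'   32 x 32 grid).
#' @slot times numeric, sample times in seconds.
#' @slot data numeric matrix, (sum(mask) * length(times)) x nVolumes:
#'   masked voxels, time-major blocks (all cells of sample 1, then 2, ...).
#' @slot meta data.frame, one row per volume.
#' @exportClass ScalpVolumes
setClass("ScalpVolumes",
  representation(gridX = "numeric", gridY = "numeric", mask = "logical",
                 times = "numeric", data = "matrix", meta = "data.frame"))

setValidity("ScalpVolumes", function(object) {
  msg <- character()
  if (length(object@mask) != length(object@gridX) * length(object@gridY))
    msg <- c(msg, "mask length must equal grid size")
  if (nrow(object@data) != sum(object@mask) * length(object@times))
    msg <- c(msg, "data rows must equal sum(mask) * length(times)")
  if (nrow(object@meta) > 0 && ncol(object@data) != nrow(object@meta))
    msg <- c(msg, "data columns must match meta rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScalpVolumes", function(object) {
  cat(sprintf("ScalpVolumes: %d x %d grid (%d in mask) x %d samples, %d volume(s)\n",
              length(object@gridX), length(object@gridY), sum(object@mask),
              length(object@times), ncol(object@data)))
})

#' @rdname ScalpVolumes-class
#' @param volumes a `ScalpVolumes`.
#' @export
volumeMask <- function(volumes) volumes@mask

#' @rdname ScalpVolumes-class
#' @export
volumeData <- function(volumes) volumes@data

#' @rdname ScalpVolumes-class
#' @export
volumeTimes <- function(volumes) volumes@times
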