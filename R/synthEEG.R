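#' ERP component specification
#'
#' A somatosensory evoked component modelled as a separable Gaussian
#' spatial profile around a peak electrode times a Gaussian temporal
#' profile around a peak latency, with percept-conditional amplitudes.
#'
#' @param name label.
#' @param peakMs peak latency, ms.
#' @param peakChannel peak electrode label.
#' @param ampOne,ampTwo amplitude (microvolts) when the double pulse is
#'   felt as one / as two.
#' @param temporalSigma temporal width, ms.
#' @param spatialSigma spatial width in layout (unit-disk) distance.
#' @return list of class `"ErpComponent"`.
#' @export
erpComponent <- function(name, peakMs, peakChannel, ampOne, ampTwo = ampOne,
                         temporalSigma = 20, spatialSigma = 0.25) {
  if (temporalSigma <= 0 || spatialSigma <= 0)
    stop("component widths must be positive")
  structure(list(name = name, peakMs = peakMs, peakChannel = peakChannel,
                 ampOne = ampOne, ampTwo = ampTwo,
                 temporalSigma = temporalSigma, spatialSigma = spatialSigma),
            class = "ErpComponent")
}

#' Default somatosensory component set
#'
#' Four components reproducing the qualitative evoked-response layout of
#' a median-nerve double-pulse paradigm: P50 (50 ms, CP4, positive),
#' N140 (peaking early at 120 ms, C6, negative), P170 (170 ms, FC2,
#' positive) and P300 (300 ms, CPz, positive). Only the P170 is
#' modulated by the percept: its "felt as two" amplitude exceeds the
#' "felt as one" amplitude by `delta` microvolts, so the injected
#' condition difference is a single fronto-central component whose
#' maximum lies inside the 129-178 ms window of interest. `delta = 0`
#' makes the two percept conditions identically distributed.
#'
#' @param delta P170 percept modulation, microvolts (default 2).
#' @return list of [erpComponent()] specs.
#' @export
defaultComponents <- function(delta = 2) {
  list(
    erpComponent("P50", 50, "CP4", ampOne = 2.5, temporalSigma = 10,
                 spatialSigma = 0.22),
    erpComponent("N140", 120, "C6", ampOne = -3, temporalSigma = 18,
                 spatialSigma = 0.25),
    erpComponent("P170", 170, "FC2", ampOne = 3, ampTwo = 3 + delta,
                 temporalSigma = 20, spatialSigma = 0.25),
    erpComponent("P300", 300, "CPz", ampOne = 5, temporalSigma = 60,
                 spatialSigma = 0.35))
}

#' Spatiotemporal field of a component
#'
#' Channels x samples pattern of one component at unit condition:
#' `amp * exp(-d^2 / (2 sSigma^2)) * exp(-(t - peak)^2 / (2 tSigma^2))`
#' where `d` is the 2-D layout distance to the peak electrode. EOG
#' channels receive no evoked signal.
#'
#' @param spec an [erpComponent()].
#' @param layout a [ChannelLayout-class].
#' @param timesMs sample times, ms.
#' @param amp amplitude to use (defaults to `spec$ampOne`).
#' @return matrix channels x samples.
#' @export
componentField <- function(spec, layout, timesMs, amp = spec$ampOne) {
  pos <- layout@pos2d
  idx <- match(spec$peakChannel, layout@names)
  if (is.na(idx)) stop("unknown peak channel: ", spec$peakChannel)
  d2 <- (pos[, 1] - pos[idx, 1])^2 + (pos[, 2] - pos[idx, 2])^2
  sp <- exp(-d2 / (2 * spec$spatialSigma^2))
  sp[layout@type != "eeg"] <- 0
  tp <- exp(-(timesMs - spec$peakMs)^2 / (2 * spec$temporalSigma^2))
  amp * outer(sp, tp)
}

# sum of component fields for a given percept
perceptField <- function(components, layout, timesMs, percept) {
  Reduce(`+`, lapply(components, function(cp)
    componentField(cp, layout, timesMs,
                   amp = if (percept == "two") cp$ampTwo else cp$ampOne)))
}

#' Ground-truth percept-difference field
#'
#' The injected "felt as two" minus "felt as one" field (channels x
#' samples), i.e. the sum over components of their amplitude
#' differences.
#'
#' @inheritParams componentField
#' @param components component list.
#' @export
differenceField <- function(components, layout, timesMs) {
  perceptField(components, layout, timesMs, "two") -
    perceptField(components, layout, timesMs, "one")
}

#' Generate spatially correlated 1/f noise
#'
#' Channels x samples noise whose per-channel power spectrum follows
#' `1/f^exponent` with an optional 10 Hz alpha bump, spatially mixed so
#' neighbouring channels are correlated. Spectral shaping is applied in
#' the frequency domain to white Gaussian noise; each channel is then
#' rescaled to standard deviation `sd` before mixing (mixing rows have
#' unit norm, preserving the marginal scale for uncorrelated inputs).
#'
#' @param nchan,nsamp dimensions.
#' @param sfreq sampling rate, Hz.
#' @param exponent spectral exponent (>= 0; 0 gives white noise).
#' @param alphaPower relative alpha-bump amplitude (0 disables).
#' @param alphaFreq,alphaWidth alpha bump centre and width, Hz.
#' @param sd per-channel noise standard deviation (microvolts).
#' @param spatialMix nchan x nchan mixing matrix, `NULL` for identity,
#'   or `"auto"` with a `layout` to build a Gaussian-falloff mixer.
#' @param layout optional [ChannelLayout-class] for `spatialMix = "auto"`.
#' @return matrix nchan x nsamp.
#' @export
generateNoise <- function(nchan, nsamp, sfreq, exponent = 1,
                          alphaPower = 1, alphaFreq = 10, alphaWidth = 2,
                          sd = 1, spatialMix = NULL, layout = NULL) {
  if (exponent < 0) stop("exponent must be >= 0")
  z <- matrix(rnorm(nsamp * nchan), nsamp, nchan)
  if (exponent > 0 || alphaPower > 0) {
    f <- seq(0, sfreq - sfreq / nsamp, length.out = nsamp)
    f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]   # mirror negative freqs
    shape <- rep(1, nsamp)
    pos <- f > 0
    if (exponent > 0)
      shape[pos] <- pmax(f[pos], 0.5)^(-exponent / 2)
    if (alphaPower > 0)
      shape <- shape + alphaPower *
        exp(-(f - alphaFreq)^2 / (2 * alphaWidth^2)) * mean(shape[pos])
    shape[1] <- 0   # no DC
    zf <- mvfft(z) * shape
    z <- Re(mvfft(zf, inverse = TRUE)) / nsamp
  }
  z <- sweep(z, 2, apply(z, 2, stats::sd), "/") * sd
  x <- t(z)
  if (identical(spatialMix, "auto")) {
    if (is.null(layout)) stop("layout needed for spatialMix = 'auto'")
    spatialMix <- spatialMixer(layout, nchan)
  }
  if (!is.null(spatialMix)) x <- spatialMix %*% x
  x
}

# Gaussian-falloff spatial mixing matrix with unit-norm rows
spatialMixer <- function(layout, nchan, width = 0.35) {
  pos <- layout@pos2d[seq_len(nchan), , drop = FALSE]
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  m <- exp(-d2 / (2 * width^2))
  m / sqrt(rowSums(m^2))
}

#' Epoch sample indices and times for a window
#'
#' Integer sample indices n with `tmin * sfreq <= n <= tmax * sfreq`
#' relative to the event sample; at 512 Hz and the -100..600 ms window
#' this is -51..307, i.e. 359 samples.
#'
#' @param sfreq sampling rate, Hz.
#' @param tmin,tmax window edges, seconds.
#' @return list with `idx` (integer offsets) and `times` (seconds).
#' @export
epochWindow <- function(sfreq, tmin = -0.1, tmax = 0.6) {
  idx <- seq.int(ceiling(tmin * sfreq), floor(tmax * sfreq))
  list(idx = idx, times = idx / sfreq)
}

#' Simulate epoched EEG for one subject
#'
#' Builds channels x samples x trials data at `sfreq` (default 512 Hz,
#' -100..600 ms window): for each trial, the sum of the component
#' fields with amplitudes chosen by that trial's percept, plus fresh
#' spatially correlated 1/f noise. The ground-truth difference field is
#' attached as attribute `"deltaField"` of the returned object's data.
#'
#' @param trials data.frame with a `percept` column ("one"/"two").
#' @param components component list from [defaultComponents()].
#' @param layout a [ChannelLayout-class].
#' @param sfreq sampling rate, Hz.
#' @param window epoch window, seconds.
#' @param noiseSd per-channel per-trial noise SD, microvolts (0 for
#'   noiseless epochs).
#' @param exponent,alphaPower noise spectrum parameters.
#' @param spatialMix `"auto"` (default), `NULL`, or a matrix.
#' @return an [EpochSet-class].
#' @export
simulateSubjectEpochs <- function(trials, components = defaultComponents(),
                                  layout = standardLayout64(), sfreq = 512,
                                  window = c(-0.1, 0.6), noiseSd = 8,
                                  exponent = 1, alphaPower = 1,
                                  spatialMix = "auto") {
  if (is.null(trials$percept)) stop("trials must carry a percept column")
  win <- epochWindow(sfreq, window[1], window[2])
  timesMs <- win$times * 1000
  nchan <- length(layout@names); nsamp <- length(win$idx)
  ntr <- nrow(trials)
  fieldOne <- perceptField(components, layout, timesMs, "one")
  fieldTwo <- perceptField(components, layout, timesMs, "two")
  mix <- if (identical(spatialMix, "auto")) spatialMixer(layout, nchan)
         else spatialMix
  dat <- array(0, dim = c(nchan, nsamp, ntr))
  for (i in seq_len(ntr)) {
    sig <- if (trials$percept[i] == "two") fieldTwo else fieldOne
    if (noiseSd > 0) {
      sig <- sig + generateNoise(nchan, nsamp, sfreq, exponent = exponent,
                                 alphaPower = alphaPower, sd = noiseSd,
                                 spatialMix = mix)
    }
    dat[, , i] <- sig
  }
  attr(dat, "deltaField") <- fieldTwo - fieldOne
  EpochSet(dat, sfreq = sfreq, times = win$times, layout = layout,
           trialMeta = trials)
}

#' Fast draw of a subject-level percept contrast
#'
#' Channels x samples contrast ("felt as two" mean minus "felt as one"
#' mean) drawn directly in its sampling distribution: the ground-truth
#' difference field scaled by a per-subject amplitude factor, plus the
#' difference of two averaged-noise terms with SD `noiseSd / sqrt(m)`
#' each. Because trial noise is Gaussian and averaging is linear, this
#' is distributionally identical to simulating `m` epochs per condition
#' and averaging, at a fraction of the cost; group-level simulations
#' (family-wise error calibration, power) use this path.
#'
#' @param nPerCond trials per condition `m` (default 90).
#' @param subjectScale multiplicative amplitude factor for this subject
#'   (draw from `rnorm(1, 1, 0.2)` for between-subject variability).
#' @inheritParams simulateSubjectEpochs
#' @return matrix channels x samples, with attribute `"deltaField"`.
#' @export
simulateSubjectContrast <- function(nPerCond = 90, subjectScale = 1,
                                    components = defaultComponents(),
                                    layout = standardLayout64(), sfreq = 512,
                                    window = c(-0.1, 0.6), noiseSd = 8,
                                    exponent = 1, alphaPower = 1) {
  win <- epochWindow(sfreq, window[1], window[2])
  timesMs <- win$times * 1000
  nchan <- length(layout@names); nsamp <- length(win$idx)
  mix <- spatialMixer(layout, nchan)
  delta <- differenceField(components, layout, timesMs)
  avgSd <- noiseSd / sqrt(nPerCond)
  ctr <- subjectScale * delta +
    generateNoise(nchan, nsamp, sfreq, exponent = exponent,
                  alphaPower = alphaPower, sd = avgSd, spatialMix = mix) -
    generateNoise(nchan, nsamp, sfreq, exponent = exponent,
                  alphaPower = alphaPower, sd = avgSd, spatialMix = mix)
  attr(ctr, "deltaField") <- delta
  ctr
}

#' Stereotyped blink template
#'
#' @param sfreq sampling rate, Hz.
#' @param durS blink duration, seconds.
#' @return numeric vector (peak-normalized Hann-squared bump).
#' @export
blinkTemplate <- function(sfreq, durS = 0.3) {
  n <- round(durS * sfreq)
  sin(seq(0, pi, length.out = n))^2
}

#' Inject eye blinks into continuous data
#'
#' Adds stereotyped blink time-courses to the vEOG channel and, scaled
#' by a frontal-weighted topography, to the scalp channels. Blink onsets
#' are Poisson with the requested rate. The blink-free input is left to
#' the caller for ground-truth comparisons.
#'
#' @param data channels x samples matrix (must contain a `vEOG` row per
#'   the layout).
#' @param layout a [ChannelLayout-class].
#' @param sfreq sampling rate, Hz.
#' @param ratePerMin mean blinks per minute (default 12; 0 returns the
#'   input unchanged).
#' @param amplitude vEOG blink peak amplitude, microvolts.
#' @param scalpGain maximum scalp projection relative to vEOG (frontal
#'   channels; decays with distance from the vEOG position).
#' @return list with `data` (contaminated), `onsets` (sample indices)
#'   and `topography` (per-channel gain).
#' @export
injectBlinks <- function(data, layout, sfreq, ratePerMin = 12,
                         amplitude = 200, scalpGain = 0.35) {
  veog <- match("vEOG", layout@names)
  if (is.na(veog)) stop("layout must contain a vEOG channel")
  nsamp <- ncol(data)
  tmpl <- blinkTemplate(sfreq)
  nb <- rbinom(1, nsamp, min(1, ratePerMin / 60 / sfreq))
  if (ratePerMin <= 0 || nb == 0)
    return(list(data = data, onsets = integer(0),
                topography = numeric(nrow(data))))
  onsets <- sort(sample.int(nsamp - length(tmpl), nb))
  pos <- layout@pos2d
  d2 <- (pos[, 1] - pos[veog, 1])^2 + (pos[, 2] - pos[veog, 2])^2
  topo <- scalpGain * exp(-d2 / (2 * 0.45^2))
  topo[layout@type != "eeg"] <- 0
  topo[veog] <- 1
  for (o in onsets) {
    seg <- o:(o + length(tmpl) - 1)
    data[, seg] <- data[, seg] + amplitude * outer(topo, tmpl)
  }
  list(data = data, onsets = onsets, topography = topo)
}

#' Simulate a continuous recording
#'
#' Continuous channels x samples data at `sfreq` (default 2048 Hz):
#' background 1/f noise plus the percept-conditional component fields
#' placed at event onsets, optionally contaminated with blinks. Used to
#' exercise the full preprocessing chain; epoched-mode simulation is
#' the fast default elsewhere.
#'
#' @param trials data.frame with `percept`; onsets are laid out
#'   `gapS` seconds apart.
#' @param components,layout,noiseSd,exponent,alphaPower as in
#'   [simulateSubjectEpochs()].
#' @param sfreq sampling rate, Hz.
#' @param gapS event spacing, seconds.
#' @param blinkRatePerMin blink contamination rate (0 = clean).
#' @return list: `data`, `sfreq`, `layout`, `events` (data.frame with
#'   `sample`, `percept`), `onsetsBlink`, `clean` (pre-blink data).
#' @export
simulateContinuous <- function(trials, components = defaultComponents(),
                               layout = standardLayout64(), sfreq = 2048,
                               gapS = 1.5, noiseSd = 8, exponent = 1,
                               alphaPower = 1, blinkRatePerMin = 0) {
  ntr <- nrow(trials)
  nchan <- length(layout@names)
  nsamp <- round((ntr + 1) * gapS * sfreq)
  mix <- spatialMixer(layout, nchan)
  x <- generateNoise(nchan, nsamp, sfreq, exponent = exponent,
                     alphaPower = alphaPower, sd = noiseSd, spatialMix = mix)
  win <- epochWindow(sfreq, -0.1, 0.6)
  timesMs <- win$times * 1000
  fieldOne <- perceptField(components, layout, timesMs, "one")
  fieldTwo <- perceptField(components, layout, timesMs, "two")
  onsets <- round((seq_len(ntr)) * gapS * sfreq)
  for (i in seq_len(ntr)) {
    seg <- onsets[i] + win$idx
    x[, seg] <- x[, seg] +
      (if (trials$percept[i] == "two") fieldTwo else fieldOne)
  }
  clean <- x
  ob <- integer(0)
  if (blinkRatePerMin > 0) {
    bl <- injectBlinks(x, layout, sfreq, ratePerMin = blinkRatePerMin)
    x <- bl$data; ob <- bl$onsets
  }
  list(data = x, sfreq = sfreq, layout = layout,
       events = data.frame(sample = onsets, percept = trials$percept),
       onsetsBlink = ob, clean = clean)
}
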