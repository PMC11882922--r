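#' Preprocessing configuration
#'
#' Defaults reproduce a conventional evoked-potential chain: 0.01 Hz
#' high-pass, 48-52 Hz notch, downsampling to 512 Hz, common-average
#' reference, blink removal, epoching -100..600 ms, artifact rejection
#' by a deterministic peak-to-peak criterion, 40 Hz low-pass on the
#' epochs, and baseline correction over -100..0 ms.
#'
#' @param hpHz high-pass cutoff, Hz.
#' @param notchHz band-stop edges, Hz.
#' @param lpHz low-pass cutoff, Hz.
#' @param targetSfreq sampling rate after downsampling, Hz.
#' @param epochWindowS epoch window, seconds.
#' @param baselineWindowS baseline window, seconds.
#' @param badTrialPtpUv peak-to-peak artifact threshold, microvolts.
#' @param badChannelFrac bad-trial fraction above which a channel is
#'   interpolated.
#' @param blinkThresholdUv vEOG blink-detection threshold, microvolts.
#' @export
preprocConfig <- function(hpHz = 0.01, notchHz = c(48, 52), lpHz = 40,
                          targetSfreq = 512, epochWindowS = c(-0.1, 0.6),
                          baselineWindowS = c(-0.1, 0),
                          badTrialPtpUv = 150, badChannelFrac = 0.20,
                          blinkThresholdUv = 80) {
  if (hpHz >= lpHz) stop("high-pass cutoff must lie below low-pass cutoff")
  if (baselineWindowS[1] < epochWindowS[1] ||
      baselineWindowS[2] > epochWindowS[2])
    stop("baseline window must lie inside the epoch window")
  structure(list(hpHz = hpHz, notchHz = notchHz, lpHz = lpHz,
                 targetSfreq = targetSfreq, epochWindowS = epochWindowS,
                 baselineWindowS = baselineWindowS,
                 badTrialPtpUv = badTrialPtpUv,
                 badChannelFrac = badChannelFrac,
                 blinkThresholdUv = blinkThresholdUv),
            class = "PreprocConfig")
}

# zero-phase Butterworth helper operating row-wise on channels x samples
applyFiltfilt <- function(x, filt) {
  t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
}

#' High-pass and notch filtering of continuous data
#'
#' Zero-phase Butterworth filtering (forward-backward): first-order
#' high-pass at `hpHz` (effective order 2 after the two passes) and
#' order-2 band-stop over `notchHz` (effective order 4). The low-pass
#' stage belongs later in the chain (applied to epochs); see
#' [lowpassEpochs()].
#'
#' @param x channels x samples matrix.
#' @param sfreq sampling rate, Hz.
#' @param cfg a [preprocConfig()].
#' @return filtered matrix.
#' @export
filterChain <- function(x, sfreq, cfg = preprocConfig()) {
  if (sfreq <= 2 * cfg$lpHz) stop("sampling rate too low for the chain")
  if (ncol(x) < 3 * sfreq / max(cfg$hpHz * sfreq, 1))
    stop("segment too short for stable filtering")
  hp <- signal::butter(1, cfg$hpHz / (sfreq / 2), type = "high")
  x <- applyFiltfilt(x, hp)
  bs <- signal::butter(2, cfg$notchHz / (sfreq / 2), type = "stop")
  applyFiltfilt(x, bs)
}

#' Downsample by an integer factor
#'
#' Anti-alias low-pass (order-6 Butterworth at 40% of the target
#' Nyquist, zero phase) followed by decimation. Event sample indices
#' are remapped by the same factor.
#'
#' @param x channels x samples matrix.
#' @param sfreq current sampling rate, Hz.
#' @param targetSfreq target rate; `sfreq / targetSfreq` must be an
#'   integer.
#' @param events optional integer event samples to remap.
#' @return list `data`, `sfreq`, `events`.
#' @export
downsampleRecording <- function(x, sfreq, targetSfreq = 512, events = NULL) {
  fac <- sfreq / targetSfreq
  if (abs(fac - round(fac)) > 1e-9) stop("non-integer decimation factor")
  fac <- as.integer(round(fac))
  if (fac > 1L) {
    aa <- signal::butter(6, 0.8 * (targetSfreq / 2) / (sfreq / 2),
                         type = "low")
    x <- applyFiltfilt(x, aa)
    x <- x[, seq(1, ncol(x), by = fac), drop = FALSE]
  }
  list(data = x, sfreq = targetSfreq,
       events = if (is.null(events)) NULL else as.integer(round(events / fac)))
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over scalp channels (EOG
#' excluded from the average but re-expressed against it). Idempotent;
#' channel differences are untouched.
#'
#' @param x channels x samples matrix.
#' @param layout a [ChannelLayout-class] (identifies scalp channels).
#' @return re-referenced matrix.
#' @export
rereferenceAverage <- function(x, layout) {
  scalp <- which(layout@type == "eeg")
  if (length(scalp) < 2) stop("need >= 2 scalp channels")
  avg <- colMeans(x[scalp, , drop = FALSE])
  sweep(x, 2, avg)
}

#' Remove blink activity by template projection
#'
#' Detects blinks on the vEOG by threshold crossing with a refractory
#' period, averages the scalp pattern at the blink peaks into a blink
#' topography, and removes that rank-1 spatial component from the scalp
#' data (orthogonalization). With fewer than `minBlinks` detections the
#' data pass through unchanged with a warning.
#'
#' @param x channels x samples matrix.
#' @param layout a [ChannelLayout-class] containing `vEOG`.
#' @param cfg a [preprocConfig()] (threshold).
#' @param refractoryS minimum spacing between detected blinks, seconds.
#' @param sfreq sampling rate, Hz.
#' @param minBlinks minimum number of blinks for a stable template.
#' @return list `data` (cleaned), `topography`, `peaks` (samples).
#' @export
removeBlinks <- function(x, layout, sfreq, cfg = preprocConfig(),
                         refractoryS = 0.5, minBlinks = 3L) {
  veog <- match("vEOG", layout@names)
  if (is.na(veog)) stop("layout must contain vEOG")
  v <- x[veog, ]
  above <- which(v > cfg$blinkThresholdUv)
  peaks <- integer(0)
  lastPeak <- -Inf
  refr <- round(refractoryS * sfreq)
  i <- 1L
  while (i <= length(above)) {
    s <- above[i]
    if (s - lastPeak > refr) {
      # local maximum within the refractory span
      seg <- s:min(length(v), s + refr)
      pk <- seg[which.max(v[seg])]
      peaks <- c(peaks, pk)
      lastPeak <- pk
    }
    i <- i + 1L
  }
  if (length(peaks) < minBlinks) {
    warning("fewer than ", minBlinks, " blinks detected; data unchanged")
    return(list(data = x, topography = NULL, peaks = peaks))
  }
  scalp <- which(layout@type == "eeg")
  topo <- rowMeans(x[scalp, peaks, drop = FALSE])
  topo <- topo / sqrt(sum(topo^2))
  xs <- x[scalp, , drop = FALSE]
  x[scalp, ] <- xs - topo %*% (t(topo) %*% xs)
  list(data = x, topography = topo, peaks = peaks)
}

#' Epoch continuous data around events
#'
#' Cuts channels x samples x trials epochs over the configured window.
#' Events whose window would leave the recording are dropped (reported
#' via attribute `"dropped"` on the trial metadata).
#'
#' @param x channels x samples matrix.
#' @param sfreq sampling rate, Hz.
#' @param eventSamples integer vector of event (first-pulse) samples.
#' @param layout a [ChannelLayout-class].
#' @param window epoch window, seconds.
#' @param trialMeta optional per-event metadata to carry along.
#' @return an [EpochSet-class].
#' @export
epochRecording <- function(x, sfreq, eventSamples, layout,
                           window = c(-0.1, 0.6), trialMeta = NULL) {
  win <- epochWindow(sfreq, window[1], window[2])
  ok <- eventSamples + min(win$idx) >= 1 &
        eventSamples + max(win$idx) <= ncol(x)
  dropped <- which(!ok)
  keep <- which(ok)
  dat <- array(0, dim = c(nrow(x), length(win$idx), length(keep)))
  for (j in seq_along(keep))
    dat[, , j] <- x[, eventSamples[keep[j]] + win$idx]
  meta <- if (is.null(trialMeta)) {
    data.frame(event_sample = eventSamples[keep])
  } else {
    cbind(trialMeta[keep, , drop = FALSE],
          event_sample = eventSamples[keep])
  }
  attr(meta, "dropped") <- dropped
  EpochSet(dat, sfreq = sfreq, times = win$times, layout = layout,
           trialMeta = meta)
}

#' Artifact rejection with bad-channel interpolation
#'
#' A channel is flagged bad on a trial when its peak-to-peak amplitude
#' exceeds the configured threshold. Channels bad on more than
#' `badChannelFrac` of trials (within the scoped run, when a `run`
#' column is present in the trial metadata) are interpolated on all
#' trials of that scope by inverse-distance weighting of up to 6
#' nearest scalp neighbours. Trials still containing a bad channel
#' afterwards are removed.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [preprocConfig()].
#' @return list `epochs` (cleaned), `keptMask`, `interpolated`
#'   (data.frame channel/run), `badFraction` (channel x run matrix).
#' @export
rejectArtifacts <- function(epochs, cfg = preprocConfig()) {
  dat <- epochs@data
  layout <- epochs@layout
  nchan <- dim(dat)[1]; ntr <- dim(dat)[3]
  scalp <- which(layout@type == "eeg")
  ptp <- apply(dat, c(1, 3), function(v) max(v) - min(v))
  bad <- ptp > cfg$badTrialPtpUv          # channels x trials
  runs <- if (!is.null(epochs@trialMeta$run)) epochs@trialMeta$run
          else rep(1L, ntr)
  interpolated <- data.frame(channel = character(0), run = integer(0))
  for (r in unique(runs)) {
    tr <- which(runs == r)
    frac <- rowMeans(bad[, tr, drop = FALSE])
    badCh <- intersect(which(frac > cfg$badChannelFrac), scalp)
    if (length(badCh) > nchan / 2)
      stop("more than half of the channels are bad; aborting")
    for (ch in badCh) {
      w <- idwWeights(layout, ch, exclude = badCh)
      for (t in tr)
        dat[ch, , t] <- crossprod(w, dat[names(w), , t])
      bad[ch, tr] <- apply(dat[ch, , tr, drop = FALSE], 3,
                           function(v) max(v) - min(v)) > cfg$badTrialPtpUv
      interpolated <- rbind(interpolated,
                            data.frame(channel = layout@names[ch], run = r))
    }
  }
  keptMask <- colSums(bad[scalp, , drop = FALSE]) == 0
  meta <- epochs@trialMeta[keptMask, , drop = FALSE]
  out <- EpochSet(dat[, , keptMask, drop = FALSE], sfreq = epochs@sfreq,
                  times = epochs@times, layout = layout, trialMeta = meta)
  list(epochs = out, keptMask = keptMask, interpolated = interpolated,
       badFraction = rowMeans(bad))
}

# inverse-distance weights over <= k nearest scalp neighbours
idwWeights <- function(layout, channel, k = 6L, exclude = integer(0)) {
  pos <- layout@pos2d
  cand <- setdiff(which(layout@type == "eeg"), c(channel, exclude))
  d <- sqrt((pos[cand, 1] - pos[channel, 1])^2 +
            (pos[cand, 2] - pos[channel, 2])^2)
  ord <- order(d)[seq_len(min(k, length(cand)))]
  w <- 1 / d[ord]
  w <- w / sum(w)
  names(w) <- layout@names[cand[ord]]
  w
}

#' Low-pass filter epochs
#'
#' Zero-phase order-4 Butterworth low-pass applied per channel and
#' trial, the final filtering stage of the chain.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [preprocConfig()].
#' @return filtered [EpochSet-class].
#' @export
lowpassEpochs <- function(epochs, cfg = preprocConfig()) {
  lp <- signal::butter(4, cfg$lpHz / (epochs@sfreq / 2), type = "low")
  dat <- epochs@data
  for (t in seq_len(dim(dat)[3]))
    dat[, , t] <- applyFiltfilt(dat[, , t], lp)
  EpochSet(dat, sfreq = epochs@sfreq, times = epochs@times,
           layout = epochs@layout, trialMeta = epochs@trialMeta)
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean over the baseline window;
#' afterwards the baseline mean is exactly zero.
#'
#' @param epochs an [EpochSet-class].
#' @param window baseline window, seconds.
#' @return corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-0.1, 0)) {
  sel <- epochs@times >= window[1] & epochs@times <= window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  dat <- epochs@data
  bl <- apply(dat[, sel, , drop = FALSE], c(1, 3), mean)
  dat <- dat - aperm(array(bl, dim = c(dim(dat)[1], dim(dat)[3],
                                       dim(dat)[2])), c(1, 3, 2))
  EpochSet(dat, sfreq = epochs@sfreq, times = epochs@times,
           layout = epochs@layout, trialMeta = epochs@trialMeta)
}

#' Barycentric interpolation weights for scalp positions
#'
#' Linear (triangulation-based) interpolation weights from the scalp
#' electrodes of a layout to arbitrary 2-D target points, computed by
#' interpolating each electrode's indicator vector. Rows for points
#' outside the electrode convex hull are all-NA.
#'
#' @param layout a [ChannelLayout-class].
#' @param px,py target point coordinates.
#' @return matrix length(px) x nScalpChannels of weights.
#' @export
interpWeights <- function(layout, px, py) {
  scalp <- which(layout@type == "eeg")
  if (length(scalp) < 3) stop("need >= 3 scalp electrodes")
  x <- layout@pos2d[scalp, 1]; y <- layout@pos2d[scalp, 2]
  if (abs(max(x) - min(x)) < 1e-9 || abs(max(y) - min(y)) < 1e-9)
    stop("degenerate (collinear) layout")
  w <- matrix(NA_real_, length(px), length(scalp),
              dimnames = list(NULL, layout@names[scalp]))
  for (j in seq_along(scalp)) {
    z <- numeric(length(scalp)); z[j] <- 1
    w[, j] <- interp::interp(x, y, z, output = "points",
                             xo = px, yo = py, method = "linear")$z
  }
  w
}

#' The 32 x 32 scalp grid
#'
#' Grid coordinates covering the bounding box of the unit-disk scalp
#' projection.
#'
#' @return list `x`, `y` (each numeric(32)).
#' @export
scalpGrid <- function() {
  list(x = seq(-1, 1, length.out = 32), y = seq(-1, 1, length.out = 32))
}

.weightCache <- new.env(parent = emptyenv())

# cached 32x32-grid interpolation weights for a layout
gridWeights <- function(layout) {
  key <- paste0(paste(layout@names, collapse = ","), "|",
                signif(sum(layout@pos2d * seq_along(layout@pos2d)), 12))
  if (!is.null(.weightCache[[key]])) return(.weightCache[[key]])
  grid <- scalpGrid()
  gx <- rep(grid$x, times = 32)           # column-major: x fastest
  gy <- rep(grid$y, each = 32)
  W <- interpWeights(layout, gx, gy)
  mask <- rowSums(is.na(W)) == 0
  res <- list(W = W, mask = mask)
  .weightCache[[key]] <- res
  res
}

#' Interpolate epochs into scalp-space volumes
#'
#' Per time sample, linearly interpolates the scalp-channel values onto
#' the 32 x 32 grid (triangulation-based barycentric weights; exact for
#' affine fields and at electrode positions). Cells outside the
#' electrode convex hull are masked. The result holds one volume per
#' trial, flattened as described in [ScalpVolumes-class].
#'
#' @param epochs an [EpochSet-class].
#' @return a [ScalpVolumes-class].
#' @export
scalpInterpolate <- function(epochs) {
  vols <- channelsToVolumes(
    lapply(seq_len(dim(epochs@data)[3]),
           function(t) epochs@data[, , t]),
    epochs@layout, epochs@times, meta = epochs@trialMeta)
  vols
}

#' Build scalp volumes from channels x samples matrices
#'
#' Lower-level entry used both for per-trial epochs and per-subject
#' contrast maps.
#'
#' @param mats list of channels x samples matrices (full layout rows).
#' @param layout a [ChannelLayout-class].
#' @param times sample times, seconds.
#' @param meta per-volume metadata.
#' @return a [ScalpVolumes-class].
#' @export
channelsToVolumes <- function(mats, layout, times, meta = data.frame()) {
  grid <- scalpGrid()
  gw <- gridWeights(layout)
  W <- gw$W; mask <- gw$mask
  Wm <- W[mask, , drop = FALSE]
  scalp <- which(layout@type == "eeg")
  dat <- vapply(mats, function(m) {
    as.vector(Wm %*% m[scalp, , drop = FALSE])
  }, numeric(sum(mask) * length(times)))
  if (is.null(dim(dat))) dat <- matrix(dat, ncol = length(mats))
  new("ScalpVolumes", gridX = grid$x, gridY = grid$y, mask = mask,
      times = times, data = dat, meta = as.data.frame(meta))
}
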