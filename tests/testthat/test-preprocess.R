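test_that("filter chain notches 50 Hz and preserves the passband", {
  sf <- 2048
  t <- seq(0, 8 - 1 / sf, by = 1 / sf)
  x <- rbind(sin(2 * pi * 50 * t), sin(2 * pi * 5 * t))
  y <- filterChain(x, sf)
  mid <- seq(2 * sf, 6 * sf)              # avoid edge transients
  amp50 <- max(abs(y[1, mid]))
  expect_lt(20 * log10(amp50 / 1), -40)   # >= 40 dB attenuation
  amp5 <- max(abs(y[2, mid]))
  expect_equal(amp5, 1, tolerance = 0.02)
  # high-pass removes a DC offset over long segments (the 0.01 Hz
  # corner has a ~16 s time constant, so use minutes of data)
  sfl <- 512
  zlong <- filterChain(matrix(3, 1, 240 * sfl), sfl)
  interior <- seq(100 * sfl, 140 * sfl)
  expect_lt(max(abs(zlong[1, interior])), 0.15)
})

test_that("downsampling decimates cleanly and remaps events", {
  sf <- 2048
  t <- seq(0, 4 - 1 / sf, by = 1 / sf)
  x <- matrix(sin(2 * pi * 5 * t), 1)
  ds <- downsampleRecording(x, sf, 512, events = c(2048, 4096))
  expect_equal(ncol(ds$data), length(t) / 4)
  expect_equal(ds$sfreq, 512)
  expect_equal(ds$events, c(512, 1024))
  mid <- seq(512, 3 * 512)
  expect_equal(max(abs(ds$data[1, mid])), 1, tolerance = 0.02)
  expect_error(downsampleRecording(x, sf, 500), "non-integer")
})

test_that("common-average reference zeroes the scalp mean exactly", {
  lay <- standardLayout64()
  set.seed(40)
  x <- matrix(rnorm(66 * 100), 66)
  y <- rereferenceAverage(x, lay)
  scalp <- which(lay@type == "eeg")
  expect_equal(colMeans(y[scalp, ]), rep(0, 100), tolerance = 1e-12)
  # idempotent; channel differences preserved
  expect_equal(rereferenceAverage(y, lay), y)
  expect_equal(y[3, ] - y[7, ], x[3, ] - x[7, ])
})

test_that("blink removal recovers contaminated frontal channels", {
  lay <- standardLayout64()
  sf <- 512
  set.seed(41)
  clean <- generateNoise(66, sf * 40, sf, sd = 5, spatialMix = "auto",
                         layout = lay)
  bl <- injectBlinks(clean, lay, sf, ratePerMin = 15, amplitude = 250)
  res <- removeBlinks(bl$data, lay, sf)
  expect_gte(length(res$peaks), 3)
  frontal <- match(c("Fp1", "Fpz", "Fp2", "AF3"), channelNames(lay))
  win <- unlist(lapply(bl$onsets, function(o) o:(o + round(0.3 * sf))))
  win <- win[win <= ncol(clean)]
  varBefore <- mean(apply(bl$data[frontal, win], 1, var))
  varAfter <- mean(apply(res$data[frontal, win], 1, var))
  expect_lt(varAfter, 0.2 * varBefore)
  # blink-free data pass through nearly unchanged
  expect_warning(res2 <- removeBlinks(clean, lay, sf), "fewer than")
  expect_identical(res2$data, clean)
})

test_that("epoching extracts the exact window and drops edge events", {
  lay <- standardLayout64()
  x <- matrix(seq_len(66 * 5120), 66)
  ev <- c(1, 1024, 2048, 5100)            # first and last too close
  ep <- epochRecording(x, 512, ev, lay)
  expect_equal(dim(epochData(ep)), c(66, 359, 2))
  expect_equal(attr(trialMeta(ep), "dropped"), c(1L, 4L))
  # values are exact slices
  expect_equal(epochData(ep)[, , 1], x[, 1024 + (-51:307)],
               ignore_attr = TRUE)
  expect_equal(epochTimes(ep), (-51:307) / 512)
})

test_that("artifact rejection flags, interpolates and removes correctly", {
  lay <- standardLayout64()
  set.seed(42)
  trials <- data.frame(percept = rep(c("one", "two"), 15))
  ep <- simulateSubjectEpochs(trials, noiseSd = 5, layout = lay)
  res <- rejectArtifacts(ep)
  expect_true(all(res$keptMask))          # clean data: nothing rejected
  expect_equal(nrow(res$interpolated), 0)
  # inject large transients into one channel on 30% of trials
  dat <- epochData(ep)
  ch <- match("C3", channelNames(lay))
  badTrials <- 1:9
  dat[ch, 100, badTrials] <- 4000
  ep2 <- EpochSet(dat, 512, epochTimes(ep), lay, trials)
  res2 <- rejectArtifacts(ep2)
  expect_equal(unique(res2$interpolated$channel), "C3")
  expect_true(all(res2$keptMask))
  # interpolated channel equals the inverse-distance neighbour average
  w <- stdtsim:::idwWeights(lay, ch)
  expected <- crossprod(w, dat[names(w), , 3])
  expect_equal(epochData(res2$epochs)[ch, , 3], as.vector(expected))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  lay <- standardLayout64()
  trials <- data.frame(percept = c("one", "two"))
  ep <- simulateSubjectEpochs(trials, noiseSd = 3, layout = lay)
  bc <- baselineCorrect(ep)
  sel <- epochTimes(bc) <= 0
  bl <- apply(epochData(bc)[, sel, , drop = FALSE], c(1, 3), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-12)
  # constant epochs become all zeros
  const <- EpochSet(array(7, dim = c(66, 359, 1)), 512, epochTimes(ep), lay,
                    data.frame(percept = "one"))
  expect_equal(max(abs(epochData(baselineCorrect(const)))), 0)
})

test_that("scalp interpolation is exact at electrodes and for affine fields", {
  lay <- standardLayout64()
  scalp <- which(lay@type == "eeg")
  pos <- lay@pos2d[scalp, ]
  # weights at electrode positions reproduce the indicator
  W <- interpWeights(lay, pos[1:10, 1], pos[1:10, 2])
  expect_equal(W[cbind(1:10, 1:10)], rep(1, 10), tolerance = 1e-9)
  # constant field -> constant volume inside the mask
  tms <- c(0, 0.1)
  mats <- list(matrix(5, 66, 2))
  vols <- channelsToVolumes(mats, lay, tms)
  expect_equal(range(volumeData(vols)), c(5, 5), tolerance = 1e-9)
  # affine field recovered exactly inside the hull
  aff <- matrix(2 + 3 * lay@pos2d[, 1] - 1.5 * lay@pos2d[, 2], 66, 2)
  vols2 <- channelsToVolumes(list(aff), lay, tms)
  gx <- rep(vols2@gridX, times = 32)[volumeMask(vols2)]
  gy <- rep(vols2@gridY, each = 32)[volumeMask(vols2)]
  expected <- rep(2 + 3 * gx - 1.5 * gy, 2)
  expect_equal(volumeData(vols2)[, 1], expected, tolerance = 1e-9)
  # every volume shares the same mask by construction
  expect_equal(sum(volumeMask(vols)), nrow(volumeData(vols)) / 2)
})

test_that("end-to-end preprocessing recovers the injected components", {
  lay <- standardLayout64()
  set.seed(43)
  # moderate noise so the trial-averaged ERP is dominated by signal at
  # every peak channel (the fidelity of the chain is what is under test)
  trials <- data.frame(percept = rep(c("one", "two"), 20))
  cont <- simulateContinuous(trials, sfreq = 2048, noiseSd = 2,
                             blinkRatePerMin = 15)
  x <- filterChain(cont$data, cont$sfreq)
  ds <- downsampleRecording(x, cont$sfreq, 512, events = cont$events$sample)
  y <- rereferenceAverage(ds$data, lay)
  y <- removeBlinks(y, lay, 512)$data
  ep <- epochRecording(y, 512, ds$events, lay,
                       trialMeta = cont$events)
  kept <- rejectArtifacts(ep)
  cleaned <- baselineCorrect(lowpassEpochs(kept$epochs))
  erp <- apply(epochData(cleaned), c(1, 2), mean)
  # compare with the injected mean field, average-referenced
  tms <- epochTimes(cleaned) * 1000
  inj <- (stdtsim:::perceptField(defaultComponents(), lay, tms, "one") +
          stdtsim:::perceptField(defaultComponents(), lay, tms, "two")) / 2
  scalp <- which(lay@type == "eeg")
  inj[scalp, ] <- sweep(inj[scalp, ], 2, colMeans(inj[scalp, ]))
  for (ch in c("CP4", "C6", "CPz")) {
    i <- match(ch, channelNames(lay))
    expect_gt(cor(erp[i, ], inj[i, ]), 0.95)
  }
})
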