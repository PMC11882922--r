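test_that("standard layout carries the expected channels", {
  lay <- standardLayout64()
  expect_length(channelNames(lay), 66)
  expect_length(scalpChannels(lay), 64)
  expect_false(anyDuplicated(channelNames(lay)) > 0)
  expect_true(all(c("CP4", "C6", "FC2", "FC1", "FCz", "Cz", "C2", "CPz")
                  %in% scalpChannels(lay)))
  pos <- channelPositions(lay)
  scalp <- scalpChannels(lay)
  expect_true(all(sqrt(rowSums(pos[scalp, ]^2)) <= 1))
  # left-right symmetry of homologous pairs
  expect_equal(pos["C3", "y"], pos["C4", "y"])
  expect_equal(pos["C3", "x"], -pos["C4", "x"])
})

test_that("default components encode the somatosensory sequence", {
  comps <- defaultComponents()
  names(comps) <- vapply(comps, `[[`, "", "name")
  expect_equal(comps$P50$peakMs, 50)
  expect_equal(comps$P50$peakChannel, "CP4")
  expect_equal(comps$N140$peakMs, 120)
  expect_equal(comps$N140$peakChannel, "C6")
  expect_lt(comps$N140$ampOne, 0)
  expect_equal(comps$P300$peakChannel, "CPz")
  # only the P170 is percept-modulated
  mod <- vapply(comps, function(cp) cp$ampTwo - cp$ampOne, numeric(1))
  expect_equal(unname(mod), c(0, 0, 2, 0))
  # the null configuration removes the modulation entirely
  lay <- standardLayout64()
  tms <- epochWindow(512)$times * 1000
  expect_equal(differenceField(defaultComponents(delta = 0), lay, tms),
               matrix(0, 66, 359))
})

test_that("component fields peak at the stated channel and latency", {
  lay <- standardLayout64()
  tms <- epochWindow(512)$times * 1000
  spec <- erpComponent("P170", 170, "FC2", ampOne = 3, temporalSigma = 20)
  f <- componentField(spec, lay, tms)
  peakIdx <- which(f == max(f), arr.ind = TRUE)
  expect_equal(channelNames(lay)[peakIdx[1]], "FC2")
  expect_equal(abs(tms[peakIdx[2]] - 170) < 1, TRUE)
  # exactly amp at the peak channel and latency
  expect_equal(max(componentField(spec, lay, 170)), 3)
  expect_error(componentField(erpComponent("x", 100, "XX9", 1), lay, tms),
               "unknown")
  # time integral scales with the temporal width
  tDense <- seq(-500, 800, by = 0.5)
  i1 <- sum(componentField(spec, lay, tDense)[match("FC2", lay@names), ])
  spec2 <- spec; spec2$temporalSigma <- 40
  i2 <- sum(componentField(spec2, lay, tDense)[match("FC2", lay@names), ])
  expect_equal(i2 / i1, 2, tolerance = 1e-6)
})

test_that("noise generator honours spectrum, mixing and determinism", {
  set.seed(30)
  w <- generateNoise(8, 4096, 512, exponent = 0, alphaPower = 0, sd = 2)
  expect_equal(dim(w), c(8, 4096))
  expect_equal(apply(w, 1, sd), rep(2, 8), tolerance = 0.01)
  expect_lt(max(abs(cor(t(w))[upper.tri(diag(8))])), 0.1)
  # log-log spectral slope ~ -exponent over 1..40 Hz
  set.seed(31)
  x <- generateNoise(12, 2^15, 512, exponent = 1, alphaPower = 0)
  f <- seq(0, 512 - 512 / 2^15, length.out = 2^15)
  sel <- f >= 1 & f <= 40
  pows <- apply(x, 1, function(ch) abs(fft(ch))^2)
  slope <- coef(lm(log(rowMeans(pows[sel, ])) ~ log(f[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
  # stationarity: variance drift across thirds below 10% (channel mean)
  thirds <- split(seq_len(2^15), rep(1:3, each = 2^15 / 3, length.out = 2^15))
  v <- vapply(thirds, function(ix) mean(apply(x[, ix], 1, var)), numeric(1))
  expect_lt((max(v) - min(v)) / mean(v), 0.10)
  expect_error(generateNoise(4, 100, 512, exponent = -1), "exponent")
  # bit-identical reruns under the same seed
  set.seed(32); a <- generateNoise(4, 512, 512)
  set.seed(32); b <- generateNoise(4, 512, 512)
  expect_identical(a, b)
})

test_that("epoch window arithmetic gives 359 samples at 512 Hz", {
  win <- epochWindow(512)
  expect_length(win$idx, 359)
  expect_equal(range(win$idx), c(-51, 307))
  expect_equal(win$times[win$idx == 0], 0)
})

test_that("noiseless epochs reproduce the injected difference field", {
  lay <- standardLayout64()
  trials <- data.frame(percept = rep(c("one", "two"), each = 4))
  ep <- simulateSubjectEpochs(trials, noiseSd = 0, layout = lay)
  expect_s4_class(ep, "EpochSet")
  expect_equal(dim(epochData(ep)), c(66, 359, 8))
  erpOne <- apply(epochData(ep)[, , 1:4], c(1, 2), mean)
  erpTwo <- apply(epochData(ep)[, , 5:8], c(1, 2), mean)
  expect_equal(erpTwo - erpOne, attr(epochData(ep), "deltaField"),
               ignore_attr = TRUE)
  # the injected difference peaks inside the 129..178 ms window
  delta <- attr(epochData(ep), "deltaField")
  tms <- epochTimes(ep) * 1000
  peakT <- tms[which(delta == max(delta), arr.ind = TRUE)[2]]
  expect_gte(peakT, 129)
  expect_lte(peakT, 178)
})

test_that("fast subject contrast equals its trial-level counterpart", {
  lay <- standardLayout64()
  # noiseless: both routes give subjectScale * deltaField exactly
  ctr <- simulateSubjectContrast(nPerCond = 10, subjectScale = 1.3,
                                 noiseSd = 0, layout = lay)
  expect_equal(ctr, 1.3 * attr(ctr, "deltaField"), ignore_attr = TRUE)
  # with noise: variance of the contrast matches the averaged-noise level
  set.seed(33)
  draws <- replicate(40, {
    m <- simulateSubjectContrast(nPerCond = 25, noiseSd = 5, layout = lay,
                                 exponent = 0, alphaPower = 0)
    m[1, 100]
  })
  expect_equal(sd(draws), 5 * sqrt(2 / 25), tolerance = 0.45)
})

test_that("blink injection contaminates vEOG and frontal channels most", {
  lay <- standardLayout64()
  x <- matrix(0, 66, 2048 * 20)
  set.seed(34)
  bl <- injectBlinks(x, lay, 2048, ratePerMin = 30)
  expect_gt(length(bl$onsets), 2)
  veog <- match("vEOG", channelNames(lay))
  fpz <- match("Fpz", channelNames(lay))
  oz <- match("Oz", channelNames(lay))
  expect_gt(max(bl$data[veog, ]), max(bl$data[fpz, ]))
  expect_gt(max(bl$data[fpz, ]), max(bl$data[oz, ]))
  # rate 0 leaves the data untouched
  expect_identical(injectBlinks(x, lay, 2048, ratePerMin = 0)$data, x)
  # onsets reproducible under the seed
  set.seed(35); o1 <- injectBlinks(x, lay, 2048, 12)$onsets
  set.seed(35); o2 <- injectBlinks(x, lay, 2048, 12)$onsets
  expect_identical(o1, o2)
})
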