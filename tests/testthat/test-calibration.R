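test_that("detection staircase reproduces hand-simulated traces", {
  # threshold 2.33: ascend from 1.0 by 0.1 -> first felt at 2.4, then
  # halved steps reversing at each response change
  st <- runDetectionStaircase(stepObserver(40, detThreshold = 2.33))
  expect_equal(st$reversals, c(2.4, 2.30, 2.35, 2.325, 2.33125, 2.328125))
  expect_equal(st$estimate, 2.3390625)
  # threshold 1.05, one step above the start
  st2 <- runDetectionStaircase(stepObserver(40, detThreshold = 1.05))
  expect_equal(st2$reversals, c(1.1, 1.0, 1.05, 1.0375, 1.05, 1.046875))
  expect_equal(st2$estimate, 1.04739583333, tolerance = 1e-9)
  # estimate lies within the reversal range
  expect_true(st$estimate >= min(st$reversals) &&
                st$estimate <= max(st$reversals))
})

test_that("detection staircase converges over a dense threshold grid", {
  grid <- seq(1.2, 5, by = 0.02)
  err <- vapply(grid, function(th) {
    abs(runDetectionStaircase(stepObserver(40, detThreshold = th))$estimate -
          th)
  }, numeric(1))
  expect_lte(max(err), 0.05)
})

test_that("staircase fails loudly when the observer never responds", {
  expect_error(
    runDetectionStaircase(stepObserver(40, detThreshold = 500)),
    "staircase failure")
})

test_that("stimulation intensity doubles the threshold estimate", {
  expect_equal(stimulusIntensity(2.0), 4.0)
  expect_equal(stimulusIntensity(2.425), 4.85)   # reported mean intensity
  expect_equal(stimulusIntensity(0.5), 1.0)
  expect_error(stimulusIntensity(0), "positive")
})

test_that("STDT staircase averages the six series stopping points", {
  set.seed(5)
  # step observer at 43: ascending 2,7,...,47 stops at 47 (first ISI
  # past threshold); descending 120,...,40 stops at 40
  st <- runStdtStaircase(stepObserver(43))
  expect_equal(st$stops, rep(c(47, 40), 3))
  expect_equal(st$estimate, 43.5)
  # threshold below the ascending start: immediate switch
  st2 <- runStdtStaircase(stepObserver(1.5))
  expect_equal(st2$stops[c(1, 3, 5)], rep(2, 3))
  expect_error(runStdtStaircase(stepObserver(43), ascendingStart = 130),
               "below")
})

test_that("population staircase estimates track the thresholds", {
  set.seed(6)
  cohort <- sampleCohort(cohortSpec(n = 40))
  est <- vapply(cohort, function(o) runStdtStaircase(o)$estimate, numeric(1))
  t50 <- vapply(cohort, function(o) o@t50, numeric(1))
  keep <- t50 < 100            # within the default descending start
  expect_lt(abs(mean(est[keep]) - mean(t50[keep])), 5)
})

test_that("calibration ISIs are centred on the initial threshold", {
  expect_equal(calibrationIsis(44), seq(2, 86, by = 6))
  expect_equal(calibrationIsis(9), seq(2, 16, by = 1))
  for (stdt in c(10, 27.3, 44, 90)) {
    isis <- calibrationIsis(stdt)
    expect_length(isis, 15)
    expect_equal(isis[1], 2)
    expect_equal(isis[8], stdt)
    expect_equal(median(isis), stdt)
  }
  expect_error(calibrationIsis(2), "re-run")
})

test_that("calibration session counts trials correctly", {
  obs <- stepObserver(40)
  counts <- runCalibrationSession(obs, calibrationIsis(40))
  expect_equal(sum(counts$nTrials), 300)
  expect_equal(counts$nTwo[counts$isi < 40], rep(0, 7))
  expect_equal(counts$nTwo[counts$isi > 40], rep(20, 7))
})

test_that("logistic fit recovers noiseless parameters", {
  obs <- Observer(40, 8)
  fit <- fitLogistic(expectedCounts(obs, calibrationIsis(40)))
  expect_equal(fit@t50, 40, tolerance = 1e-4)
  expect_equal(fit@scale, 8, tolerance = 1e-4)
  expect_equal(fit@t01, 40 - 8 * log(99), tolerance = 1e-3)
  expect_lt(fit@mse, 1e-10)
  # threshold identity is structural
  expect_equal(fit@t99, 2 * fit@t50 - fit@t01)
})

test_that("logistic fit is deterministic and rejects no-information data", {
  counts <- data.frame(isi = calibrationIsis(35), nTrials = 20)
  set.seed(7)
  counts$nTwo <- rbinom(15, 20, psychometricP(counts$isi, Observer(35, 9)))
  f1 <- fitLogistic(counts); f2 <- fitLogistic(counts)
  expect_identical(f1@t50, f2@t50)
  expect_error(fitLogistic(data.frame(isi = 1:5, nTwo = 0, nTrials = 20)),
               "non-identifiable")
  expect_error(fitLogistic(data.frame(isi = 1, nTwo = 3, nTrials = 20)),
               "distinct")
})

test_that("fit residual mse stays below the binomial variance bound", {
  obs <- Observer(40, 8)
  isis <- calibrationIsis(40)
  p <- psychometricP(isis, obs)
  bound <- mean(p * (1 - p)) / 20
  set.seed(8)
  mses <- replicate(50, fitLogistic(runCalibrationSession(obs, isis))@mse)
  expect_true(all(mses >= 0))
  expect_lt(mean(mses), bound)
})

test_that("design levels span T01..T99 with the threshold as midpoint", {
  fit <- PsychometricFit(t50 = 40.505, scale = (78.56 - 2.45) / (2 * log(99)))
  lv <- designIsiLevels(fit)
  expect_equal(lv[1], fit@t01)
  expect_equal(lv[10], fit@t99)
  expect_equal(diff(lv), rep((fit@t99 - fit@t01) / 9, 9))
  expect_equal((lv[5] + lv[6]) / 2, fit@t50)
})

test_that("negative-T01 rule shifts the span symmetrically toward t50", {
  # t01 = -5, t50 = 20, t99 = 45: delta = 6, levels 1..39
  fit <- PsychometricFit(t50 = 20, scale = 25 / log(99))
  expect_equal(fit@t01, -5)
  lv <- designIsiLevels(fit)
  expect_equal(lv[1], 1)
  expect_equal(lv[10], 39)
  expect_equal(diff(lv)[1], 38 / 9, tolerance = 1e-12)
  expect_equal((lv[5] + lv[6]) / 2, 20)
  expect_error(designIsiLevels(PsychometricFit(t50 = 0.9, scale = 5)),
               "exceed 1 ms")
})

test_that("trial allocation reproduces the anchored normal shape", {
  counts <- allocateTrials()
  expect_equal(counts, c(8L, 13L, 20L, 27L, 32L, 32L, 27L, 20L, 13L, 8L))
  expect_equal(sum(counts), 200)
  expect_equal(counts, rev(counts))
  expect_true(all(diff(counts[1:5]) >= 0))          # unimodal
  expect_equal(sum(counts[2:4]), (200 - 2 * 8 - 2 * 32) / 2)
})

test_that("fit and design tables are written as TSV", {
  fit <- PsychometricFit(40, 8, mse = 0.01, nTrials = 300L)
  path <- tempfile(fileext = ".tsv")
  writeFitTable(list(obs01 = fit), path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$t99, 2 * tab$t50 - tab$t01)
  d <- defaultDesign()
  path2 <- tempfile(fileext = ".tsv")
  writeDesignTable(d, path2)
  tab2 <- read.table(path2, header = TRUE, sep = "\t")
  expect_equal(sum(tab2$trials_per_run), 200)
  unlink(c(path, path2))
})
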