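test_that("first-level contrast equals the ERP difference exactly", {
  set.seed(50)
  nv <- 16 * 10                           # 4x4 grid, 10 samples
  dat <- matrix(rnorm(nv * 12), nv, 12)
  vols <- toyVolumes(dat, ng = 4, nt = 10,
                     meta = data.frame(percept = rep(c("one", "two"), 6)))
  ctr <- firstLevel(vols)
  expected <- rowMeans(dat[, c(FALSE, TRUE)]) - rowMeans(dat[, c(TRUE, FALSE)])
  expect_equal(volumeData(ctr)[, 1], expected, tolerance = 1e-14)
  # identical to the dummy-regression solution per voxel (lm oracle)
  g <- factor(rep(c("one", "two"), 6))
  for (v in c(1, 57, 160)) {
    fit <- lm(dat[v, ] ~ 0 + g)
    expect_equal(volumeData(ctr)[v, 1],
                 unname(coef(fit)["gtwo"] - coef(fit)["gone"]))
  }
  expect_error(firstLevel(vols, rep("one", 12)), "each condition")
  # identical conditions give a zero contrast
  vols2 <- toyVolumes(cbind(dat[, 1], dat[, 1]), ng = 4, nt = 10)
  expect_equal(max(abs(volumeData(firstLevel(vols2, c("one", "two"))))), 0)
})

test_that("randomized percept labels yield a near-zero mean contrast", {
  set.seed(51)
  dat <- matrix(rnorm(160 * 10), 160, 10)
  vols <- toyVolumes(dat, ng = 4, nt = 10)
  perms <- replicate(200, {
    lab <- sample(rep(c("one", "two"), 5))
    mean(volumeData(firstLevel(vols, lab)))
  })
  expect_lt(abs(mean(perms)), 3 * sd(perms) / sqrt(200) + 1e-3)
})

test_that("second-level t matches a per-voxel regression oracle", {
  set.seed(52)
  n <- 9
  dat <- matrix(rnorm(160 * n, mean = 0.3), 160, n)
  cov <- rnorm(n, 30, 10)
  vols <- toyVolumes(dat, ng = 4, nt = 10)
  res <- secondLevel(vols, cov)
  expect_equal(res$df, n - 2)
  cc <- cov - mean(cov)
  for (v in c(3, 80, 144)) {
    fit <- summary(lm(dat[v, ] ~ cc))
    expect_equal(res$t[v], unname(fit$coefficients["(Intercept)", "t value"]),
                 tolerance = 1e-10)
  }
  # centering invariance
  res2 <- secondLevel(vols, cov + 100)
  expect_equal(res$t, res2$t)
  # constant covariate falls back to the one-sample t with a warning
  expect_warning(res3 <- secondLevel(vols, rep(4, n)), "constant")
  plain <- secondLevel(vols)
  expect_equal(res3$t, plain$t)
  expect_equal(res3$df, n - 1)
  expect_error(secondLevel(vols, c(NA, rnorm(n - 1))), "finite")
})

test_that("a covariate orthogonal to the data leaves the t-map unchanged", {
  set.seed(53)
  n <- 10
  cc <- rnorm(n); cc <- cc - mean(cc)
  dat <- matrix(rnorm(160 * n, 0.2), 160, n)
  # project the covariate direction out of every voxel
  dat <- dat - outer(as.vector(dat %*% cc) / sum(cc^2), cc)
  vols <- toyVolumes(t(t(dat)), ng = 4, nt = 10)
  tWith <- secondLevel(vols, cc)$t
  tWithout <- secondLevel(vols)$t
  # same numerator and residual sum of squares; only df differs, so the
  # two t-maps agree up to the deterministic df rescaling
  expect_equal(tWith, tWithout * sqrt((n - 2) / (n - 1)), tolerance = 1e-10)
})

test_that("cluster finding respects 6-connectivity and the mask", {
  nt <- 10
  vols <- toyVolumes(matrix(0, 16 * nt, 1), ng = 4, nt = nt)
  tv <- rep(0, 16 * nt)
  expect_equal(nrow(findClusters(tv, 11, vols)), 0)
  # two voxels sharing only a diagonal corner: two clusters
  # grid cell (x, y) at time 1: row = (y-1)*4 + x
  tv2 <- tv; tv2[c(1, 6)] <- 10           # (1,1) and (2,2)
  cl2 <- findClusters(tv2, 11, vols)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$k_voxels, c(1L, 1L))
  # L-shaped 3-voxel blob: one cluster of extent 3
  tv3 <- tv; tv3[c(1, 2, 6)] <- 10        # (1,1), (2,1), (2,2)
  cl3 <- findClusters(tv3, 11, vols)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$k_voxels, 3L)
  # temporal adjacency joins voxels across samples
  tv4 <- tv; tv4[c(1, 1 + 16)] <- 10      # same cell, samples 1 and 2
  expect_equal(findClusters(tv4, 11, vols)$k_voxels, 2L)
  # masked-out cells never cluster (mask excludes cell 2)
  volsM <- vols; volsM@mask[2] <- FALSE
  volsM@data <- matrix(0, 15 * nt, 1)
  tv5 <- rep(0, 15 * nt); tv5[c(1, 2)] <- 10   # cells 1 and 3 now adjacent rows
  cl5 <- findClusters(tv5, 11, volsM)
  expect_equal(nrow(cl5), 2)              # cell 2 gone: no bridge
})

test_that("cluster peaks and time spans are reported correctly", {
  nt <- 20
  vols <- toyVolumes(matrix(0, 16 * nt, 1), ng = 4, nt = nt)
  tv <- rep(0, 16 * nt)
  rows <- 16 * (4:8) + 6                  # cell 6 over samples 5..9
  tv[rows] <- c(5, 6, 9, 6, 5)
  cl <- findClusters(tv, 11, vols)
  expect_equal(cl$k_voxels, 5L)
  expect_equal(cl$time_min_ms, vols@times[5] * 1000)
  expect_equal(cl$time_max_ms, vols@times[9] * 1000)
  expect_equal(cl$t_peak, 9)
  expect_equal(cl$peak_time_ms, vols@times[7] * 1000)
})

test_that("permutation FWE control has a valid p-value floor", {
  set.seed(54)
  n <- 10; nt <- 12
  # strong common effect in a 2x2 block of cells over several samples
  base <- matrix(rnorm(16 * nt * n, 0, 0.5), 16 * nt, n)
  effRows <- as.vector(outer(16 * (3:8), c(6, 7, 10, 11), `+`))
  base[effRows, ] <- base[effRows, ] + 5
  vols <- toyVolumes(base, ng = 4, nt = nt)
  res <- suppressWarnings(clusterFwe(vols, nPerm = 99L, clusterAlpha = 0.001))
  expect_gte(nrow(res$clusters), 1)
  expect_equal(min(res$clusters$p_fwe_cluster), 1 / 100)
  expect_equal(min(res$clusters$p_fwe_peak), 1 / 100)
  expect_length(res$nullMaxExtent, 99)
  expect_error(clusterFwe(vols, nPerm = 10L), ">= 20")
  small <- toyVolumes(base[, 1:5], ng = 4, nt = nt)
  expect_error(clusterFwe(small, nPerm = 100L), ">= 8")
})

test_that("median split partitions subjects and analyses each side", {
  set.seed(55)
  n <- 16; nt <- 8
  dat <- matrix(rnorm(16 * nt * n, 1.5), 16 * nt, n)
  vols <- toyVolumes(dat, ng = 4, nt = nt)
  stdts <- c(runif(8, 10, 25), runif(8, 35, 80))
  res <- suppressWarnings(
    medianSplitAnalysis(vols, stdts, nPerm = 50L))
  expect_equal(as.integer(table(res$groups)[c("low", "high")]), c(8L, 8L))
  expect_true(is.data.frame(res$low$clusters))
  expect_true(is.data.frame(res$high$clusters))
  expect_error(medianSplitAnalysis(vols, rep(10, n), nPerm = 50L),
               ">= 4")
})

test_that("run-drift covariate variant matches an lm oracle", {
  set.seed(56)
  n <- 12; nt <- 6
  dat <- matrix(rnorm(16 * nt * n, 0.8), 16 * nt, n)
  vols <- toyVolumes(dat, ng = 4, nt = nt)
  stdts <- rnorm(n, 40, 15)
  drift <- rnorm(n, 5, 1)
  res <- suppressWarnings(
    runCovariateVariant(vols, stdts, drift, nPerm = 50L))
  s1 <- stdts - mean(stdts); d1 <- drift - mean(drift)
  for (v in c(2, 50)) {
    fit <- summary(lm(dat[v, ] ~ s1 + d1))
    expect_equal(res$t[v],
                 unname(fit$coefficients["(Intercept)", "t value"]),
                 tolerance = 1e-8)
  }
  expect_equal(res$df, n - 3)
  expect_error(runCovariateVariant(vols, stdts, drift[1:3]), "per subject")
})
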