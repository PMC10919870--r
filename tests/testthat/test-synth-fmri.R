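# Response simulator: noiseless exactness, Spearman-Brown reliability of
# averaged repeats, time-series structure, and localizer selectivity.

test_that("noiseless averaged responses equal x'W* + b* exactly", {
  truth <- makeGroundTruth(4, 9, noiseSd = 0, seed = 2)
  X <- randMatrix(30, 4, 1); Xt <- randMatrix(20, 4, 2)
  fve <- simulateVoxelResponses(X, Xt, truth, repeats = 3, seed = 3)
  W <- encodingWeights(truth); b <- faceBias(truth)
  expect_equal(trainResponses(fve), X %*% W + rep(b, each = 30),
               ignore_attr = TRUE)
  expect_equal(testResponses(fve), Xt %*% W + rep(b, each = 20),
               ignore_attr = TRUE)
  expect_error(simulateVoxelResponses(X[, 1:3], Xt, truth), "must match")
})

test_that("container validity ties repeats to voxels and test stimuli", {
  truth <- makeGroundTruth(3, 6, seed = 1)
  fve <- simulateVoxelResponses(randMatrix(25, 3, 4), randMatrix(20, 3, 5),
                                truth, repeats = 4, seed = 6)
  expect_s4_class(fve, "FaceVoxelExperiment")
  expect_identical(dim(testRepeatArray(fve)), c(20L, 6L, 4L))
  expect_equal(testResponses(fve),
               t(apply(testRepeatArray(fve), c(2, 1), mean)),
               ignore_attr = TRUE)
})

test_that("split-half reliability of 50 averaged repeats at SNR 1 matches Spearman-Brown", {
  truth <- makeGroundTruth(4, 60, seed = 3)
  Xt <- randMatrix(20, 4, 7)
  truth <- setNoiseSd(truth, noiseSdForSnr(truth, Xt, 1))
  fve <- simulateVoxelResponses(randMatrix(50, 4, 8), Xt, truth,
                                repeats = 50, seed = 9)
  rel <- splitHalfReliability(fve, nSplits = 30, seed = 10)
  # Pearson reliability of 25-trial averages at per-trial SNR 1 is
  # 1 / (1 + 1/25) = 25/26; converted to Spearman for bivariate Gaussians:
  rhoP <- 25 / 26
  rhoS <- (6 / pi) * asin(rhoP / 2)
  expect_equal(mean(rel), rhoS, tolerance = 0.03)
})

test_that("reliability is 1 without noise and near 0 for pure noise", {
  truth0 <- makeGroundTruth(3, 10, noiseSd = 0, seed = 4)
  fve0 <- simulateVoxelResponses(randMatrix(50, 3, 11), randMatrix(20, 3, 12),
                                 truth0, repeats = 4, seed = 13)
  expect_equal(splitHalfReliability(fve0, nSplits = 5, seed = 1),
               rep(1, 10))
  truthN <- makeGroundTruth(3, 10, noiseSd = 1, seed = 5)
  truthN@W[] <- 0
  fveN <- simulateVoxelResponses(randMatrix(50, 3, 14), randMatrix(20, 3, 15),
                                 truthN, repeats = 10, seed = 16)
  relN <- splitHalfReliability(fveN, nSplits = 100, seed = 2)
  expect_lt(abs(mean(relN)), 0.1)
  expect_error(splitHalfReliability(array(0, c(20, 5, 1))), "at least 2")
})

test_that("reliability increases with repeat count at fixed noise", {
  wins <- 0L
  for (i in 1:30) {
    truth <- makeGroundTruth(3, 8, seed = i)
    Xt <- randMatrix(20, 3, 100 + i)
    truth <- setNoiseSd(truth, noiseSdForSnr(truth, Xt, 0.5))
    Xtr <- randMatrix(50, 3, 200 + i)
    f40 <- simulateVoxelResponses(Xtr, Xt, truth, repeats = 40, seed = 300 + i)
    f60 <- simulateVoxelResponses(Xtr, Xt, truth, repeats = 60, seed = 400 + i)
    r40 <- mean(splitHalfReliability(f40, nSplits = 10, seed = i))
    r60 <- mean(splitHalfReliability(f60, nSplits = 10, seed = i))
    wins <- wins + (r60 > r40)
  }
  expect_gt(wins, 22)   # paired direction, Spearman-Brown
})

test_that("time series is flat at b* when weights, drift, motion and noise are zero", {
  truth <- makeGroundTruth(3, 5, noiseSd = 0, seed = 1)
  truth@W[] <- 0; truth@driftCoefs[] <- 0; truth@motionCoefs[] <- 0
  ss <- simulateTimeseries(randMatrix(20, 3, 17), randMatrix(3, 3, 18), truth,
                           TR = 2, testRepeats = 2, seed = 19)
  expect_equal(ss@series,
               matrix(faceBias(truth), nrow(ss@series), 5, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("stimulus events are spaced 3 seconds apart (1 s on, 2 s ISI)", {
  truth <- makeGroundTruth(3, 4, seed = 2)
  ss <- simulateTimeseries(randMatrix(20, 3, 20), randMatrix(3, 3, 21), truth,
                           TR = 2, testRepeats = 3, seed = 22)
  for (r in unique(ss@events$run)) {
    expect_equal(unique(diff(sort(ss@events$onset[ss@events$run == r]))), 3)
  }
  expect_true(all(ss@events$duration == 1))
  expect_error(simulateTimeseries(randMatrix(20, 3, 1), randMatrix(3, 3, 2),
                                  truth, TR = 0), "TR must be positive")
})

test_that("regressing a noiseless time series on the true design recovers all coefficients", {
  truth <- makeGroundTruth(4, 6, nRuns = 2L, noiseSd = 0, seed = 3)
  X <- randMatrix(30, 4, 23); Xt <- randMatrix(3, 4, 24)
  ss <- simulateTimeseries(X, Xt, truth, TR = 2, testRepeats = 2,
                           nRuns = 2L, seed = 25)
  rownames(X) <- sprintf("train_%04d", 1:30)
  d <- buildDesign(X, testIds = sprintf("test_%02d", 1:3), mode = "hrf",
                   events = ss@events, TR = 2, runIndex = ss@runIndex,
                   motion = ss@motion)
  fit <- fitEncodingGlm(d, ss@series)
  expect_lt(max(abs(encodingWeights(fit) - encodingWeights(truth))), 1e-6)
  expect_lt(max(abs(faceBias(fit) - faceBias(truth))), 1e-6)
  nuis <- fit@nuisance
  for (r in 1:2) {
    expect_lt(max(abs(nuis[sprintf("drift(%d)", r), ] - truth@driftCoefs[r, ])), 1e-6)
    for (a in 1:3) {
      expect_lt(max(abs(nuis[sprintf("motion(%d,%d)", a, r), ] -
                          truth@motionCoefs[3 * (r - 1) + a, ])), 1e-6)
    }
  }
})

test_that("localizer: no shift gives exchangeable groups, 3-sd shift separates them", {
  mask <- c(rep(TRUE, 500), rep(FALSE, 500))
  loc0 <- simulateLocalizer(mask, shift = 0, seed = 1)
  p <- t.test(selectivity(loc0)[mask], selectivity(loc0)[!mask])$p.value
  expect_gt(p, 0.01)

  # with a 3-sd shift on both selectivity and reliability, top-10% selection
  # recovers the masked voxels (mean over seeds; normal-tail separation)
  recov <- vapply(1:20, function(i) {
    m <- c(rep(TRUE, 100), rep(FALSE, 900))
    loc <- simulateLocalizer(m, shift = 3, seed = i)
    set.seed(i + 5000)
    rel <- rnorm(1000) + 3 * m
    mean(isSelected(parcelSelect(loc, rel, fraction = 0.1))[m])
  }, numeric(1))
  expect_gte(mean(recov), 0.95)
})

test_that("parcel labels survive localizer simulation and selection", {
  labels <- rep(c("OFA", "FFA"), each = 10)
  loc <- simulateLocalizer(rep(TRUE, 20), shift = 1, parcelLabels = labels, seed = 2)
  expect_identical(parcels(loc), labels)
  sel <- parcelSelect(loc, rnorm(20), fraction = 0.2)
  expect_identical(parcels(sel), labels)
  expect_equal(sum(isSelected(sel)[labels == "OFA"]), 2)
  expect_equal(sum(isSelected(sel)[labels == "FFA"]), 2)
})
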