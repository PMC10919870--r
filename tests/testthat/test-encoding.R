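# Encoding GLM: design construction, OLS fitting against a normal-equations
# oracle, prediction, and Spearman evaluation against a rank-Pearson oracle.

test_that("amplitude design for 24 dims, 20 test images and one run has 49 columns", {
  X <- randMatrix(40, 24, 1)
  motion <- randMatrix(60, 3, 2)
  d <- buildDesign(X, testIds = sprintf("t%02d", 1:20), run = rep(1L, 60),
                   motion = motion)
  expect_identical(ncol(designValues(d)), 49L)   # 24 + 20 + 1 + 1 + 3
  roles <- columnRoles(d)
  expect_identical(sum(roles == "face_bias"), 1L)
  expect_identical(sum(grepl("^latent", roles)), 24L)
  expect_identical(sum(grepl("^test_image", roles)), 20L)
  expect_identical(sum(grepl("^drift", roles)), 1L)
  expect_identical(sum(grepl("^motion", roles)), 3L)
})

test_that("all-zero latents produce zero latent columns and zero fitted weights", {
  X <- matrix(0, 30, 3)
  d <- buildDesign(X, testIds = c("a", "b"))
  expect_true(all(designValues(d)[, 1:3] == 0))
  y <- matrix(rnorm(32 * 4), 32, 4)
  fit <- suppressWarnings(fitEncodingGlm(d, y))
  expect_equal(encodingWeights(fit), matrix(0, 3, 4), ignore_attr = TRUE)
})

test_that("an hrf-mode column for a single event is the shifted, scaled kernel", {
  TR <- 2
  X <- matrix(2.5, 1, 1, dimnames = list("s1", NULL))
  events <- data.frame(onset = 6, duration = 1, stimulus_id = "s1", run = 1L)
  runIndex <- rep(1L, 30)
  d <- buildDesign(X, mode = "hrf", events = events, TR = TR,
                   runIndex = runIndex)
  col <- designValues(d)[, 1]
  # direct convolution oracle: kernel at t - onset, scaled by the latent
  # value; the design kernel has 32 s of support
  t <- (seq_len(30) - 1) * TR - 6
  oracle <- 2.5 * canonicalHrf(t) * (t <= 32)
  expect_equal(col, oracle, tolerance = 1e-10)
})

test_that("hrf mode errors on stimuli without latent rows", {
  X <- matrix(1, 1, 1, dimnames = list("s1", NULL))
  events <- data.frame(onset = c(0, 3), duration = 1,
                       stimulus_id = c("s1", "mystery"), run = 1L)
  expect_error(buildDesign(X, mode = "hrf", events = events, TR = 2,
                           runIndex = rep(1L, 20)),
               "mystery")
})

test_that("OLS fit matches the normal-equations oracle and leaves orthogonal residuals", {
  set.seed(4)
  X <- randMatrix(50, 5, 5)
  d <- buildDesign(X, testIds = c("t1", "t2", "t3"))
  Xd <- designValues(d)
  y <- matrix(rnorm(53 * 7), 53, 7)
  fit <- fitEncodingGlm(d, y)
  oracle <- solve(crossprod(Xd), crossprod(Xd, y))
  roles <- columnRoles(d)
  expect_equal(encodingWeights(fit), oracle[grepl("^latent", roles), ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(faceBias(fit), oracle[roles == "face_bias", ], tolerance = 1e-8,
               ignore_attr = TRUE)
  coefs <- rbind(encodingWeights(fit),
                 fit@nuisance[seq_len(3), , drop = FALSE],
                 matrix(faceBias(fit), 1))
  # residuals orthogonal to every design column
  full <- qr.coef(qr(Xd), y)
  resid <- y - Xd %*% full
  expect_lt(max(abs(crossprod(Xd, resid))), 1e-8)
})

test_that("noiseless simulated responses identify W* and b* exactly", {
  truth <- makeGroundTruth(6, 15, noiseSd = 0, seed = 6)
  X <- randMatrix(80, 6, 7); Xt <- randMatrix(20, 6, 8)
  fve <- simulateVoxelResponses(X, Xt, truth, repeats = 2, seed = 9)
  d <- buildDesign(X, testIds = rownames(testResponses(fve)))
  fit <- fitEncodingGlm(d, rbind(trainResponses(fve), testResponses(fve)))
  relErr <- max(abs(encodingWeights(fit) - encodingWeights(truth))) /
    max(abs(encodingWeights(truth)))
  expect_lt(relErr, 1e-6)
  expect_lt(max(abs(faceBias(fit) - faceBias(truth))), 1e-6)
})

test_that("pure-drift responses load on the drift regressor, not the latents", {
  X <- randMatrix(40, 3, 10)
  run <- rep(1L, 42)
  d <- buildDesign(X, testIds = c("t1", "t2"), run = run)
  roles <- columnRoles(d)
  driftCol <- designValues(d)[, roles == "drift(1)"]
  y <- matrix(driftCol * 2.5, ncol = 1)
  fit <- fitEncodingGlm(d, y)
  expect_equal(max(abs(encodingWeights(fit))), 0, tolerance = 1e-10)
  expect_equal(fit@nuisance["drift(1)", 1], 2.5, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("rank-deficient designs warn and fall back to the minimum-norm solution", {
  X <- cbind(1:10, (1:10) * 2)   # collinear latents
  d <- buildDesign(X)
  y <- matrix(X[, 1] * 3, ncol = 1)
  expect_warning(fit <- fitEncodingGlm(d, y), "rank deficient")
  expect_true(all(is.finite(encodingWeights(fit))))
})

test_that("prediction is X W + b, matching a hand-computed 2 x 2 example", {
  W <- matrix(c(2, -1, 0, 3), 2, 2)   # dims x voxels
  fit <- new("EncodingFit", W = W, b = c(10, 20),
             nuisance = matrix(0, 0, 2), mode = "amplitude")
  # zero latents -> bias only
  expect_equal(predictTestResponses(fit, matrix(0, 3, 2)),
               matrix(c(10, 10, 10, 20, 20, 20), 3, 2), ignore_attr = TRUE)
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  # row 1: (1,0) %*% W = (2, 0); row 2: (0,1) %*% W = (-1, 3)
  expect_equal(predictTestResponses(fit, X),
               matrix(c(12, 9, 20, 23), 2, 2), ignore_attr = TRUE)
  # identity W, zero b, identity latents -> identity predictions
  fitI <- new("EncodingFit", W = diag(2), b = c(0, 0),
              nuisance = matrix(0, 0, 2), mode = "amplitude")
  expect_equal(predictTestResponses(fitI, diag(2)), diag(2), ignore_attr = TRUE)
})

test_that("Spearman evaluation matches the rank-then-Pearson oracle and flags constants", {
  set.seed(11)
  pred <- matrix(rnorm(20 * 6), 20, 6)
  obs <- matrix(rnorm(20 * 6), 20, 6)
  res <- evaluateEncoding(pred, obs)
  oracle <- vapply(1:6, function(j) cor(rank(pred[, j]), rank(obs[, j])),
                   numeric(1))
  expect_equal(perVoxelR(res), oracle, tolerance = 1e-12)
  expect_true(all(perVoxelR(res) >= -1 & perVoxelR(res) <= 1))

  expect_equal(perVoxelR(evaluateEncoding(obs, obs)), rep(1, 6))
  rev <- apply(obs, 2, function(col) -col)
  expect_equal(perVoxelR(evaluateEncoding(rev, obs)), rep(-1, 6))

  predC <- pred; predC[, 2] <- 5
  resC <- evaluateEncoding(predC, obs)
  expect_equal(perVoxelR(resC)[2], 0)
  expect_true(resC@constant[2])

  roiM <- roiMeans(evaluateEncoding(pred, obs,
                                    roi = list(a = 1:3, b = 4:6)))
  expect_equal(roiM[["a"]], mean(oracle[1:3]))
})

test_that("amplitude fit on averaged data agrees with hrf fit on matched noiseless series", {
  truth <- makeGroundTruth(4, 8, noiseSd = 0, seed = 12)
  X <- randMatrix(40, 4, 13); Xt <- randMatrix(5, 4, 14)
  fve <- simulateVoxelResponses(X, Xt, truth, repeats = 2, seed = 15)
  dA <- buildDesign(X, testIds = rownames(testResponses(fve)))
  fitA <- fitEncodingGlm(dA, rbind(trainResponses(fve), testResponses(fve)))

  ss <- simulateTimeseries(X, Xt, truth, TR = 2, testRepeats = 2, seed = 16)
  rownames(X) <- sprintf("train_%04d", 1:40)
  dH <- buildDesign(X, testIds = sprintf("test_%02d", 1:5), mode = "hrf",
                    events = ss@events, TR = 2, runIndex = ss@runIndex,
                    motion = ss@motion)
  fitH <- fitEncodingGlm(dH, ss@series)
  expect_lt(max(abs(encodingWeights(fitA) - encodingWeights(fitH))), 1e-4)
})

test_that("W recovery improves with SNR and is near-perfect at SNR 10", {
  medCor <- vapply(c(0.5, 2, 10), function(snr) {
    truth <- makeGroundTruth(8, 50, seed = 17)
    X <- randMatrix(500, 8, 18); Xt <- randMatrix(20, 8, 19)
    truth <- setNoiseSd(truth, noiseSdForSnr(truth, X, snr))
    fve <- simulateVoxelResponses(X, Xt, truth, repeats = 2, seed = 20)
    d <- buildDesign(X, testIds = rownames(testResponses(fve)))
    fit <- fitEncodingGlm(d, rbind(trainResponses(fve), testResponses(fve)))
    median(vapply(1:50, function(v) {
      cor(encodingWeights(fit)[, v], encodingWeights(truth)[, v])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(medCor) > 0))
  expect_gt(medCor[3], 0.95)
})
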