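# Pseudo-inverse decoding and pairwise identity accuracy.

makeFit2 <- function(W, b = rep(0, ncol(W))) {
  new("EncodingFit", W = W, b = b, nuisance = matrix(0, 0, ncol(W)),
      mode = "amplitude")
}

test_that("pseudo-inverse decoding inverts noiseless responses", {
  set.seed(51)
  W <- matrix(rnorm(4 * 10), 4, 10)
  b <- rnorm(10)
  x <- randMatrix(20, 4, 52)
  y <- x %*% W + rep(b, each = 20)
  xh <- decodeLatents(makeFit2(W, b), y)
  expect_lt(max(abs(xh - x)), 1e-8)
  # square invertible W: pinv equals the inverse
  Ws <- matrix(rnorm(16), 4, 4)
  expect_lt(max(abs(MASS::ginv(Ws) - solve(Ws))), 1e-10)
  # per-row least-squares oracle
  oracle <- t(qr.solve(t(W), t(y - rep(b, each = 20))))
  expect_equal(xh, oracle, tolerance = 1e-8)
  expect_warning(decodeLatents(makeFit2(matrix(rnorm(8), 4, 2), rep(0, 2)),
                               matrix(rnorm(4), 2, 2)),
                 "underdetermined")
})

test_that("the standard 20-image test set yields 380 comparisons and exact decoding scores 1", {
  x <- randMatrix(20, 6, 53)
  res <- pairwiseIdentityAccuracy(x, x)
  expect_identical(nComparisons(res), 380L)
  expect_equal(accuracy(res), 1)
  expect_error(pairwiseIdentityAccuracy(x, x, subset = 1), "at least 2")
  expect_error(pairwiseIdentityAccuracy(x, x, subset = c(1, 99)), "invalid")
})

test_that("identical target and foil true vectors tie at exactly 0.5", {
  x <- randMatrix(20, 4, 54)
  xTrue <- matrix(rep(rnorm(4), each = 20), 20, 4)   # one shared identity vector
  res <- pairwiseIdentityAccuracy(x, xTrue)
  expect_equal(accuracy(res), 0.5)
})

test_that("constant subset vectors are skipped with a warning", {
  x <- randMatrix(20, 4, 55)
  xTrue <- randMatrix(20, 4, 56)
  xC <- x; xC[3, ] <- 7   # constant decoded row
  expect_warning(res <- pairwiseIdentityAccuracy(xC, xTrue), "skipped")
  expect_identical(nComparisons(res), 380L - 19L)
})

test_that("subset battery reduces to the plain call and orders accuracy by information", {
  set.seed(57)
  truth <- makeGroundTruth(8, 60, seed = 58)
  X <- randMatrix(200, 8, 59)
  truth <- setNoiseSd(truth, noiseSdForSnr(truth, X, 1))
  spec <- defaultFactorSpec()
  rel <- which(spec$identityRelevant)
  irr <- which(!spec$identityRelevant)
  Xt <- sampleTestFactors(spec, seed = 60, testIrrelevantScale = 0.2)
  fve <- simulateVoxelResponses(X, Xt, truth, repeats = 10, seed = 61)
  d <- buildDesign(X, testIds = rownames(testResponses(fve)))
  fit <- fitEncodingGlm(d, rbind(trainResponses(fve), testResponses(fve)))
  xh <- decodeLatents(fit, testResponses(fve))
  bat <- subsetBattery(xh, Xt, list(all = 1:8, relevant = rel, irrelevant = irr))
  solo <- pairwiseIdentityAccuracy(xh, Xt)
  expect_equal(accuracy(bat$all), accuracy(solo))
  expect_gt(accuracy(bat$relevant), accuracy(bat$irrelevant))
  expect_error(subsetBattery(xh, Xt, list(bad = integer())), "empty subset")
})

test_that("subset accuracy is invariant to dimension order within the subset", {
  xh <- randMatrix(20, 6, 62)
  xt <- randMatrix(20, 6, 63)
  a <- pairwiseIdentityAccuracy(xh, xt, subset = c(1, 3, 5))
  b <- pairwiseIdentityAccuracy(xh, xt, subset = c(5, 1, 3))
  expect_equal(accuracy(a), accuracy(b))
})

test_that("added entangled dimensions carrying no extra identity variance change little", {
  set.seed(64)
  xt <- randMatrix(20, 4, 65)
  mix <- matrix(rnorm(16), 4, 4)
  xtFull <- cbind(xt, xt %*% mix)        # entangled dims are mixtures
  accs <- vapply(1:50, function(i) {
    set.seed(i + 700)
    # the decoded entangled dims are the same mixtures of the decoded
    # relevant dims, so by construction they add no identity information
    noisyRel <- xt + matrix(rnorm(20 * 4, sd = 0.4), 20, 4)
    noisy <- cbind(noisyRel, noisyRel %*% mix)
    relA <- accuracy(pairwiseIdentityAccuracy(noisy, xtFull, subset = 1:4))
    bothA <- accuracy(pairwiseIdentityAccuracy(noisy, xtFull, subset = 1:8))
    bothA - relA
  }, numeric(1))
  expect_lt(abs(mean(accs)), 0.05)
})

test_that("decoding accuracy is monotone non-decreasing in SNR", {
  spec <- defaultFactorSpec()
  accs <- vapply(c(0.25, 1, 4), function(snr) {
    truth <- makeGroundTruth(8, 50, seed = 66)
    X <- randMatrix(150, 8, 67)
    truth <- setNoiseSd(truth, noiseSdForSnr(truth, X, snr))
    Xt <- sampleTestFactors(spec, seed = 68)
    fve <- simulateVoxelResponses(X, Xt, truth, repeats = 5, seed = 69)
    d <- buildDesign(X, testIds = rownames(testResponses(fve)))
    fit <- fitEncodingGlm(d, rbind(trainResponses(fve), testResponses(fve)))
    accuracy(pairwiseIdentityAccuracy(decodeLatents(fit, testResponses(fve)), Xt))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("restricted-pinv mode decodes each subset with its own weights", {
  set.seed(70)
  W <- matrix(rnorm(6 * 30), 6, 30)
  x <- randMatrix(20, 6, 71)
  # only the subset's dimensions drive the responses, so the restricted
  # pseudo-inverse recovers them exactly
  y <- x[, 1:3] %*% W[1:3, ]
  fit <- makeFit2(W)
  bat <- subsetBattery(NULL, x, list(half = 1:3), restrictedPinv = TRUE,
                       fit = fit, y = y)
  expect_match(bat$half@subsetName, "restricted pinv")
  expect_equal(accuracy(bat$half), 1)
})
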