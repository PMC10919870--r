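# VAE objectives, training behaviour, traversals, the hyperparameter grid,
# and the supervised disentanglement gap score.

test_that("closed-form KL matches its defining examples and is non-negative", {
  expect_equal(klToPrior(rep(0, 4), rep(0, 4)), 0)
  expect_equal(klToPrior(c(1, 0, 0), rep(0, 3)), 0.5)
  set.seed(1)
  mus <- matrix(rnorm(200 * 6), 200, 6)
  lvs <- matrix(rnorm(200 * 6), 200, 6)
  expect_true(all(klToPrior(mus, lvs) >= 0))
})

test_that("analytic gradients match numeric differentiation on a tiny network", {
  set.seed(3)
  p <- 9L; k <- 3L
  params <- LatentFaces:::.initParams(p, 5L, 4L, k)
  # perturb the zero-initialized heads so all paths carry gradient
  params$Wm <- matrix(rnorm(4 * k, sd = 0.3), 4, k)
  params$Wv <- matrix(rnorm(4 * k, sd = 0.3), 4, k)
  X <- matrix(runif(2 * p), 2, p)
  eps <- matrix(rnorm(2 * k), 2, k)
  lossAt <- function(pr) {
    enc <- LatentFaces:::.encoderForward(pr, X)
    Z <- enc$MU + exp(0.5 * enc$LV) * eps
    dec <- LatentFaces:::.decoderForward(pr, Z)
    LatentFaces:::.reconLoss(dec$L, X) + 2 * LatentFaces:::.klLoss(enc$MU, enc$LV)
  }
  bw <- LatentFaces:::.vaeBackward(params, X, eps, klWeight = 2, gamma = 0)
  for (nm in c("W1", "Wm", "Wv", "U1", "U3", "b1", "c3")) {
    g <- bw$grads[[nm]]
    idx <- seq_len(min(4, length(g)))
    for (i in idx) {
      h <- 1e-5
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("a gamma = 0 FactorVAE objective equals the beta = 1 beta-VAE objective", {
  ds <- ciFaceSet()
  imgs <- imagesToMatrix(trainImages(ds))
  cfgF <- vaeConfig("factor_vae", latentDim = 6, gamma = 0, seed = 2,
                    epochs = 2, batchSize = 24, hidden = c(32L, 16L), side = 32)
  cfgB <- vaeConfig("beta_vae", latentDim = 6, beta = 1, seed = 2,
                    epochs = 2, batchSize = 24, hidden = c(32L, 16L), side = 32)
  expect_true(cfgF$standardVae && cfgB$standardVae)
  mF <- trainVae(imgs, cfgF)
  mB <- trainVae(imgs, cfgB)
  lF <- vaeLossTerms(mF, imgs[1:24, ])
  lB <- vaeLossTerms(mB, imgs[1:24, ])
  expect_equal(lF$objective, lB$objective, tolerance = 1e-6)
  # same seed and identical update rules: identical training logs
  expect_equal(trainingLog(mF), trainingLog(mB), tolerance = 1e-10)
})

test_that("training is reproducible under the seed and logs one record per epoch", {
  ds <- ciFaceSet()
  imgs <- imagesToMatrix(trainImages(ds))[1:80, ]
  cfg <- vaeConfig("factor_vae", latentDim = 4, gamma = 5, seed = 9,
                   epochs = 3, batchSize = 16, hidden = c(32L, 16L), side = 32)
  m1 <- trainVae(imgs, cfg)
  m2 <- trainVae(imgs, cfg)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@params, m2@params)
  expect_identical(nrow(trainingLog(m1)), 3L)
})

test_that("trained CI model reconstructs held-out faces better than the mean image", {
  ds <- ciFaceSet()
  m <- ciModel()
  log <- trainingLog(m)
  expect_lt(log$heldoutReconstruction[nrow(log)], log$heldoutReconstruction[1])

  te <- imagesToMatrix(testImages(ds))
  meanImg <- colMeans(imagesToMatrix(trainImages(ds)))
  recon <- t(vapply(seq_len(nrow(te)), function(i) {
    as.numeric(decodeLatentVector(m, encodeImage(m, te[i, ])$mean))
  }, numeric(ncol(te))))
  mseModel <- mean((recon - te)^2)
  mseMean <- mean(sweep(te, 2, meanImg)^2)
  expect_lt(mseModel, mseMean)
})

test_that("encoding is deterministic and an untrained model emits zero posterior means", {
  ds <- ciFaceSet()
  m <- ciModel()
  img <- testImages(ds)[1, , ]
  e1 <- encodeImage(m, img); e2 <- encodeImage(m, img)
  expect_identical(e1, e2)
  L <- extractLatents(m, testImages(ds))
  expect_identical(dim(L), c(20L, 6L))

  set.seed(5)
  raw <- LatentFaces:::.initParams(16, 8, 6, 3)
  untrained <- new("VaeModel", params = raw, discriminator = list(),
                   config = unclass(vaeConfig(latentDim = 3, side = 4)),
                   trainingLog = data.frame())
  e <- encodeImage(untrained, matrix(runif(16), 4, 4))
  expect_identical(e$mean, rep(0, 3))
  expect_identical(e$logVar, rep(0, 3))
})

test_that("latent traversals hold other dimensions fixed and honour the -2..2 default", {
  ds <- ciFaceSet()
  m <- ciModel()
  img <- testImages(ds)[2, , ]
  fr <- latentTraversal(m, img, dim = 1, steps = 5)
  expect_length(fr, 5L)
  expect_equal(eval(formals(latentTraversal)$lo), -2)
  expect_equal(eval(formals(latentTraversal)$hi), 2)
  z <- encodeImage(m, img)$mean
  one <- latentTraversal(m, img, dim = 1, lo = z[1], hi = z[1], steps = 1)
  expect_equal(one[[1]], decodeLatentVector(m, z))

  # zero decoder weights for a dimension -> constant traversal
  m2 <- m
  m2@params$U1[3, ] <- 0
  fr2 <- latentTraversal(m2, img, dim = 3, steps = 4)
  for (i in 2:4) expect_identical(fr2[[i]], fr2[[1]])

  paths <- writeTraversalFrames(m, img, dim = 1, dir = tempfile("trav"), steps = 3)
  expect_true(all(file.exists(paths)))
})

test_that("the reference hyperparameter grid enumerates 240 + 240 configs with gamma 0 aliased", {
  grid <- hyperparameterGrid()
  tab <- attr(grid, "gridTable")
  expect_identical(sum(tab$family == "factor_vae"), 240L)
  expect_identical(sum(tab$family == "beta_vae"), 240L)
  expect_identical(length(grid), 480L)
  # gamma = 0 cells are not present as separate factor_vae configs
  expect_identical(sum(tab$family == "factor_vae" & tab$gamma == 0), 0L)
  expect_true(attr(grid, "gammaZeroAliased"))
  small <- hyperparameterGrid(latentDims = 8L, betas = numeric(), gammas = 10,
                              seeds = 1L)
  expect_length(small, 1L)
})

test_that("gap score is 1 on factorially permuted latents, 0 on symmetric mixing", {
  F <- factorialFactors()
  perm <- F[, c(3, 1, 4, 2)]
  expect_equal(disentanglementScore(perm, F)$score, 1)
  # sign flips and permutations leave the score unchanged
  flipped <- perm %*% diag(c(-1, 1, -1, 1))
  expect_equal(disentanglementScore(flipped, F)$score, 1)
  L <- matrix(rowSums(F), nrow(F), 4)
  expect_warning(sc <- disentanglementScore(cbind(L[, 1:3], 0 * L[, 4]), F),
                 "constant")
  expect_equal(disentanglementScore(L, F)$score, 0)
})

test_that("gap score degrades under random rotation and strict mixing of aligned latents", {
  scores <- vapply(1:20, function(i) {
    set.seed(i)
    F <- matrix(runif(2000 * 8, -1, 1), 2000, 8)
    R <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
    disentanglementScore(F %*% R, F)$score
  }, numeric(1))
  expect_lt(mean(scores), 0.3)

  set.seed(30)
  F <- matrix(runif(2000 * 4, -1, 1), 2000, 4)
  aligned <- disentanglementScore(F, F)$score
  mixed <- F
  mixed[, 2] <- F[, 1] + F[, 2]
  expect_lt(disentanglementScore(mixed, F)$score, aligned)
})

test_that("model selection is the score argmax with deterministic tie-breaking", {
  c24 <- vaeConfig(latentDim = 24, seed = 2)
  c48 <- vaeConfig(latentDim = 48, seed = 1)
  c8 <- vaeConfig(latentDim = 8, seed = 3)
  res <- list(list(config = c48, score = 0.5),
              list(config = c24, score = 0.5),
              list(config = c8, score = 0.2))
  expect_identical(selectModel(res)$latentDim, 24L)
  expect_identical(selectModel(res[3])$latentDim, 8L)
  expect_error(selectModel(list()), "no scored")
  tie <- list(list(config = vaeConfig(latentDim = 24, seed = 5), score = 0.4),
              list(config = vaeConfig(latentDim = 24, seed = 2), score = 0.4))
  expect_identical(selectModel(tie)$seed, 2L)
})

test_that("divergent training aborts with a diagnostic", {
  ds <- ciFaceSet()
  imgs <- imagesToMatrix(trainImages(ds))[1:60, ]
  cfg <- vaeConfig("beta_vae", latentDim = 4, beta = 1, seed = 1, epochs = 3,
                   batchSize = 16, hidden = c(32L, 16L), side = 32,
                   learningRate = 1e3)
  expect_error(trainVae(imgs, cfg), "diverged")
})
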