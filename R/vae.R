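# Desk-scale disentangled variational autoencoder. A fully connected
# encoder/decoder pair trained by manual backpropagation with Adam:
# Bernoulli (BCE-with-logits) reconstruction, closed-form Gaussian KL to the
# standard-normal prior, and — for the FactorVAE family — a total-correlation
# penalty estimated by a small discriminator via the density-ratio trick on
# dimension-permuted latent batches.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' VAE model configuration
#'
#' @param family `"beta_vae"` or `"factor_vae"`. A factor_vae with gamma = 0
#'   is the same model as a beta_vae with beta = 1 (a standard VAE); the
#'   returned config records this equivalence in `standardVae`.
#' @param latentDim Number of latent dimensions (>= 2).
#' @param beta KL weight (>= 1; used by the beta_vae objective).
#' @param gamma Total-correlation weight (>= 0; used by the factor_vae
#'   objective, whose KL weight is 1).
#' @param seed Integer training seed.
#' @param epochs,batchSize,learningRate Training controls.
#' @param hidden Integer vector of the two hidden-layer widths.
#' @param side Image side length the model expects.
#' @param discHidden,discLearningRate Discriminator controls (factor_vae).
#' @return A named list of class `vaeConfig`.
#' @examples
#' cfg <- vaeConfig("factor_vae", latentDim = 8, gamma = 10)
#' cfg$standardVae
#' @export
vaeConfig <- function(family = c("beta_vae", "factor_vae"), latentDim = 8L,
                      beta = 1, gamma = 0, seed = 1L, epochs = 15L,
                      batchSize = 32L, learningRate = 3e-3,
                      hidden = c(128L, 64L), side = 32L,
                      discHidden = 64L, discLearningRate = 1e-3) {
  family <- match.arg(family)
  if (latentDim < 2L) stop("latentDim must be at least 2")
  if (beta < 1) stop("beta must be >= 1")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(
    family = family, latentDim = as.integer(latentDim), beta = beta,
    gamma = gamma, seed = as.integer(seed), epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), learningRate = learningRate,
    hidden = as.integer(hidden), side = as.integer(side),
    discHidden = as.integer(discHidden), discLearningRate = discLearningRate,
    standardVae = (family == "beta_vae" && beta == 1) ||
      (family == "factor_vae" && gamma == 0)
  ), class = "vaeConfig")
}

.initParams <- function(p, h1, h2, k) {
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(
    W1 = he(p, h1), b1 = numeric(h1),
    W2 = he(h1, h2), b2 = numeric(h2),
    # encoder heads start at zero: an untrained model emits all-zero
    # posterior means with unit variance
    Wm = matrix(0, h2, k), bm = numeric(k),
    Wv = matrix(0, h2, k), bv = numeric(k),
    U1 = he(k, h2), c1 = numeric(h2),
    U2 = he(h2, h1), c2 = numeric(h1),
    U3 = he(h1, p), c3 = numeric(p)
  )
}

.initDisc <- function(k, hd) {
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  list(V1 = he(k, hd), a1 = numeric(hd),
       V2 = he(hd, hd), a2 = numeric(hd),
       v3 = he(hd, 1L), a3 = numeric(1L))
}

.addRow <- function(M, v) sweep(M, 2, v, "+")

.encoderForward <- function(params, X) {
  A1 <- .addRow(X %*% params$W1, params$b1); H1 <- relu(A1)
  A2 <- .addRow(H1 %*% params$W2, params$b2); H2 <- relu(A2)
  list(A1 = A1, H1 = H1, A2 = A2, H2 = H2,
       MU = .addRow(H2 %*% params$Wm, params$bm),
       LV = .addRow(H2 %*% params$Wv, params$bv))
}

.decoderForward <- function(params, Z) {
  D1p <- .addRow(Z %*% params$U1, params$c1); D1 <- relu(D1p)
  D2p <- .addRow(D1 %*% params$U2, params$c2); D2 <- relu(D2p)
  list(D1p = D1p, D1 = D1, D2p = D2p, D2 = D2,
       L = .addRow(D2 %*% params$U3, params$c3))
}

.discForward <- function(disc, Z) {
  P1p <- .addRow(Z %*% disc$V1, disc$a1); P1 <- relu(P1p)
  P2p <- .addRow(P1 %*% disc$V2, disc$a2); P2 <- relu(P2p)
  list(P1p = P1p, P1 = P1, P2p = P2p, P2 = P2,
       T = as.numeric(P2 %*% disc$v3 + disc$a3[1]))
}

.reconLoss <- function(L, X) mean(rowSums(softplus(L) - X * L))
.klLoss <- function(MU, LV) mean(rowSums(0.5 * (MU^2 + exp(LV) - 1 - LV)))

# Gradient of mean(T) with respect to Z, discriminator frozen.
.discGradZ <- function(disc, fw, B) {
  dP2 <- matrix(disc$v3, B, length(disc$v3), byrow = TRUE) / B
  dP2p <- dP2 * (fw$P2p > 0)
  dP1 <- dP2p %*% t(disc$V2)
  dP1p <- dP1 * (fw$P1p > 0)
  dP1p %*% t(disc$V1)
}

# Full VAE gradient for one batch. Returns losses and parameter gradients.
# klWeight is beta for the beta_vae family and 1 for factor_vae.
.vaeBackward <- function(params, X, eps, klWeight, gamma, disc = NULL) {
  B <- nrow(X)
  enc <- .encoderForward(params, X)
  SD <- exp(0.5 * enc$LV)
  Z <- enc$MU + SD * eps
  dec <- .decoderForward(params, Z)

  recon <- .reconLoss(dec$L, X)
  kl <- .klLoss(enc$MU, enc$LV)
  tc <- 0
  dZtc <- 0
  if (!is.null(disc) && gamma > 0) {
    fw <- .discForward(disc, Z)
    tc <- mean(fw$T)
    dZtc <- gamma * .discGradZ(disc, fw, B)
  }

  dL <- (sigmoid(dec$L) - X) / B
  g <- list()
  g$U3 <- crossprod(dec$D2, dL); g$c3 <- colSums(dL)
  dD2 <- dL %*% t(params$U3)
  dD2p <- dD2 * (dec$D2p > 0)
  g$U2 <- crossprod(dec$D1, dD2p); g$c2 <- colSums(dD2p)
  dD1 <- dD2p %*% t(params$U2)
  dD1p <- dD1 * (dec$D1p > 0)
  g$U1 <- crossprod(Z, dD1p); g$c1 <- colSums(dD1p)
  dZ <- dD1p %*% t(params$U1) + dZtc

  dMU <- dZ + klWeight * enc$MU / B
  dLV <- dZ * eps * 0.5 * SD + klWeight * 0.5 * (exp(enc$LV) - 1) / B

  g$Wm <- crossprod(enc$H2, dMU); g$bm <- colSums(dMU)
  g$Wv <- crossprod(enc$H2, dLV); g$bv <- colSums(dLV)
  dH2 <- dMU %*% t(params$Wm) + dLV %*% t(params$Wv)
  dA2 <- dH2 * (enc$A2 > 0)
  g$W2 <- crossprod(enc$H1, dA2); g$b2 <- colSums(dA2)
  dH1 <- dA2 %*% t(params$W2)
  dA1 <- dH1 * (enc$A1 > 0)
  g$W1 <- crossprod(X, dA1); g$b1 <- colSums(dA1)

  list(recon = recon, kl = kl, tc = tc, grads = g, Z = Z)
}

# Discriminator gradient: cross-entropy real (joint) vs permuted (product of
# marginals) latent batches.
.discBackward <- function(disc, Zreal, Zperm) {
  B <- nrow(Zreal)
  fr <- .discForward(disc, Zreal)
  fp <- .discForward(disc, Zperm)
  loss <- mean(softplus(-fr$T)) + mean(softplus(fp$T))
  g <- list(V1 = 0, a1 = 0, V2 = 0, a2 = 0, v3 = 0, a3 = 0)
  acc <- function(fw, Z, dT) {
    dP2 <- outer(dT, as.numeric(disc$v3))
    g$v3 <<- g$v3 + crossprod(fw$P2, matrix(dT)); g$a3 <<- g$a3 + sum(dT)
    dP2p <- dP2 * (fw$P2p > 0)
    g$V2 <<- g$V2 + crossprod(fw$P1, dP2p); g$a2 <<- g$a2 + colSums(dP2p)
    dP1 <- dP2p %*% t(disc$V2)
    dP1p <- dP1 * (fw$P1p > 0)
    g$V1 <<- g$V1 + crossprod(Z, dP1p); g$a1 <<- g$a1 + colSums(dP1p)
  }
  acc(fr, Zreal, -sigmoid(-fr$T) / B)
  acc(fp, Zperm, sigmoid(fp$T) / B)
  list(loss = loss, grads = g)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

.asPixelMatrix <- function(images, side = NULL) {
  if (is.matrix(images)) return(images)
  if (length(dim(images)) == 3L) return(imagesToMatrix(images))
  stop("images must be an n x pixels matrix or an n x side x side array")
}

#' Train a beta-VAE or FactorVAE
#'
#' Minibatch Adam with manual backpropagation. The beta_vae objective is
#' reconstruction + beta * KL; the factor_vae objective is
#' reconstruction + KL + gamma * TC, with the total correlation TC estimated
#' by a discriminator trained alongside on dimension-permuted latent batches.
#' A held-out split (10%) tracks reconstruction error per epoch. Training is
#' fully reproducible under the config seed; a non-finite loss aborts with a
#' diagnostic.
#'
#' @param images n x pixels matrix or n x side x side array with values in
#'   [0, 1].
#' @param config A [vaeConfig()].
#' @return A \linkS4class{VaeModel}.
#' @export
trainVae <- function(images, config) {
  stopifnot(inherits(config, "vaeConfig"))
  X <- .asPixelMatrix(images)
  if (min(X) < 0 || max(X) > 1) stop("pixel values must lie in [0, 1]")
  p <- ncol(X)
  if (p != config$side^2) {
    stop("image pixel count ", p, " does not match config side ", config$side)
  }
  n <- nrow(X)
  if (n < config$batchSize) stop("need at least one full batch of images")
  k <- config$latentDim
  useDisc <- config$family == "factor_vae" && config$gamma > 0

  withSeed(config$seed, {
    params <- .initParams(p, config$hidden[1], config$hidden[2], k)
    disc <- if (useDisc) .initDisc(k, config$discHidden) else list()
    st <- .adamInit(params)
    stD <- if (useDisc) .adamInit(disc) else NULL

    nHold <- max(1L, round(0.1 * n))
    holdIdx <- sample(n, nHold)
    Xh <- X[holdIdx, , drop = FALSE]
    Xt <- X[-holdIdx, , drop = FALSE]
    nt <- nrow(Xt)

    log <- data.frame(epoch = seq_len(config$epochs), reconstruction = NA_real_,
                      kl = NA_real_, tc = NA_real_,
                      heldoutReconstruction = NA_real_)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nt)
      starts <- seq(1L, nt - config$batchSize + 1L, by = config$batchSize)
      epRec <- epKl <- epTc <- 0
      for (s in starts) {
        idx <- ord[s:(s + config$batchSize - 1L)]
        Xb <- Xt[idx, , drop = FALSE]
        eps <- matrix(rnorm(config$batchSize * k), config$batchSize, k)
        bw <- .vaeBackward(params, Xb, eps,
                           klWeight = if (config$family == "beta_vae") config$beta else 1,
                           gamma = config$gamma,
                           disc = if (useDisc) disc else NULL)
        if (!is.finite(bw$recon) || !is.finite(bw$kl)) {
          stop(sprintf("training diverged at epoch %d (recon = %g, kl = %g); lower the learning rate",
                       ep, bw$recon, bw$kl))
        }
        upd <- .adamStep(params, bw$grads, st, config$learningRate)
        params <- upd$params; st <- upd$state
        if (useDisc) {
          Zperm <- apply(bw$Z, 2, sample)
          dbw <- .discBackward(disc, bw$Z, Zperm)
          updD <- .adamStep(disc, dbw$grads, stD, config$discLearningRate)
          disc <- updD$params; stD <- updD$state
        }
        epRec <- epRec + bw$recon; epKl <- epKl + bw$kl; epTc <- epTc + bw$tc
      }
      nb <- length(starts)
      enc <- .encoderForward(params, Xh)
      dec <- .decoderForward(params, enc$MU)
      log[ep, -1] <- c(epRec / nb, epKl / nb, epTc / nb, .reconLoss(dec$L, Xh))
    }
    new("VaeModel", params = params, discriminator = disc,
        config = unclass(config), trainingLog = log)
  })
}

#' Loss terms of a model on a batch
#'
#' Reconstruction (Bernoulli BCE), KL to the prior (closed form, always
#' >= 0), the discriminator total-correlation estimate (NA when no
#' discriminator exists), and the family objective: reconstruction +
#' beta * KL for beta_vae, reconstruction + KL + gamma * TC for factor_vae.
#' With `sampleSeed = NULL` the latent is the posterior mean (deterministic);
#' give a seed to use a reparameterized sample.
#'
#' @param model A \linkS4class{VaeModel}.
#' @param images Batch of images (matrix or array).
#' @param sampleSeed Optional seed for latent sampling.
#' @return List with `reconstruction`, `kl`, `tc`, `objective`.
#' @export
vaeLossTerms <- function(model, images, sampleSeed = NULL) {
  X <- .asPixelMatrix(images)
  if (nrow(X) < 1L) stop("batch must be nonempty")
  cfg <- modelConfig(model)
  enc <- .encoderForward(model@params, X)
  Z <- if (is.null(sampleSeed)) enc$MU else {
    withSeed(sampleSeed,
             enc$MU + exp(0.5 * enc$LV) * matrix(rnorm(length(enc$MU)), nrow(enc$MU)))
  }
  dec <- .decoderForward(model@params, Z)
  recon <- .reconLoss(dec$L, X)
  kl <- .klLoss(enc$MU, enc$LV)
  tc <- if (length(model@discriminator)) mean(.discForward(model@discriminator, Z)$T) else NA_real_
  obj <- if (cfg$family == "beta_vae") {
    recon + cfg$beta * kl
  } else {
    recon + kl + if (cfg$gamma > 0) cfg$gamma * tc else 0
  }
  list(reconstruction = recon, kl = kl, tc = tc, objective = obj)
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Closed form 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2); non-negative for
#' every posterior.
#'
#' @param mean,logVar Numeric vectors (or matrices, row = posterior).
#' @return Numeric KL value(s), summed over dimensions.
#' @export
klToPrior <- function(mean, logVar) {
  if (is.matrix(mean)) rowSums(0.5 * (mean^2 + exp(logVar) - 1 - logVar))
  else sum(0.5 * (mean^2 + exp(logVar) - 1 - logVar))
}

#' Encode an image to its latent posterior
#'
#' @param model A \linkS4class{VaeModel}.
#' @param image side x side matrix or pixel vector.
#' @return List with `mean` and `logVar` vectors.
#' @export
encodeImage <- function(model, image) {
  x <- matrix(as.numeric(image), 1L)
  if (ncol(x) != modelConfig(model)$side^2) stop("image size does not match the model")
  enc <- .encoderForward(model@params, x)
  list(mean = as.numeric(enc$MU), logVar = as.numeric(enc$LV))
}

#' Extract the latent matrix (posterior means) for a set of images
#'
#' @param model A \linkS4class{VaeModel}.
#' @param images Matrix or array of images.
#' @param ids Optional stimulus ids used as rownames.
#' @return Stimulus x latentDim matrix of posterior means.
#' @export
extractLatents <- function(model, images, ids = NULL) {
  X <- .asPixelMatrix(images)
  enc <- .encoderForward(model@params, X)
  out <- enc$MU
  rownames(out) <- ids
  out
}

#' Decode a latent vector to an image
#'
#' @param model A \linkS4class{VaeModel}.
#' @param z Numeric latent vector.
#' @return side x side image matrix in [0, 1].
#' @export
decodeLatentVector <- function(model, z) {
  dec <- .decoderForward(model@params, matrix(z, 1L))
  vectorToImage(sigmoid(as.numeric(dec$L)), modelConfig(model)$side)
}

#' Latent traversal of one dimension
#'
#' Encodes the image, holds all latent values at the posterior mean, sweeps
#' dimension `dim` from `lo` to `hi` in `steps` equal steps, and decodes each
#' interpolated vector.
#'
#' @param model A \linkS4class{VaeModel}.
#' @param image Image to traverse around.
#' @param dim Latent dimension index.
#' @param lo,hi Traversal range (default -2 to +2).
#' @param steps Number of frames.
#' @return List of side x side image matrices.
#' @export
latentTraversal <- function(model, image, dim, lo = -2, hi = 2, steps = 9L) {
  k <- modelConfig(model)$latentDim
  if (dim < 1 || dim > k) stop("invalid latent dimension")
  z <- encodeImage(model, image)$mean
  vals <- if (steps == 1L) lo else seq(lo, hi, length.out = steps)
  lapply(vals, function(v) {
    zz <- z; zz[dim] <- v
    decodeLatentVector(model, zz)
  })
}

#' Write traversal frames and a montage to disk
#'
#' Exports each traversal frame as a PNG plus a single horizontal montage
#' image for quick inspection.
#'
#' @inheritParams latentTraversal
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
writeTraversalFrames <- function(model, image, dim, dir, lo = -2, hi = 2,
                                 steps = 9L) {
  frames <- latentTraversal(model, image, dim, lo, hi, steps)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(frames)) {
    f <- file.path(dir, sprintf("dim%02d_frame%02d.png", dim, i))
    png::writePNG(frames[[i]], f)
    paths <- c(paths, f)
  }
  montage <- do.call(cbind, frames)
  mf <- file.path(dir, sprintf("dim%02d_montage.png", dim))
  png::writePNG(montage, mf)
  invisible(c(paths, mf))
}
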