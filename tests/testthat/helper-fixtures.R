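# Shared fixtures, built once per test run. The trained model is the
# expensive one; it is cached so the unit tests and the acceptance checks
# reuse a single training run.

.fixtures <- new.env(parent = emptyenv())

ciFaceSet <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- sampleFaceDataset(nTrain = 200, side = 32, seed = 101)
  }
  .fixtures$ds
}

ciModelConfig <- function(...) {
  vaeConfig("factor_vae", latentDim = 6, gamma = 10, seed = 1, epochs = 30,
            batchSize = 24, hidden = c(64L, 32L), side = 32, ...)
}

ciModel <- function() {
  if (is.null(.fixtures$model)) {
    ds <- ciFaceSet()
    .fixtures$model <- trainVae(imagesToMatrix(trainImages(ds)), ciModelConfig())
  }
  .fixtures$model
}

randMatrix <- function(n, k, seed) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k)
}

# Balanced full-factorial factor table: sample cross-correlations between
# midranks of different columns are exactly zero by symmetry.
factorialFactors <- function(levels = 4L, nFactors = 4L) {
  lv <- seq(-1, 1, length.out = levels)
  as.matrix(do.call(expand.grid, rep(list(lv), nFactors)))
}
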