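# Hyperparameter grid and disentanglement-based model selection. Because the
# synthetic generative factors are known, selection uses a supervised gap
# score on the |Spearman| importance matrix between latents and factors
# rather than an unsupervised metric.

#' Enumerate the hyperparameter grid
#'
#' Full cross-product of families x latent sizes x disentanglement values x
#' seeds. The gamma = 0 FactorVAE cell is the same model as a beta = 1
#' beta-VAE and is aliased to it rather than duplicated: those cells appear
#' once, as beta-VAE configs. With the reference grid (4 latent sizes,
#' beta in {1, 2, 4, 6, 8, 16}, gamma in {0, 10, 20, 30, 40, 50, 100},
#' 10 seeds) this enumerates 240 FactorVAE and 240 beta-VAE configurations.
#'
#' @param latentDims Integer vector of latent sizes.
#' @param betas Numeric beta values for the beta-VAE family.
#' @param gammas Numeric gamma values for the FactorVAE family (0 allowed;
#'   aliased).
#' @param seeds Integer vector of initialization seeds.
#' @param ... Further arguments passed to [vaeConfig()] (epochs, side, ...).
#' @return List of `vaeConfig` objects with a `gridTable` attribute
#'   (data.frame of family, latentDim, beta, gamma, seed).
#' @examples
#' g <- hyperparameterGrid(latentDims = 8, gammas = 10, seeds = 1)
#' length(g)
#' @export
hyperparameterGrid <- function(latentDims = c(24L, 32L, 48L, 64L),
                               betas = c(1, 2, 4, 6, 8, 16),
                               gammas = c(0, 10, 20, 30, 40, 50, 100),
                               seeds = 1:10, ...) {
  configs <- list()
  tab <- data.frame(family = character(), latentDim = integer(),
                    beta = numeric(), gamma = numeric(), seed = integer())
  for (d in latentDims) for (b in betas) for (s in seeds) {
    configs[[length(configs) + 1L]] <-
      vaeConfig("beta_vae", latentDim = d, beta = b, seed = s, ...)
    tab[nrow(tab) + 1L, ] <- list("beta_vae", d, b, 0, s)
  }
  for (d in latentDims) for (g in setdiff(gammas, 0)) for (s in seeds) {
    configs[[length(configs) + 1L]] <-
      vaeConfig("factor_vae", latentDim = d, gamma = g, seed = s, ...)
    tab[nrow(tab) + 1L, ] <- list("factor_vae", d, 1, g, s)
  }
  # gamma = 0 cells alias the beta = 1 beta-VAE cells: only recorded, never
  # duplicated as configs
  attr(configs, "gridTable") <- tab
  attr(configs, "gammaZeroAliased") <- 0 %in% gammas
  configs
}

#' Supervised disentanglement gap score
#'
#' Importance of latent l for factor f is the absolute Spearman correlation
#' across stimuli. For each factor the score contribution is the normalized
#' gap between the largest and second-largest importance,
#' (m1 - m2) / m1 (0 when m1 = 0); the score is the mean over factors. It is
#' 1 exactly when each factor aligns with a unique latent with zero
#' cross-talk, 0 when every latent mixes all factors symmetrically, and is
#' invariant to latent permutations and sign flips.
#'
#' @param latents Stimulus x latent matrix (posterior means).
#' @param factors Stimulus x factor matrix of true generative factors (>= 2
#'   factors).
#' @return List with `score` (in [0, 1]) and `importance` (latents x factors
#'   matrix).
#' @export
disentanglementScore <- function(latents, factors) {
  assertMatrix(latents); assertMatrix(factors)
  if (nrow(latents) != nrow(factors)) stop("row counts must match")
  if (ncol(factors) < 2L) stop("at least 2 factors are required")
  const <- apply(latents, 2, stats::sd) == 0
  if (any(const)) warning(sum(const), " constant latent column(s): importance set to 0")
  imp <- matrix(0, ncol(latents), ncol(factors))
  if (any(!const)) {
    imp[!const, ] <- abs(stats::cor(latents[, !const, drop = FALSE], factors,
                                    method = "spearman"))
  }
  gaps <- apply(imp, 2, function(col) {
    srt <- sort(col, decreasing = TRUE)
    if (srt[1] == 0) 0 else (srt[1] - srt[2]) / srt[1]
  })
  list(score = mean(gaps), importance = imp)
}

#' Select the best model from scored grid results
#'
#' Argmax of the disentanglement score; ties broken deterministically by
#' smaller latent dimension, then smaller seed.
#'
#' @param results List of entries, each a list with `config` (a
#'   [vaeConfig()]) and `score` (numeric).
#' @return The winning `vaeConfig`.
#' @export
selectModel <- function(results) {
  if (length(results) == 0L) stop("no scored models to select from")
  scores <- vapply(results, function(r) r$score, numeric(1))
  dims <- vapply(results, function(r) r$config$latentDim, integer(1))
  seeds <- vapply(results, function(r) r$config$seed, integer(1))
  ord <- order(-scores, dims, seeds)
  results[[ord[1]]]$config
}

#' Classify latent dimensions by their factor alignment
#'
#' Assigns each latent dimension to the semantic class of its best-aligned
#' factor (identity-relevant or identity-irrelevant) when the alignment is
#' strong and isolated, and to the entangled class otherwise (weak best
#' importance or small gap to the runner-up).
#'
#' @param latents Stimulus x latent matrix.
#' @param factors Stimulus x factor matrix.
#' @param identityRelevant Logical vector over factors.
#' @param minImportance Minimum best importance for a dimension to count as
#'   aligned.
#' @param minGap Minimum normalized gap (m1 - m2) / m1 for alignment.
#' @return List of integer index vectors: `relevant`, `irrelevant`,
#'   `entangled`.
#' @export
classifyDimensions <- function(latents, factors, identityRelevant,
                               minImportance = 0.4, minGap = 0.3) {
  stopifnot(length(identityRelevant) == ncol(factors))
  imp <- disentanglementScore(latents, factors)$importance
  relevant <- integer(); irrelevant <- integer(); entangled <- integer()
  for (l in seq_len(nrow(imp))) {
    srt <- sort(imp[l, ], decreasing = TRUE)
    best <- which.max(imp[l, ])
    gap <- if (srt[1] == 0) 0 else (srt[1] - srt[2]) / srt[1]
    if (srt[1] < minImportance || gap < minGap) {
      entangled <- c(entangled, l)
    } else if (identityRelevant[best]) {
      relevant <- c(relevant, l)
    } else {
      irrelevant <- c(irrelevant, l)
    }
  }
  list(relevant = relevant, irrelevant = irrelevant, entangled = entangled)
}
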