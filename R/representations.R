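# Comparing representation spaces: canonical correlation analysis between two
# embeddings of the same stimuli, and PCA reduction of an external embedding
# to a matched dimensionality.

#' Mean canonical correlation between two embeddings
#'
#' Standardizes the columns of both matrices, whitens each set with a small
#' ridge on its covariance for numerical stability, and returns the mean of
#' the canonical correlations over min(dims) components (or only the first,
#' with `summary = "first"`). The statistic is invariant to invertible linear
#' transforms of either embedding and lies in [0, 1].
#'
#' @param A,B Stimulus x feature matrices with aligned rows; the row count
#'   must exceed the larger feature count.
#' @param ridge Ridge added to the within-set correlation matrices
#'   (relative to their unit diagonal).
#' @param summary `"mean"` (default) or `"first"`.
#' @return Numeric scalar in [0, 1].
#' @examples
#' A <- matrix(rnorm(200), 50, 4)
#' ccaSimilarity(A, A %*% matrix(rnorm(16), 4, 4))
#' @export
ccaSimilarity <- function(A, B, ridge = 1e-8, summary = c("mean", "first")) {
  summary <- match.arg(summary)
  assertMatrix(A); assertMatrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have the same number of rows")
  if (nrow(A) <= max(ncol(A), ncol(B))) {
    stop("need more rows than the larger feature count for CCA")
  }
  if (!all(is.finite(A)) || !all(is.finite(B))) stop("embeddings must be finite")

  std <- function(M) {
    s <- apply(M, 2, stats::sd)
    if (any(s == 0)) {
      warning("constant column(s) dropped before CCA")
      M <- M[, s > 0, drop = FALSE]
      s <- s[s > 0]
    }
    scale(M)
  }
  A <- std(A); B <- std(B)
  n <- nrow(A)
  Saa <- crossprod(A) / (n - 1)
  Sbb <- crossprod(B) / (n - 1)
  Sab <- crossprod(A, B) / (n - 1)
  whiten <- function(S, r) {
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values + r
    if (any(e$values < 1e-8)) {
      warning("rank-deficient input: increasing ridge regularization")
      vals <- e$values + 1e-6
    }
    e$vectors %*% diag(1 / sqrt(vals), nrow(S)) %*% t(e$vectors)
  }
  K <- whiten(Saa, ridge) %*% Sab %*% whiten(Sbb, ridge)
  rho <- pmin(1, svd(K)$d)
  m <- min(ncol(A), ncol(B))
  if (summary == "first") rho[1] else mean(rho[seq_len(m)])
}

#' PCA reduction of an embedding
#'
#' Column-centered principal component analysis; returns the top-k scores and
#' the fraction of variance they capture.
#'
#' @param E Stimulus x feature matrix.
#' @param k Number of components, k <= min(rows - 1, features).
#' @return List with `reduced` (stimulus x k score matrix), `rotation`, and
#'   `varianceExplained` (fraction in (0, 1]).
#' @examples
#' E <- matrix(rnorm(500), 50, 10)
#' pcaReduce(E, 3)$varianceExplained
#' @export
pcaReduce <- function(E, k) {
  assertMatrix(E)
  if (k > min(nrow(E) - 1L, ncol(E))) stop("k exceeds min(rows - 1, features)")
  p <- stats::prcomp(E, center = TRUE, scale. = FALSE)
  ve <- sum(p$sdev[seq_len(k)]^2) / sum(p$sdev^2)
  list(reduced = p$x[, seq_len(k), drop = FALSE],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       varianceExplained = ve)
}
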