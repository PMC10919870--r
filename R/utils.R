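# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded package functions do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic substream seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12347L) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Population-sd z-score (denominator n, per the selection-metric convention).
zscorePop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    warning("constant scores: z set to 0")
    return(rep(0, length(x)))
  }
  (x - mu) / s
}

#' Per-column Spearman correlation between two matrices
#'
#' Correlates column i of `a` with column i of `b` across rows. Columns that are
#' constant in either matrix get r = 0 and are flagged.
#'
#' @param a,b Numeric matrices of identical dimension (observations x channels).
#' @return Numeric vector of Spearman correlations with a logical
#'   `constant` attribute marking flagged channels.
#' @keywords internal
spearmanColumns <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  ra <- apply(a, 2, rank)
  rb <- apply(b, 2, rank)
  ca <- apply(ra, 2, stats::sd)
  cb <- apply(rb, 2, stats::sd)
  const <- ca == 0 | cb == 0
  r <- rep(0, ncol(a))
  if (any(!const)) {
    ra <- scale(ra[, !const, drop = FALSE])
    rb <- scale(rb[, !const, drop = FALSE])
    r[!const] <- colSums(ra * rb) / (nrow(a) - 1)
  }
  attr(r, "constant") <- const
  r
}

# Clamp to [lo, hi]. Argument order matters: pmin/pmax keep the attributes
# (including dim) of their first argument.
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

assertMatrix <- function(x, what = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  }
  invisible(x)
}
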