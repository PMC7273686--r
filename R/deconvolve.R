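#' Network deconvolution of an association score matrix
#'
#' Removes transitive (indirect) association weight: the observed matrix is
#' linearly scaled so that, after the eigenvalue transform
#' `lambda -> lambda / (1 + lambda)`, the spectrum is bounded by `beta`
#' (largest positive eigenvalue scaled to `beta / (1 - beta)`; the negative
#' side to `-beta / (1 + beta)`), then reconstructed from the transformed
#' eigendecomposition. The diagonal is treated as zero (self-association
#' carries no information about indirect paths). With `alpha = 1` every
#' candidate entry is retained; with `alpha < 1` only the top `alpha`
#' fraction of entries by observed magnitude enters the deconvolution, the
#' rest are zeroed.
#'
#' @param scores Symmetric numeric matrix of association scores.
#' @param alpha Fraction of edges kept, in (0, 1].
#' @param beta Eigenvalue scaling factor, in (0, 1).
#' @return The direct-score matrix (zero diagonal, symmetric).
#' @export
deconvolve <- function(scores, alpha = 1, beta = 0.9) {
  if (!isSymmetric(unname(scores), tol = 1e-8))
    abort("`scores` must be symmetric.")
  stopifnot(alpha > 0, alpha <= 1, beta > 0, beta < 1)
  G <- unname(as.matrix(scores))
  diag(G) <- 0
  if (alpha < 1) {
    off <- abs(G[upper.tri(G)])
    if (any(off > 0)) {
      cut <- sort(off[off > 0], decreasing = TRUE)
      cut <- cut[max(1, ceiling(alpha * length(cut)))]
      G[abs(G) < cut] <- 0
    }
  }
  if (all(G == 0)) {
    dimnames(G) <- dimnames(scores)
    return(G)
  }
  eg <- eigen(G, symmetric = TRUE)
  lam_max <- max(eg$values)
  lam_min <- min(eg$values)
  bounds <- c(
    if (lam_max > 0) beta / ((1 - beta) * lam_max),
    if (lam_min < 0) beta / ((1 + beta) * abs(lam_min)))
  gamma <- min(bounds)
  lam <- gamma * eg$values
  lam_dir <- lam / (1 + lam)
  G_dir <- eg$vectors %*% (lam_dir * t(eg$vectors))
  G_dir <- (G_dir + t(G_dir)) / 2
  diag(G_dir) <- 0
  dimnames(G_dir) <- dimnames(scores)
  G_dir
}
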