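#' Spearman rank correlation of two abundance profiles
#'
#' Rank correlation with average (mid-)ranks for ties. Returns `NA` (an
#' explicit undefined marker) when either vector is constant; such pairs are
#' excluded downstream.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @examples
#' spearman_score(c(1, 2, 3), c(2, 4, 6))   # 1
#' spearman_score(c(1, 2, 3), c(3, 2, 1))   # -1
#' @export
spearman_score <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Bray-Curtis similarity of two relative-abundance profiles
#'
#' `1 - sum(|x - y|) / sum(x + y)`, in \[0, 1\]. Returns `NA` when both
#' vectors are all zero.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return A similarity in \[0, 1\], or `NA`.
#' @examples
#' braycurtis_similarity(c(1, 1), c(1, 3))  # 2/3
#' @export
braycurtis_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("Entries must be non-negative.")
  den <- sum(x + y)
  if (den <= 0) return(NA_real_)
  1 - sum(abs(x - y)) / den
}

# Pairwise score matrices on relative abundances: Spearman via Pearson of
# row ranks; Bray-Curtis via vegan.
pairwise_scores <- function(relab) {
  ranks <- row_ranks_cpp(relab)
  rho <- suppressWarnings(cor(t(ranks)))
  bc <- 1 - as.matrix(vegan::vegdist(relab, method = "bray"))
  dimnames(rho) <- dimnames(bc) <- list(rownames(relab), rownames(relab))
  diag(rho) <- 1
  diag(bc) <- 1
  list(rho = rho, bc = bc)
}
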