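#' Permutation null distribution for one taxon pair
#'
#' Each iteration independently permutes the two ESVs' counts across
#' samples. With `renormalize = TRUE` (required for Spearman, to mitigate
#' compositionality bias) the per-sample totals are recomputed after the
#' shuffle — only the pair's rows moved, so totals change — and the measure
#' is evaluated on the renormalized relative abundances. Without
#' renormalization the ESVs' relative-abundance values are shuffled as-is
#' (the Bray-Curtis path).
#'
#' @param table An [abundance_table()].
#' @param pair Character vector of two ESV ids.
#' @param measure `"spearman"` or `"bc"`.
#' @param n_iter Number of permutations.
#' @param renormalize Recompose relative abundances after each shuffle;
#'   defaults to `TRUE` for Spearman and `FALSE` for Bray-Curtis.
#' @param seed Integer seed.
#' @return Numeric vector of `n_iter` null scores.
#' @export
permutation_null <- function(table, pair, measure = c("spearman", "bc"),
                             n_iter = 1000,
                             renormalize = (measure == "spearman"),
                             seed = 1) {
  measure <- match.arg(measure)
  force(renormalize)
  if (n_iter <= 0) abort("`n_iter` must be positive.")
  if (!all(pair %in% rownames(table$counts)))
    abort("Both pair members must be present in the table.")
  x <- table$counts[pair[1], ]
  y <- table$counts[pair[2], ]
  set.seed(seed)
  if (renormalize) {
    rest <- colSums(table$counts) - x - y
    perm_scores_cpp(x, y, rest, n_iter,
                    if (measure == "spearman") 0L else 1L, TRUE)
  } else {
    relab <- relative_abundances(table)
    perm_scores_cpp(relab[pair[1], ], relab[pair[2], ], numeric(length(x)),
                    n_iter, if (measure == "spearman") 0L else 1L, FALSE)
  }
}

#' Bootstrap distribution of an association score
#'
#' Resamples sample columns with replacement and recomputes the measure on
#' the pair's relative abundances. Iterations whose resample has fewer than
#' three distinct samples (or leaves a profile constant, for Spearman) are
#' redrawn up to ten times to keep the measure defined.
#'
#' @inheritParams permutation_null
#' @return Numeric vector of `n_iter` bootstrap scores.
#' @export
bootstrap_distribution <- function(table, pair,
                                   measure = c("spearman", "bc"),
                                   n_iter = 1000, seed = 1) {
  measure <- match.arg(measure)
  if (n_iter <= 0) abort("`n_iter` must be positive.")
  if (n_samples(table) < 3)
    abort("At least 3 samples are needed for a bootstrap distribution.")
  if (!all(pair %in% rownames(table$counts)))
    abort("Both pair members must be present in the table.")
  relab <- relative_abundances(table)
  set.seed(seed)
  boot_scores_cpp(relab[pair[1], ], relab[pair[2], ], n_iter,
                  if (measure == "spearman") 0L else 1L, 10L)
}

#' ReBoot p-value from a permutation null and a bootstrap distribution
#'
#' The null value is the mean of the permutation scores; its probability is
#' read off a Gaussian fitted to the mean and standard deviation of the
#' bootstrap distribution, two-sided:
#' `p = 2 * (1 - pnorm(|mean(null) - mean(boot)| / sd(boot)))`.
#'
#' @param null_values Permutation null scores.
#' @param boot_values Bootstrap scores.
#' @return The p-value, with attributes `z` and `degenerate` (`TRUE` when
#'   `sd(boot) == 0`: then p is 0 if the means differ and 1 if they agree).
#' @examples
#' reboot_pvalue(rep(0.696, 10), rnorm(1e4, 0.5, 0.1))  # ~0.05
#' @export
reboot_pvalue <- function(null_values, boot_values) {
  m_null <- mean(null_values, na.rm = TRUE)
  m_boot <- mean(boot_values, na.rm = TRUE)
  s_boot <- sd(boot_values, na.rm = TRUE)
  if (is.na(s_boot) || s_boot == 0) {
    p <- if (isTRUE(all.equal(m_null, m_boot))) 1 else 0
    return(structure(p, z = if (p == 1) 0 else Inf, degenerate = TRUE))
  }
  z <- (m_null - m_boot) / s_boot
  structure(2 * pnorm(-abs(z)), z = z, degenerate = FALSE)
}

#' Combine two dependent p-values with Brown's method
#'
#' Brown's extension of Fisher's method: `T = -2(log p1 + log p2)` is
#' referred to a scaled chi-square whose first two moments match
#' `E = 4`, `Var = 8 + 2 * covariance`, where `covariance` is the
#' covariance of `(-2 log p1, -2 log p2)`; with zero covariance this is
#' exactly Fisher's method.
#'
#' @param p1,p2 p-values in (0, 1\]; zeros are clamped to the smallest
#'   positive double.
#' @param covariance Covariance of the log-transformed p-values, clamped to
#'   \[0, 4\] (4 is perfect dependence, under which the merge returns the
#'   common p). Estimate it once per network with
#'   [estimate_brown_covariance()].
#' @return Vector of merged p-values.
#' @export
browns_merge <- function(p1, p2, covariance = 0) {
  stopifnot(length(p1) == length(p2))
  p1 <- pmax(p1, .Machine$double.xmin)
  p2 <- pmax(p2, .Machine$double.xmin)
  covariance <- min(max(covariance, 0), 4)
  T_stat <- -2 * (log(p1) + log(p2))
  E <- 4
  V <- 8 + 2 * covariance
  c_scale <- V / (2 * E)
  df <- 2 * E^2 / V
  pchisq(T_stat / c_scale, df = df, lower.tail = FALSE)
}

#' Empirical covariance of log-transformed p-value pairs
#'
#' The covariance of `(-2 log p1, -2 log p2)` across all candidate edges,
#' clamped to \[0, 4\]; estimated once per environment since a single pair
#' gives one observation.
#'
#' @param p1,p2 Vectors of per-measure p-values across candidate pairs.
#' @return A single covariance in \[0, 4\].
#' @export
estimate_brown_covariance <- function(p1, p2) {
  keep <- is.finite(p1) & is.finite(p2) & p1 > 0 & p2 > 0
  if (sum(keep) < 3) return(0)
  min(max(cov(-2 * log(p1[keep]), -2 * log(p2[keep])), 0), 4)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); order-preserving against input positions.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Benjamini-Yekutieli adjustment
#'
#' Step-up adjustment with the harmonic-sum inflation `c(m) = sum(1/i)`,
#' valid under arbitrary dependence (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order; always elementwise >= BH.
#' @export
by_adjust <- function(pvalues) p.adjust(pvalues, method = "BY")
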