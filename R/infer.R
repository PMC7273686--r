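#' Configuration for network inference
#'
#' @param n_iter Permutation and bootstrap iterations per candidate pair.
#' @param alpha_fdr FDR level applied to the Brown-merged p-values (and to
#'   each measure's own adjusted p-values for both-measure support).
#' @param bc_quantile Tail mass of the per-pair permutation null used as the
#'   Bray-Curtis support criterion: positive edges need
#'   `bc_sim >= null (1 - bc_quantile) quantile`, negative edges
#'   `bc_sim <= null bc_quantile quantile`.
#' @param rmt_scan Numeric `c(start, stop, step)` scan grid for the RMT
#'   threshold on `|rho|`.
#' @param rmt_fallback Fallback threshold when no scanned value qualifies.
#' @param nd_alpha,nd_beta Network-deconvolution parameters (fraction of
#'   edges kept; eigenvalue scaling factor).
#' @param seed Integer seed covering all randomness in one environment's
#'   inference.
#' @return A list of class `infer_config`.
#' @export
infer_config <- function(n_iter = 1000, alpha_fdr = 0.05, bc_quantile = 0.05,
                         rmt_scan = c(0.30, 0.95, 0.01), rmt_fallback = 0.6,
                         nd_alpha = 1, nd_beta = 0.9, seed = 1) {
  stopifnot(n_iter > 0, alpha_fdr > 0, alpha_fdr < 1,
            bc_quantile > 0, bc_quantile < 0.5,
            length(rmt_scan) == 3,
            nd_alpha > 0, nd_alpha <= 1, nd_beta > 0, nd_beta < 1)
  structure(list(n_iter = as.integer(n_iter), alpha_fdr = alpha_fdr,
                 bc_quantile = bc_quantile, rmt_scan = rmt_scan,
                 rmt_fallback = rmt_fallback, nd_alpha = nd_alpha,
                 nd_beta = nd_beta, seed = as.integer(seed)),
            class = "infer_config")
}

#' Both-measure support rule for edge candidates
#'
#' An edge candidate is supported when (i) `|rho|` reaches the RMT score
#' threshold, (ii) both measures' BH-adjusted ReBoot p-values pass the FDR
#' level, and (iii) the Bray-Curtis criterion holds: for positive edges the
#' observed similarity reaches the upper quantile of its own permutation
#' null, for negative (mutual-exclusion) edges it falls at or below the
#' complementary lower quantile.
#'
#' @param candidates Tibble of edge candidates with columns `rho`, `bc_sim`,
#'   `q_spearman`, `q_bc` (per-measure BH-adjusted p), `bc_null_lo`,
#'   `bc_null_hi` (per-pair null quantiles).
#' @param rho_threshold RMT threshold on `|rho|`.
#' @param alpha_fdr Per-measure FDR level.
#' @return Logical vector of support flags.
#' @export
both_measure_support <- function(candidates, rho_threshold,
                                 alpha_fdr = 0.05) {
  with(candidates, {
    sig_both <- !is.na(q_spearman) & q_spearman <= alpha_fdr &
      !is.na(q_bc) & q_bc <= alpha_fdr
    bc_crit <- ifelse(rho >= 0,
                      bc_sim >= bc_null_hi,
                      bc_sim <= bc_null_lo)
    !is.na(rho) & abs(rho) >= rho_threshold & sig_both &
      !is.na(bc_crit) & bc_crit
  })
}

#' Score every candidate pair of one environment table
#'
#' Computes observed Spearman and Bray-Curtis scores on relative abundances
#' and, for each pair, ReBoot permutation/bootstrap p-values per measure,
#' the Brown-merged p (dependence estimated empirically across all pairs),
#' and BH adjustments. Constant-abundance ESVs are excluded from the
#' candidate set.
#'
#' @param table Single-environment [abundance_table()].
#' @param config An [infer_config()].
#' @return A tibble of edge candidates, one row per tested pair.
#' @export
score_candidates <- function(table, config = infer_config()) {
  counts <- table$counts
  keep <- apply(counts, 1, function(r) length(unique(r)) > 1)
  counts <- counts[keep, , drop = FALSE]
  n_excluded <- sum(!keep)
  if (nrow(counts) < 2) abort("Fewer than 2 non-constant ESVs to test.")
  if (ncol(counts) < 4) abort("At least 4 samples are required.")
  sub <- abundance_table(counts, table$environments)
  relab <- relative_abundances(sub)
  scores <- pairwise_scores(relab)
  ids <- rownames(counts)
  idx <- which(upper.tri(scores$rho), arr.ind = TRUE)
  pairs <- cbind(idx[, 1] - 1L, idx[, 2] - 1L)
  set.seed(config$seed)
  summ <- reboot_summaries_cpp(counts, relab, colSums(counts), pairs,
                               config$n_iter, config$bc_quantile, 10L)
  p_sp <- 2 * pnorm(-abs((summ[, 1] - summ[, 2]) /
                           ifelse(summ[, 3] > 0, summ[, 3], NA)))
  p_sp[is.na(p_sp)] <- ifelse(
    abs(summ[is.na(p_sp), 1] - summ[is.na(p_sp), 2]) < 1e-12, 1, 0)
  p_bc <- 2 * pnorm(-abs((summ[, 4] - summ[, 5]) /
                           ifelse(summ[, 6] > 0, summ[, 6], NA)))
  p_bc[is.na(p_bc)] <- ifelse(
    abs(summ[is.na(p_bc), 4] - summ[is.na(p_bc), 5]) < 1e-12, 1, 0)
  cov_hat <- estimate_brown_covariance(p_sp, p_bc)
  p_merged <- browns_merge(p_sp, p_bc, cov_hat)
  tibble(
    esv_a = ids[idx[, 1]],
    esv_b = ids[idx[, 2]],
    rho = scores$rho[idx],
    bc_sim = scores$bc[idx],
    p_spearman = p_sp,
    p_bc = p_bc,
    p_merged = p_merged,
    p_adjusted = bh_adjust(p_merged),
    q_spearman = bh_adjust(p_sp),
    q_bc = bh_adjust(p_bc),
    bc_null_lo = summ[, 7],
    bc_null_hi = summ[, 8],
    brown_covariance = cov_hat,
    n_excluded_constant = n_excluded
  )
}

#' Infer a co-occurrence network for one environment
#'
#' Orchestrates the full inference chain on a preprocessed,
#' single-environment table: relative abundances, pairwise Spearman and
#' Bray-Curtis scores, per-pair permutation/bootstrap (ReBoot) p-values per
#' measure, Brown's merge, BH adjustment, RMT score thresholding,
#' both-measure support, and network deconvolution. Edges failing any
#' criterion are discarded; retained edges carry `sign = sign(rho)`.
#'
#' @param table Single-environment [abundance_table()].
#' @param config An [infer_config()].
#' @param taxonomy Optional taxonomy tibble (joined onto vertices).
#' @param environment Environment label; defaults to the table's (unique)
#'   label, or `"unknown"` when the table has none.
#' @return A [cooc_network()] with a `provenance` tibble of per-stage
#'   candidate counts.
#' @export
infer_environment_network <- function(table, config = infer_config(),
                                      taxonomy = NULL, environment = NULL) {
  if (is.null(environment)) {
    environment <- if (!is.null(table$environments))
      unique(unname(table$environments)) else "unknown"
  }
  if (length(environment) != 1)
    abort("`table` must cover a single environment.")
  cand <- score_candidates(table, config)
  rmt <- suppressWarnings(rmt_threshold(
    abs(build_score_matrix(cand, "rho")),
    scan_start = config$rmt_scan[1], scan_stop = config$rmt_scan[2],
    scan_step = config$rmt_scan[3], fallback = config$rmt_fallback))
  supported <- both_measure_support(cand, rmt$threshold, config$alpha_fdr)
  retained <- supported & !is.na(cand$p_adjusted) &
    cand$p_adjusted <= config$alpha_fdr & cand$rho != 0
  edges <- cand[retained, , drop = FALSE]
  # deconvolution on the retained signed score matrix; with nd_alpha = 1 it
  # annotates direct scores without removing edges
  if (nrow(edges) > 0) {
    S <- build_score_matrix(edges, "rho")
    D <- deconvolve(S, alpha = config$nd_alpha, beta = config$nd_beta)
    edges$direct_score <- D[cbind(match(edges$esv_a, rownames(D)),
                                  match(edges$esv_b, colnames(D)))]
    if (config$nd_alpha < 1) {
      k <- ceiling(config$nd_alpha * nrow(edges))
      keep_idx <- order(-abs(edges$direct_score))[seq_len(k)]
      edges <- edges[sort(keep_idx), , drop = FALSE]
    }
  } else {
    edges$direct_score <- numeric(0)
  }
  relab <- relative_abundances(table)
  vertices <- tibble(esv_id = rownames(table$counts),
                     mean_rel_abundance = rowMeans(relab))
  if (!is.null(taxonomy))
    vertices <- dplyr::left_join(vertices, taxonomy, by = "esv_id")
  edges_out <- tibble(
    esv_a = edges$esv_a, esv_b = edges$esv_b,
    sign = sign(edges$rho), rho = edges$rho, bc_sim = edges$bc_sim,
    p_spearman = edges$p_spearman, p_bc = edges$p_bc,
    p_merged = edges$p_merged, p_adjusted = edges$p_adjusted,
    environment = environment, direct_score = edges$direct_score)
  provenance <- tibble(
    environment = environment,
    n_esvs = n_esvs(table), n_samples = n_samples(table),
    n_candidate_pairs = nrow(cand),
    n_excluded_constant = cand$n_excluded_constant[1] %||% 0L,
    rho_threshold = rmt$threshold,
    rmt_fallback_used = rmt$warning,
    brown_covariance = cand$brown_covariance[1] %||% NA_real_,
    n_fdr_pass = sum(cand$p_adjusted <= config$alpha_fdr, na.rm = TRUE),
    n_supported = sum(supported, na.rm = TRUE),
    n_retained = nrow(edges_out))
  cooc_network(vertices, edges_out, provenance = provenance)
}

# Symmetric score matrix (unit diagonal) over the ESVs appearing in a
# candidate table.
build_score_matrix <- function(cand, col = "rho") {
  ids <- sort(unique(c(cand$esv_a, cand$esv_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(cand$esv_a, ids)
  j <- match(cand$esv_b, ids)
  v <- cand[[col]]
  v[is.na(v)] <- 0
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  diag(m) <- 1
  m
}

#' Infer subnetworks for every environment of a dataset
#'
#' Convenience driver: splits (if needed), then runs
#' [infer_environment_network()] per environment with a seed derived
#' deterministically from `config$seed` and the environment's position.
#'
#' @param tables Named list of single-environment [abundance_table()]s.
#' @param config An [infer_config()].
#' @param taxonomy Optional taxonomy tibble.
#' @return Named list of [cooc_network()]s.
#' @export
infer_all_networks <- function(tables, config = infer_config(),
                               taxonomy = NULL) {
  out <- vector("list", length(tables))
  names(out) <- names(tables)
  for (k in seq_along(tables)) {
    cfg <- config
    cfg$seed <- (config$seed + 1009L * k) %% .Machine$integer.max
    out[[k]] <- infer_environment_network(tables[[k]], cfg,
                                          taxonomy = taxonomy,
                                          environment = names(tables)[k])
  }
  out
}
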