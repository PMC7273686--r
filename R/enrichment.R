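#' Taxon-pair overrepresentation of edges (hypergeometric)
#'
#' Tests whether edges fall between two taxa more often than expected under
#' uniform edge placement conditional on network size. For an unordered
#' label pair (A, B) at the chosen rank: the population is all `N = C(V, 2)`
#' unordered vertex pairs, the successes are the `K` pairs with one endpoint
#' in A and one in B (within-taxon pairs use `K = C(|A|, 2)`), the draws are
#' the `n` realized edges, and `k` is the observed A-B edge count; the
#' overrepresentation p is the hypergeometric upper tail `P(X >= k)`
#' (lower tail reported separately), BY-adjusted across label pairs.
#'
#' @param net A [cooc_network()].
#' @param taxonomy Taxonomy tibble with `esv_id` and the rank column.
#' @param rank Taxonomic rank column name (default `"class"`).
#' @return Tibble: `taxon_a`, `taxon_b`, `observed_edges`,
#'   `possible_pairs`, `total_edges`, `total_possible_pairs`, `p`
#'   (upper tail), `p_lower`, `p_adjusted` (BY on `p`).
#' @export
taxon_pair_overrepresentation <- function(net, taxonomy, rank = "class") {
  if (!rank %in% names(taxonomy))
    abort(sprintf("Taxonomy has no '%s' column.", rank))
  labels <- setNames(taxonomy[[rank]], taxonomy$esv_id)
  v <- net$vertices$esv_id
  lab <- labels[v]
  lab[is.na(lab)] <- "unclassified"
  names(lab) <- v
  de <- distinct_edges(net)
  N <- choose(length(v), 2)
  n_edges <- nrow(de)
  sizes <- table(lab)
  edge_lab <- canonical_pair(unname(lab[de$esv_a]), unname(lab[de$esv_b]))
  obs <- dplyr::count(tibble(taxon_a = edge_lab$esv_a,
                             taxon_b = edge_lab$esv_b),
                      .data$taxon_a, .data$taxon_b, name = "observed_edges")
  taxa <- sort(names(sizes))
  idx <- which(upper.tri(diag(length(taxa)), diag = TRUE), arr.ind = TRUE)
  grid <- tibble(taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]])
  out <- dplyr::left_join(grid, obs, by = c("taxon_a", "taxon_b"))
  out$observed_edges[is.na(out$observed_edges)] <- 0L
  out$possible_pairs <- ifelse(
    out$taxon_a == out$taxon_b,
    choose(as.numeric(sizes[out$taxon_a]), 2),
    as.numeric(sizes[out$taxon_a]) * as.numeric(sizes[out$taxon_b]))
  if (any(out$observed_edges > pmin(out$possible_pairs, n_edges)))
    abort("Observed edge count exceeds possible pairs: bookkeeping bug.")
  out$total_edges <- n_edges
  out$total_possible_pairs <- N
  out$p <- phyper(out$observed_edges - 1, out$possible_pairs,
                  N - out$possible_pairs, n_edges, lower.tail = FALSE)
  out$p_lower <- phyper(out$observed_edges, out$possible_pairs,
                        N - out$possible_pairs, n_edges)
  out$p_adjusted <- by_adjust(out$p)
  as_tibble(out)
}

#' Mutual exclusion versus co-presence test (binomial)
#'
#' Of `m` edges between a pair of taxa, `k` are negative (mutual
#' exclusion). With background negative-edge frequency `q` (the
#' network-wide fraction of negative edges), the exclusion
#' overrepresentation p is the binomial upper tail `P(X >= k)`; co-presence
#' overrepresentation is the symmetric lower tail `P(X <= k)`.
#'
#' @param m Total edges for the taxon pair.
#' @param k Negative edges among them.
#' @param q Background negative-edge frequency in \[0, 1\].
#' @return One-row tibble: `p_exclusion`, `p_copresence`.
#' @export
exclusion_copresence_test <- function(m, k, q) {
  stopifnot(k >= 0, k <= m, q >= 0, q <= 1)
  tibble(p_exclusion = pbinom(k - 1, m, q, lower.tail = FALSE),
         p_copresence = pbinom(k, m, q))
}

#' Network-wide exclusion/co-presence enrichment per taxon pair
#'
#' Applies [exclusion_copresence_test()] to every taxon pair with at least
#' one edge, with the background frequency estimated from the network, and
#' BY-adjusts each tail.
#'
#' @inheritParams taxon_pair_overrepresentation
#' @return Tibble with per-pair edge counts, negative counts, both tail
#'   p-values and their BY adjustments.
#' @export
exclusion_enrichment <- function(net, taxonomy, rank = "class") {
  labels <- setNames(taxonomy[[rank]], taxonomy$esv_id)
  de <- distinct_edges(net)
  if (nrow(de) == 0) return(tibble())
  la <- labels[de$esv_a]
  lb <- labels[de$esv_b]
  la[is.na(la)] <- "unclassified"
  lb[is.na(lb)] <- "unclassified"
  cp <- canonical_pair(unname(la), unname(lb))
  q <- mean(de$sign < 0)
  out <- tibble(taxon_a = cp$esv_a, taxon_b = cp$esv_b,
                negative = de$sign < 0) |>
    dplyr::group_by(.data$taxon_a, .data$taxon_b) |>
    dplyr::summarise(m = dplyr::n(), k = sum(.data$negative),
                     .groups = "drop")
  tails <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(i)
    exclusion_copresence_test(out$m[i], out$k[i], q)))
  out <- dplyr::bind_cols(out, tails)
  out$background_q <- q
  out$p_exclusion_adjusted <- by_adjust(out$p_exclusion)
  out$p_copresence_adjusted <- by_adjust(out$p_copresence)
  out
}
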