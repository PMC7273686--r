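# Independent oracles shared across test files.

# Definitional modularity of a partition: Q = sum_c (e_c / m - (d_c / 2m)^2)
modularity_oracle <- function(edges, membership) {
  m <- nrow(edges)
  Q <- 0
  for (cl in unique(membership)) {
    inside <- sum(membership[edges$esv_a] == cl &
                    membership[edges$esv_b] == cl)
    d <- sum(membership[edges$esv_a] == cl) +
      sum(membership[edges$esv_b] == cl)
    Q <- Q + inside / m - (d / (2 * m))^2
  }
  Q
}

# Exhaustive-enumeration oracle: place n edges uniformly among all vertex
# pairs and count placements with at least k edges between labels A and B.
enumeration_oracle <- function(n_vertices, labels, n_edges, k,
                               taxon_a, taxon_b) {
  pairs <- t(combn(n_vertices, 2))
  is_ab <- (labels[pairs[, 1]] == taxon_a & labels[pairs[, 2]] == taxon_b) |
    (labels[pairs[, 1]] == taxon_b & labels[pairs[, 2]] == taxon_a)
  placements <- combn(nrow(pairs), n_edges)
  hits <- apply(placements, 2, function(idx) sum(is_ab[idx]) >= k)
  mean(hits)
}
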