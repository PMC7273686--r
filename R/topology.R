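#' Topology report for a co-occurrence network
#'
#' All metrics are computed on the undirected, unweighted skeleton (edge
#' presence only, negative edges included): edge count, diameter and average
#' separation (largest connected component), global clustering coefficient
#' (transitivity), mean vertex betweenness, and the modularity Q of the
#' fast-greedy agglomerative partition.
#'
#' @param net A [cooc_network()].
#' @return An object of class `topology_report`: `metrics` (one-row tibble)
#'   and `modules` (tibble `esv_id`, `module`). An empty network yields
#'   zeros with `NA` diameter/separation.
#' @export
topology_report <- function(net) {
  de <- distinct_edges(net)
  if (nrow(de) == 0) {
    return(structure(list(
      metrics = tibble(edge_count = 0L, diameter = NA_real_,
                       clustering_coefficient = 0,
                       average_separation = NA_real_,
                       mean_betweenness = 0, modularity = NA_real_,
                       n_components = 0L, largest_component_size = 0L),
      modules = tibble(esv_id = character(), module = integer())),
      class = "topology_report"))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  fg <- igraph::cluster_fast_greedy(g)
  # cut the agglomeration dendrogram exactly at the modularity maximum
  n_comm <- igraph::vcount(g) - (which.max(fg$modularity) - 1)
  memb <- igraph::cut_at(fg, no = n_comm)
  metrics <- tibble(
    edge_count = igraph::ecount(g),
    diameter = igraph::diameter(giant, unconnected = FALSE),
    clustering_coefficient = nan_to_zero(
      igraph::transitivity(g, type = "global")),
    average_separation = igraph::mean_distance(giant, unconnected = FALSE),
    mean_betweenness = mean(igraph::betweenness(g, directed = FALSE)),
    modularity = igraph::modularity(g, memb),
    n_components = comp$no,
    largest_component_size = max(comp$csize))
  modules <- tibble(esv_id = igraph::V(g)$name,
                    module = as.integer(memb))
  structure(list(metrics = metrics, modules = modules),
            class = "topology_report")
}

nan_to_zero <- function(x) if (is.nan(x)) 0 else x

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Power-law (scale-free) fit of the degree distribution
#'
#' Ordinary least squares of `log10(frequency of degree k)` on `log10(k)`
#' over the observed positive degrees. With all degrees equal the fit is
#' undefined; with two distinct degrees the line is exact (`R^2 = 1`) and
#' the regression p-value undefined.
#'
#' @param net A [cooc_network()].
#' @return One-row tibble: `r_squared`, `slope`, `p_value`,
#'   `n_degree_values`.
#' @export
scale_free_fit <- function(net) {
  g <- as_igraph(net)
  k <- igraph::degree(g)
  k <- k[k > 0]
  freq <- table(k)
  kk <- as.numeric(names(freq))
  if (length(kk) < 2)
    return(tibble(r_squared = NA_real_, slope = NA_real_,
                  p_value = NA_real_, n_degree_values = length(kk)))
  fit <- lm(log10(as.numeric(freq)) ~ log10(kk))
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  pv <- if (length(kk) > 2) sm$coefficients[2, 4] else NA_real_
  tibble(r_squared = sm$r.squared, slope = unname(coef(fit)[2]),
         p_value = pv, n_degree_values = length(kk))
}

#' Association between vertex abundance and degree
#'
#' Spearman correlation between vertex degree and mean relative abundance.
#' A non-random network is expected to show no strong association. Constant
#' degree or abundance makes the correlation undefined (`NA`).
#'
#' @param net A [cooc_network()] whose vertices carry
#'   `mean_rel_abundance`.
#' @return One-row tibble: `rho`, `p_value`, `n_vertices`.
#' @export
abundance_degree_association <- function(net) {
  if (nrow(net$vertices) < 3)
    abort("At least 3 vertices are required.")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  ab <- net$vertices$mean_rel_abundance[
    match(names(deg), net$vertices$esv_id)]
  if (length(unique(deg)) < 2 || length(unique(ab)) < 2)
    return(tibble(rho = NA_real_, p_value = NA_real_,
                  n_vertices = length(deg)))
  ct <- suppressWarnings(cor.test(deg, ab, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_vertices = length(deg))
}

#' Taxonomic and environmental composition of network modules
#'
#' For each module of a [topology_report()]: class-rank relative
#' composition, per-environment vertex fractions (a vertex belongs to every
#' environment whose subnetwork contributed one of its edges), module sizes,
#' and the vertex fraction covered by the largest `top_n` modules.
#'
#' @param net A [cooc_network()] (typically merged across environments).
#' @param report Its [topology_report()].
#' @param taxonomy Taxonomy tibble with `esv_id` and a `class` column;
#'   vertices without taxonomy count as `"unclassified"`.
#' @param top_n Number of largest modules for the coverage figure.
#' @return A list: `class_composition`, `environment_composition`,
#'   `module_sizes` (tibbles) and `top_coverage` (fraction of vertices in
#'   the `top_n` largest modules).
#' @export
module_composition <- function(net, report, taxonomy = NULL, top_n = 8) {
  mods <- report$modules
  if (nrow(mods) == 0)
    return(list(class_composition = tibble(), environment_composition = tibble(),
                module_sizes = tibble(), top_coverage = NA_real_))
  tax_class <- if (!is.null(taxonomy) && "class" %in% names(taxonomy)) {
    setNames(taxonomy$class, taxonomy$esv_id)
  } else {
    setNames(character(0), character(0))
  }
  mods$class <- tax_class[mods$esv_id]
  mods$class[is.na(mods$class)] <- "unclassified"
  class_comp <- mods |>
    dplyr::count(.data$module, .data$class, name = "n") |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  # vertex -> environments via incident edge records
  ve <- dplyr::bind_rows(
    net$edges[, c("esv_a", "environment")] |>
      dplyr::rename(esv_id = "esv_a"),
    net$edges[, c("esv_b", "environment")] |>
      dplyr::rename(esv_id = "esv_b")) |>
    dplyr::distinct()
  env_comp <- dplyr::left_join(ve, mods[, c("esv_id", "module")],
                               by = "esv_id") |>
    dplyr::count(.data$environment, .data$module, name = "n") |>
    dplyr::group_by(.data$environment) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  sizes <- mods |>
    dplyr::count(.data$module, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$module) |>
    dplyr::mutate(rank = dplyr::row_number())
  top_cov <- sum(sizes$size[seq_len(min(top_n, nrow(sizes)))]) /
    sum(sizes$size)
  list(class_composition = class_comp, environment_composition = env_comp,
       module_sizes = sizes, top_coverage = top_cov)
}
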