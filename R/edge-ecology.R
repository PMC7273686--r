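#' Classify edges as generalist or specialist across subnetworks
#'
#' Generalist edges occur in at least two environment subnetworks.
#' Specialist edges (exactly one subnetwork) subdivide by their endpoints'
#' generality: a specialist edge linking a generalist vertex pair has both
#' endpoints present as vertices in at least two subnetworks; otherwise it
#' links a specialist vertex pair.
#'
#' @param subnets Named list of per-environment [cooc_network()]s (>= 2).
#' @return A list of class `edge_classification`: `edges` (tibble `esv_a`,
#'   `esv_b`, `n_environments`, `environments`, `class`) and `proportions`
#'   (per-subnetwork tibble of the three class proportions and edge count).
#' @export
classify_edges <- function(subnets) {
  if (length(subnets) < 2)
    abort("At least 2 subnetworks are required.")
  env_edges <- dplyr::bind_rows(lapply(names(subnets), function(e) {
    de <- distinct_edges(subnets[[e]])
    if (nrow(de) == 0) return(NULL)
    tibble(esv_a = de$esv_a, esv_b = de$esv_b, environment = e)
  }))
  vertex_envs <- dplyr::bind_rows(lapply(names(subnets), function(e) {
    v <- subnets[[e]]$vertices
    if (nrow(v) == 0) return(NULL)
    tibble(esv_id = v$esv_id, environment = e)
  })) |> dplyr::distinct()
  vertex_generality <- vertex_envs |>
    dplyr::count(.data$esv_id, name = "n_envs")
  gen_of <- setNames(vertex_generality$n_envs, vertex_generality$esv_id)
  edges <- env_edges |>
    dplyr::group_by(.data$esv_a, .data$esv_b) |>
    dplyr::summarise(
      n_environments = dplyr::n(),
      environments = paste(sort(.data$environment), collapse = ","),
      .groups = "drop")
  edges$class <- ifelse(
    edges$n_environments >= 2, "generalist",
    ifelse(gen_of[edges$esv_a] >= 2 & gen_of[edges$esv_b] >= 2,
           "specialist_generalist_pair", "specialist_specialist_pair"))
  per_env <- dplyr::left_join(
    env_edges, edges[, c("esv_a", "esv_b", "class")],
    by = c("esv_a", "esv_b"))
  classes <- c("generalist", "specialist_generalist_pair",
               "specialist_specialist_pair")
  proportions <- per_env |>
    dplyr::count(.data$environment, .data$class, name = "n") |>
    tidyr::complete(environment = names(subnets),
                    class = classes, fill = list(n = 0L)) |>
    dplyr::group_by(.data$environment) |>
    dplyr::mutate(n_edges = sum(.data$n),
                  proportion = ifelse(.data$n_edges > 0,
                                      .data$n / .data$n_edges, NA_real_)) |>
    dplyr::ungroup()
  structure(list(edges = edges, proportions = proportions),
            class = "edge_classification")
}

#' Omission score of one edge for one environment
#'
#' How much one environment drives an edge: the Spearman correlation of the
#' pair is recomputed on the pooled table without that environment's samples
#' (the omission score, OS) and compared against `n_random` recomputations
#' that each remove a uniformly chosen sample set of the same size. The
#' nonparametric p is the fraction of random |OS| strictly smaller than the
#' group |OS| (ties count against locality); an edge is local to the
#' environment when `ratio = |OS| / |original rho| < 1` and the BH-adjusted
#' p (over all edges analysed together, see [omission_analysis()]) is below
#' 0.05.
#'
#' @param table Pooled [abundance_table()] with environment labels.
#' @param edge Character vector of two ESV ids.
#' @param environment Environment label whose samples are omitted.
#' @param n_random Number of random same-size removals.
#' @param seed Integer seed.
#' @return One-row tibble: `esv_a`, `esv_b`, `environment`, `original_rho`,
#'   `omission_rho`, `ratio`, `p`.
#' @export
omission_score <- function(table, edge, environment, n_random = 1000,
                           seed = 1) {
  if (is.null(table$environments))
    abort("Pooled table needs environment labels.")
  if (!all(edge %in% rownames(table$counts)))
    abort("Both edge ESVs must be present in the pooled table.")
  in_env <- table$environments == environment
  if (!any(in_env)) abort(sprintf("No samples labelled '%s'.", environment))
  if (sum(!in_env) < 3)
    abort("Omitting the environment leaves fewer than 3 samples.")
  relab <- relative_abundances(table)
  x <- relab[edge[1], ]
  y <- relab[edge[2], ]
  original <- spearman_score(x, y)
  cp <- canonical_pair(edge[1], edge[2])
  os_group <- abs(spearman_score(x[!in_env], y[!in_env]))
  set.seed(seed)
  n <- length(x)
  k <- sum(in_env)
  os_random <- vapply(seq_len(n_random), function(i) {
    drop <- sample.int(n, k)
    abs(spearman_score(x[-drop], y[-drop]))
  }, numeric(1))
  p <- sum(os_random < os_group, na.rm = TRUE) / n_random
  ratio <- if (is.na(original) || original == 0) NA_real_
           else os_group / abs(original)
  tibble(esv_a = cp$esv_a, esv_b = cp$esv_b, environment = environment,
         original_rho = original, omission_rho = os_group,
         ratio = ratio, p = p)
}

#' Omission-score localization of generalist edges
#'
#' Runs [omission_score()] for each (edge, environment) request, adjusts the
#' p-values with BH across all of them, and flags edges local to an
#' environment (`ratio < 1` and adjusted p < 0.05). Following the study
#' design, callers typically pass generalist edges with each environment of
#' their environment set.
#'
#' @param table Pooled [abundance_table()] with environment labels.
#' @param requests Tibble with columns `esv_a`, `esv_b`, `environment`.
#' @param n_random Random removals per request.
#' @param seed Integer seed (each request gets a derived seed).
#' @param alpha Significance level on the adjusted p.
#' @return Tibble of omission results with `p_adjusted` and `local`.
#' @export
omission_analysis <- function(table, requests, n_random = 1000, seed = 1,
                              alpha = 0.05) {
  res <- dplyr::bind_rows(lapply(seq_len(nrow(requests)), function(i) {
    omission_score(table,
                   c(requests$esv_a[i], requests$esv_b[i]),
                   requests$environment[i], n_random = n_random,
                   seed = (seed + 7919L * i) %% .Machine$integer.max)
  }))
  res$p_adjusted <- bh_adjust(res$p)
  res$local <- !is.na(res$ratio) & res$ratio < 1 &
    res$p_adjusted < alpha
  res
}

#' Jaccard environment similarity from edge overlap
#'
#' Pairwise Jaccard distance `1 - |E_i intersect E_j| / |E_i union E_j|` on
#' the subnetworks' edge sets, average-linkage hierarchical clustering, and
#' the two-group cut.
#'
#' @param subnets Named list of [cooc_network()]s (>= 2).
#' @return A list: `distance` (matrix), `clustering` (hclust), `groups`
#'   (named two-group membership).
#' @export
environment_similarity <- function(subnets) {
  if (length(subnets) < 2)
    abort("At least 2 subnetworks are required.")
  sets <- lapply(subnets, function(n) {
    de <- distinct_edges(n)
    edge_key(de$esv_a, de$esv_b)
  })
  k <- length(sets)
  d <- matrix(0, k, k, dimnames = list(names(subnets), names(subnets)))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 1 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  hc <- hclust(as.dist(d), method = "average")
  list(distance = d, clustering = hc, groups = cutree(hc, k = 2))
}

#' Taxon profiles of the top-abundant ESVs per edge class
#'
#' For each edge class, endpoint ESVs are ranked by mean relative abundance
#' in the pooled table; the `top_n` are tabulated at genus and class rank.
#'
#' @param classification An [classify_edges()] result.
#' @param table Pooled [abundance_table()].
#' @param taxonomy Taxonomy tibble with `esv_id`, `class`, `genus`.
#' @param top_n ESVs kept per class.
#' @return A list: `top_esvs` (tibble `class`, `esv_id`, `abundance`,
#'   `rank`, plus taxonomy) and `composition` (genus/class counts per edge
#'   class).
#' @export
edge_type_taxa_profile <- function(classification, table, taxonomy = NULL,
                                   top_n = 50) {
  relab <- relative_abundances(table)
  ab <- rowMeans(relab)
  edges <- classification$edges
  endpoint <- dplyr::bind_rows(
    tibble(class = edges$class, esv_id = edges$esv_a),
    tibble(class = edges$class, esv_id = edges$esv_b)) |>
    dplyr::distinct()
  endpoint$abundance <- ab[endpoint$esv_id]
  top <- endpoint |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$esv_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  if (!is.null(taxonomy))
    top <- dplyr::left_join(top, taxonomy, by = "esv_id",
                            suffix = c("", "_taxon"))
  comp <- NULL
  if (!is.null(taxonomy) && "genus" %in% names(taxonomy)) {
    comp <- top |>
      dplyr::count(.data$class, .data$genus, name = "n")
  }
  list(top_esvs = top, composition = comp)
}

#' Correlations between edge-class proportions across subnetworks
#'
#' Pairwise Spearman correlations (with `cor.test` p-values) between the
#' three edge-class proportions, and of each proportion with the
#' subnetworks' edge counts.
#'
#' @param proportions The `proportions` tibble of [classify_edges()] (>= 4
#'   subnetworks).
#' @return Tibble: `var_a`, `var_b`, `rho`, `p_value`; `NA` rho for
#'   constant vectors.
#' @export
edge_type_correlations <- function(proportions) {
  wide <- proportions |>
    dplyr::select("environment", "class", "proportion") |>
    tidyr::pivot_wider(names_from = "class", values_from = "proportion")
  counts <- proportions |>
    dplyr::distinct(.data$environment, .data$n_edges)
  wide <- dplyr::left_join(wide, counts, by = "environment")
  if (nrow(wide) < 4)
    abort("At least 4 subnetworks are required.")
  vars <- setdiff(names(wide), "environment")
  pairs <- utils::combn(vars, 2)
  dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    a <- wide[[pairs[1, k]]]
    b <- wide[[pairs[2, k]]]
    ok <- complete.cases(a, b)
    if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2)
      return(tibble(var_a = pairs[1, k], var_b = pairs[2, k],
                    rho = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman"))
    tibble(var_a = pairs[1, k], var_b = pairs[2, k],
           rho = unname(ct$estimate), p_value = ct$p.value)
  }))
}

#' Top-degree hubs of a subnetwork
#'
#' The `k` highest-degree vertices; ties at the boundary are broken by
#' lexicographic ESV id so the list is deterministic. Networks with fewer
#' than `k` vertices return all of them, flagged.
#'
#' @param net A [cooc_network()].
#' @param k Number of hubs.
#' @return Tibble `esv_id`, `degree`, `rank`, with attribute `truncated`
#'   set when fewer than `k` vertices exist.
#' @export
identify_hubs <- function(net, k = 10) {
  de <- distinct_edges(net)
  if (nrow(de) == 0) abort("Cannot identify hubs of an empty network.")
  deg <- table(c(de$esv_a, de$esv_b))
  out <- tibble(esv_id = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$esv_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "truncated") <- nrow(out) < k
  out
}

#' Hub presence across subnetworks
#'
#' Binary hub-by-subnetwork presence matrix, Jaccard + average-linkage
#' clustering of the subnetworks by their hub sets, and the specialist-hub
#' report (hubs present in exactly one subnetwork).
#'
#' @param hub_lists Named list (one element per subnetwork) of hub tibbles
#'   from [identify_hubs()] or plain ESV id vectors.
#' @return A list: `presence` (logical matrix hubs x subnetworks),
#'   `clustering` (hclust), `groups` (two-group cut), `specialist_hubs`
#'   (tibble `esv_id`, `environment`), `n_specialist`.
#' @export
hub_presence_clustering <- function(hub_lists) {
  if (length(hub_lists) < 2)
    abort("At least 2 subnetworks are required.")
  sets <- lapply(hub_lists, function(h)
    if (is.data.frame(h)) h$esv_id else as.character(h))
  all_hubs <- sort(unique(unlist(sets)))
  presence <- vapply(sets, function(s) all_hubs %in% s,
                     logical(length(all_hubs)))
  rownames(presence) <- all_hubs
  k <- length(sets)
  d <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 1 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  hc <- hclust(as.dist(d), method = "average")
  n_pres <- rowSums(presence)
  spec <- all_hubs[n_pres == 1]
  spec_env <- vapply(spec, function(h)
    colnames(presence)[which(presence[h, ])[1]], character(1))
  list(presence = presence, clustering = hc, groups = cutree(hc, k = 2),
       specialist_hubs = tibble(esv_id = spec,
                                environment = unname(spec_env)),
       n_specialist = length(spec))
}

#' Negative-edge counts and endpoint class profiles per subnetwork
#'
#' Negative edges (Spearman rho < 0, interpreted as mutual exclusion /
#' competition / niche differentiation) are counted and expressed as a
#' percentage of each subnetwork's edges; both endpoints of every negative
#' edge are tabulated at class rank.
#'
#' @param subnets Named list of [cooc_network()]s.
#' @param taxonomy Optional taxonomy tibble with `esv_id` and `class`.
#' @return A list: `summary` (tibble `environment`, `n_edges`,
#'   `n_negative`, `pct_negative`) and `composition` (tibble `environment`,
#'   `class`, `n`, counting both endpoints).
#' @export
negative_edge_profile <- function(subnets, taxonomy = NULL) {
  tax_class <- if (!is.null(taxonomy) && "class" %in% names(taxonomy)) {
    setNames(taxonomy$class, taxonomy$esv_id)
  } else NULL
  summaries <- list()
  comps <- list()
  for (e in names(subnets)) {
    de <- distinct_edges(subnets[[e]])
    n_edges <- nrow(de)
    neg <- de[de$sign < 0, , drop = FALSE]
    summaries[[e]] <- tibble(
      environment = e, n_edges = n_edges, n_negative = nrow(neg),
      pct_negative = if (n_edges > 0) 100 * nrow(neg) / n_edges
                     else NA_real_)
    if (nrow(neg) > 0) {
      ids <- c(neg$esv_a, neg$esv_b)
      cls <- if (!is.null(tax_class)) {
        cl <- tax_class[ids]
        cl[is.na(cl)] <- "unclassified"
        cl
      } else rep("unclassified", length(ids))
      comps[[e]] <- tibble(environment = e, class = cls) |>
        dplyr::count(.data$environment, .data$class, name = "n")
    }
  }
  list(summary = dplyr::bind_rows(summaries),
       composition = dplyr::bind_rows(comps))
}
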