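#' Construct a co-occurrence network
#'
#' A signed, weighted co-occurrence network over ESV vertices. Edges are
#' stored as one record per (unordered pair, environment); a pair present in
#' several environment subnetworks therefore has several records, each
#' keeping that environment's scores and p-values.
#'
#' @param vertices Tibble with at least `esv_id`; typically also
#'   `mean_rel_abundance` and taxonomy columns. Vertices without any
#'   incident edge are dropped (a finalized network has no degree-0
#'   vertices).
#' @param edges Tibble with columns `esv_a`, `esv_b`, `sign`, `rho`,
#'   `bc_sim`, `p_spearman`, `p_bc`, `p_merged`, `p_adjusted`,
#'   `environment`; optionally `direct_score`. Pairs are canonicalized so
#'   `esv_a < esv_b`.
#' @param provenance Optional tibble of per-stage candidate counts.
#' @return An object of class `cooc_network`.
#' @export
cooc_network <- function(vertices, edges, provenance = NULL) {
  edges <- as_tibble(edges)
  vertices <- as_tibble(vertices)
  required <- c("esv_a", "esv_b", "sign", "rho", "bc_sim", "p_spearman",
                "p_bc", "p_merged", "p_adjusted", "environment")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0)
    abort(paste0("Edge table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!"direct_score" %in% names(edges)) edges$direct_score <- NA_real_
  if (nrow(edges) > 0) {
    cp <- canonical_pair(edges$esv_a, edges$esv_b)
    edges$esv_a <- cp$esv_a
    edges$esv_b <- cp$esv_b
    if (any(edges$esv_a == edges$esv_b)) abort("Self-loops are not allowed.")
    rec <- paste(edges$esv_a, edges$esv_b, edges$environment, sep = "\r")
    if (anyDuplicated(rec))
      abort("Duplicate edge record for the same pair and environment.")
    if (any(edges$rho == 0, na.rm = TRUE))
      abort("Retained edges must have nonzero Spearman rho.")
    if (isTRUE(any(edges$sign != sign(edges$rho))))
      abort("Edge sign must equal sign(rho).")
    endpoints <- unique(c(edges$esv_a, edges$esv_b))
    if (!all(endpoints %in% vertices$esv_id))
      abort("Every edge endpoint must be a listed vertex.")
    vertices <- vertices[vertices$esv_id %in% endpoints, , drop = FALSE]
  } else {
    vertices <- vertices[0, , drop = FALSE]
  }
  structure(list(vertices = vertices, edges = edges,
                 provenance = provenance),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  de <- distinct_edges(x)
  envs <- unique(x$edges$environment)
  cat(sprintf("<cooc_network> %d vertices, %d edges (%d records) in %d environment(s)\n",
              nrow(x$vertices), nrow(de), nrow(x$edges), length(envs)))
  invisible(x)
}

#' Collapse edge records to one row per unordered pair
#'
#' @param net A [cooc_network()].
#' @return Tibble with one row per pair: `esv_a`, `esv_b`,
#'   `n_environments`, `environments` (sorted, comma-joined),
#'   `sign` (of the record with largest `|rho|`), `rho` (same record),
#'   `sign_discordant` flag.
#' @export
distinct_edges <- function(net) {
  if (nrow(net$edges) == 0)
    return(tibble(esv_a = character(), esv_b = character(),
                  n_environments = integer(), environments = character(),
                  sign = double(), rho = double(),
                  sign_discordant = logical()))
  net$edges |>
    dplyr::group_by(.data$esv_a, .data$esv_b) |>
    dplyr::summarise(
      n_environments = dplyr::n_distinct(.data$environment),
      environments = paste(sort(unique(.data$environment)), collapse = ","),
      sign_discordant = dplyr::n_distinct(.data$sign) > 1,
      rho = .data$rho[which.max(abs(.data$rho))],
      sign = sign(.data$rho),
      .groups = "drop") |>
    dplyr::select("esv_a", "esv_b", "n_environments", "environments",
                  "sign", "rho", "sign_discordant")
}

as_igraph <- function(net) {
  de <- distinct_edges(net)
  g <- igraph::graph_from_data_frame(
    de[, c("esv_a", "esv_b")], directed = FALSE,
    vertices = net$vertices[order(net$vertices$esv_id), "esv_id",
                            drop = FALSE])
  g
}

#' Merge environment subnetworks into one network
#'
#' Vertex set is the union of vertex sets; edges are unioned under canonical
#' unordered-pair equality, keeping each environment's records (so a pair
#' present in k subnetworks has an environment set of size k). Pairs with
#' conflicting signs across environments are kept once per sign and flagged
#' `sign_discordant` in [distinct_edges()]. Vertices left without any
#' incident edge are dropped.
#'
#' @param nets Named list of [cooc_network()]s, one per environment; each
#'   input must cover a distinct, single environment.
#' @return A merged [cooc_network()].
#' @export
merge_networks <- function(nets) {
  tags <- unlist(lapply(nets, function(n) unique(n$edges$environment)))
  if (anyDuplicated(tags))
    abort("Two input networks share an environment tag.")
  edges <- dplyr::bind_rows(lapply(nets, `[[`, "edges"))
  vertices <- dplyr::bind_rows(lapply(nets, `[[`, "vertices"))
  if (nrow(vertices) > 0) {
    vertices <- vertices |>
      dplyr::group_by(.data$esv_id) |>
      dplyr::summarise(dplyr::across(dplyr::any_of("mean_rel_abundance"),
                                     ~ mean(.x, na.rm = TRUE)),
                       dplyr::across(dplyr::where(is.character), ~ .x[1]),
                       .groups = "drop")
  }
  cooc_network(vertices, edges)
}

#' Write a co-occurrence network to disk
#'
#' `edge-tsv` writes one row per (pair, environment) record with the
#' record's own `environment` plus the pair's full comma-joined
#' `environments` set; `graphml` writes an igraph multigraph (one parallel
#' edge per record) with vertex and edge attributes.
#'
#' @param net A [cooc_network()].
#' @param path Output path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    de <- distinct_edges(net)
    out <- dplyr::left_join(
      net$edges,
      de[, c("esv_a", "esv_b", "environments")],
      by = c("esv_a", "esv_b"))
    out <- dplyr::arrange(out, .data$esv_a, .data$esv_b, .data$environment)
    out <- dplyr::rename(out, bc_similarity = "bc_sim")
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      as.data.frame(net$edges), directed = FALSE,
      vertices = as.data.frame(net$vertices))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-occurrence network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @return A [cooc_network()]. The edge-TSV format carries no vertex
#'   attributes, so vertices are reconstructed from edge endpoints.
#' @export
read_network <- function(path, format = c("edge-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      esv_a = "c", esv_b = "c", environment = "c", environments = "c",
      .default = readr::col_double()), progress = FALSE)
    df <- dplyr::rename(df, bc_sim = "bc_similarity")
    df$environments <- NULL
    vertices <- tibble(esv_id = sort(unique(c(df$esv_a, df$esv_b))))
    cooc_network(vertices, df)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vat <- igraph::as_data_frame(g, what = "vertices")
    eat <- igraph::as_data_frame(g, what = "edges")
    vertices <- as_tibble(vat)
    names(vertices)[names(vertices) == "name"] <- "esv_id"
    edges <- as_tibble(eat)
    names(edges)[names(edges) == "from"] <- "esv_a"
    names(edges)[names(edges) == "to"] <- "esv_b"
    cooc_network(vertices, edges)
  }
}
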