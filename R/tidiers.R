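#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a co-occurrence network into its edge table
#'
#' @param x A [cooc_network()].
#' @param ... Unused.
#' @return The edge tibble, one row per (pair, environment) record.
#' @export
tidy.cooc_network <- function(x, ...) x$edges

#' One-row summary of a co-occurrence network
#'
#' @param x A [cooc_network()].
#' @param ... Unused.
#' @return Tibble: `n_vertices`, `n_edges`, `n_records`,
#'   `n_environments`, `n_negative`, `pct_negative`.
#' @export
glance.cooc_network <- function(x, ...) {
  de <- distinct_edges(x)
  tibble(
    n_vertices = nrow(x$vertices),
    n_edges = nrow(de),
    n_records = nrow(x$edges),
    n_environments = length(unique(x$edges$environment)),
    n_negative = sum(de$sign < 0),
    pct_negative = if (nrow(de) > 0) 100 * mean(de$sign < 0) else NA_real_)
}

#' Tidy a topology report into its module assignment
#'
#' @param x A [topology_report()].
#' @param ... Unused.
#' @return Tibble `esv_id`, `module`.
#' @export
tidy.topology_report <- function(x, ...) x$modules

#' One-row metric summary of a topology report
#'
#' @param x A [topology_report()].
#' @param ... Unused.
#' @return The metrics tibble.
#' @export
glance.topology_report <- function(x, ...) x$metrics

#' Tidy an edge classification
#'
#' @param x An [classify_edges()] result.
#' @param ... Unused.
#' @return The per-edge classification tibble.
#' @export
tidy.edge_classification <- function(x, ...) x$edges

#' Per-subnetwork class proportions of an edge classification
#'
#' @param x An [classify_edges()] result.
#' @param ... Unused.
#' @return The proportions tibble.
#' @export
glance.edge_classification <- function(x, ...) x$proportions
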