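# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

random_counts <- function(p, n, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(p * n, lambda), p, n,
              dimnames = list(sprintf("esv%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  m
}

random_table <- function(p, n, seed = 1, env = "soil", lambda = 20) {
  m <- random_counts(p, n, seed, lambda)
  abundance_table(m, setNames(rep(env, n), colnames(m)))
}

# Hand-built network from an edge data frame (esv_a, esv_b, rho, optionally
# bc_sim); vertices are the endpoints.
make_test_net <- function(edges_df, environment = "env1",
                          abundances = NULL) {
  n <- nrow(edges_df)
  edges <- tibble::tibble(
    esv_a = edges_df$esv_a, esv_b = edges_df$esv_b,
    sign = sign(edges_df$rho), rho = edges_df$rho,
    bc_sim = if ("bc_sim" %in% names(edges_df)) edges_df$bc_sim
             else rep(0.5, n),
    p_spearman = rep(1e-4, n), p_bc = rep(1e-4, n),
    p_merged = rep(1e-5, n), p_adjusted = rep(1e-4, n),
    environment = environment)
  ids <- sort(unique(c(edges$esv_a, edges$esv_b)))
  ab <- if (is.null(abundances)) {
    stats::setNames(seq_along(ids) / (2 * length(ids)), ids)
  } else abundances
  vertices <- tibble::tibble(esv_id = ids,
                             mean_rel_abundance = unname(ab[ids]))
  cooc_network(vertices, edges)
}

# Edge list of an unweighted graph as a test network (all rho = 0.8).
net_from_edges <- function(a, b, environment = "env1") {
  make_test_net(tibble::tibble(esv_a = a, esv_b = b,
                               rho = rep(0.8, length(a))),
                environment = environment)
}

# A small multi-environment planted dataset with its inferred subnetworks,
# shared by ecology tests (kept deliberately small).
planted_three_env <- function() fixture("planted_three_env", function() {
  labs <- default_environment_labels()[1:3]
  pe <- dplyr::bind_rows(
    tibble::tibble(esv_a = 1, esv_b = 2, rho = 0.9,
                   environments = list(labs)),
    tibble::tibble(esv_a = 3, esv_b = 4, rho = 0.9,
                   environments = list(labs[1:2])),
    tibble::tibble(esv_a = 5, esv_b = 6, rho = 0.9,
                   environments = list(labs[1])),
    tibble::tibble(esv_a = 7, esv_b = 8, rho = -0.85,
                   environments = list(labs[2])))
  design <- planted_design(n_environments = 3,
                           samples_per_environment = 80, n_esvs = 25,
                           sequencing_depth = 5000, planted_edges = pe,
                           seed = 33)
  ds <- generate_dataset(design)
  tabs <- split_by_environment(ds$table)
  nets <- infer_all_networks(tabs, infer_config(n_iter = 80, seed = 17))
  list(dataset = ds, tables = tabs, nets = nets)
})
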