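#' The 14 environment labels used throughout the package
#'
#' Level-3 environment ontology categories covering the habitats sampled by
#' large cross-biome amplicon surveys.
#'
#' @return A character vector of length 14.
#' @export
default_environment_labels <- function() {
  c("soil", "rhizosphere", "plant surface", "plant corpus",
    "animal surface", "animal corpus", "animal secretion",
    "animal proximal gut", "animal distal gut", "saline water",
    "non-saline water", "saline sediment", "non-saline sediment",
    "non-saline surface")
}

#' Describe a planted multi-environment community design
#'
#' Parameters of the synthetic-data generator: a Gaussian copula over latent
#' log-abundances plants pairwise monotone associations, and fixed-depth
#' multinomial sampling closes each sample compositionally.
#'
#' @param n_environments Number of environments (<= 14 labelled ones by
#'   default; more get generated labels).
#' @param samples_per_environment Samples drawn per environment.
#' @param n_esvs Number of ESVs.
#' @param sequencing_depth Total counts per sample (multinomial size).
#' @param planted_edges Data frame with columns `esv_a`, `esv_b` (integer
#'   indices or ESV ids), `rho` (latent correlation in \[-1, 1\]) and
#'   optionally `environments` (list-column of environment labels; default
#'   all environments).
#' @param hub_spec Data frame with columns `esv` (index or id) and `degree`:
#'   each hub receives `degree` planted positive partners (latent rho
#'   `hub_rho`) in all environments.
#' @param hub_rho Latent correlation used for hub partner edges.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-ESV baseline
#'   abundances.
#' @param sparsity Per-environment probability that an ESV is present at all
#'   (ESVs involved in planted edges of that environment are always present).
#' @param match_planted_abundance Give the two partners of every planted
#'   edge comparable baseline abundances (log-abundance offset drawn
#'   `N(0, match_sdlog)`). Pairwise association measures on compositional
#'   data are only jointly informative for taxa whose abundance ranges
#'   overlap — Bray-Curtis similarity in particular saturates when one
#'   taxon dwarfs the other — so planted associations are placed between
#'   taxa of the same abundance order, as they would be detectable in a
#'   real survey.
#' @param match_sdlog Standard deviation of the partner log-abundance
#'   offset.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `planted_design`.
#' @export
planted_design <- function(n_environments = 14,
                           samples_per_environment = 60,
                           n_esvs = 150,
                           sequencing_depth = 10000,
                           planted_edges = NULL,
                           hub_spec = NULL,
                           hub_rho = 0.8,
                           base_meanlog = 0,
                           base_sdlog = 1,
                           sparsity = 1,
                           match_planted_abundance = TRUE,
                           match_sdlog = 0.25,
                           seed = 1) {
  stopifnot(n_environments >= 1, samples_per_environment >= 3,
            n_esvs >= 2, sequencing_depth >= 1,
            sparsity > 0, sparsity <= 1)
  labels <- default_environment_labels()
  if (n_environments <= length(labels)) {
    labels <- labels[seq_len(n_environments)]
  } else {
    labels <- c(labels, sprintf("env%02d", seq_len(n_environments - length(labels))))
  }
  esv_ids <- sprintf("esv%04d", seq_len(n_esvs))
  pe <- normalize_planted_edges(planted_edges, esv_ids, labels)
  if (!is.null(hub_spec) && nrow(hub_spec) > 0) {
    pe <- add_hub_edges(pe, hub_spec, hub_rho, esv_ids, labels)
  }
  if (nrow(pe) > 0) {
    if (any(abs(pe$rho) > 1)) abort("|latent correlation| must be <= 1.")
    if (any(pe$esv_a == pe$esv_b)) abort("Planted self-edges are not allowed.")
    if (any(lengths(pe$environments) == 0))
      abort("Planted edges need a non-empty environment subset.")
  }
  structure(list(
    environments = labels,
    samples_per_environment = samples_per_environment,
    esv_ids = esv_ids,
    sequencing_depth = sequencing_depth,
    planted_edges = pe,
    base_meanlog = base_meanlog,
    base_sdlog = base_sdlog,
    sparsity = sparsity,
    match_planted_abundance = isTRUE(match_planted_abundance),
    match_sdlog = match_sdlog,
    seed = as.integer(seed)
  ), class = "planted_design")
}

normalize_planted_edges <- function(planted_edges, esv_ids, labels) {
  if (is.null(planted_edges) || nrow(planted_edges) == 0) {
    return(tibble(esv_a = character(), esv_b = character(),
                  rho = double(), environments = list()))
  }
  pe <- as_tibble(planted_edges)
  to_id <- function(v) if (is.numeric(v)) esv_ids[v] else as.character(v)
  pe$esv_a <- to_id(pe$esv_a)
  pe$esv_b <- to_id(pe$esv_b)
  if (!all(c(pe$esv_a, pe$esv_b) %in% esv_ids))
    abort("Planted edge references an unknown ESV.")
  if (!"environments" %in% names(pe)) {
    pe$environments <- rep(list(labels), nrow(pe))
  } else if (!is.list(pe$environments)) {
    pe$environments <- as.list(pe$environments)
  }
  bad_env <- setdiff(unlist(pe$environments), labels)
  if (length(bad_env) > 0)
    abort(paste0("Planted edge references unknown environment(s): ",
                 paste(bad_env, collapse = ", ")))
  cp <- canonical_pair(pe$esv_a, pe$esv_b)
  pe$esv_a <- cp$esv_a
  pe$esv_b <- cp$esv_b
  pe[, c("esv_a", "esv_b", "rho", "environments")]
}

add_hub_edges <- function(pe, hub_spec, hub_rho, esv_ids, labels) {
  hub_spec <- as_tibble(hub_spec)
  used <- unique(c(pe$esv_a, pe$esv_b))
  for (i in seq_len(nrow(hub_spec))) {
    hub <- hub_spec$esv[i]
    if (is.numeric(hub)) hub <- esv_ids[hub]
    deg <- hub_spec$degree[i]
    if (deg >= length(esv_ids))
      abort("Hub target degree must be smaller than the number of ESVs.")
    partners <- setdiff(esv_ids, c(hub, used))
    if (length(partners) < deg)
      abort("Not enough free ESVs to satisfy hub degrees.")
    partners <- partners[seq_len(deg)]
    cp <- canonical_pair(rep(hub, deg), partners)
    pe <- dplyr::bind_rows(pe, tibble(
      esv_a = cp$esv_a, esv_b = cp$esv_b, rho = hub_rho,
      environments = rep(list(labels), deg)))
    used <- unique(c(used, hub, partners))
  }
  pe
}

# Correlation matrix for one environment with planted entries; repaired to
# positive definiteness by eigenvalue clipping (deterministic), then rescaled
# to unit diagonal.
environment_correlation <- function(design, env) {
  p <- length(design$esv_ids)
  R <- diag(p)
  rownames(R) <- colnames(R) <- design$esv_ids
  pe <- design$planted_edges
  if (nrow(pe) > 0) {
    keep <- vapply(pe$environments, function(e) env %in% e, logical(1))
    for (i in which(keep)) {
      R[pe$esv_a[i], pe$esv_b[i]] <- pe$rho[i]
      R[pe$esv_b[i], pe$esv_a[i]] <- pe$rho[i]
    }
  }
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    vals <- pmax(eg$values, 1e-8)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0) {
      off <- which(abs(R) > 0.999 & row(R) < col(R), arr.ind = TRUE)
      abort(paste0("Planted correlation matrix for environment '", env,
                   "' is not positive semi-definite after repair; ",
                   "offending pairs near |rho| = 1: ",
                   paste(design$esv_ids[off[, 1]], design$esv_ids[off[, 2]],
                         sep = "-", collapse = ", ")))
    }
    rownames(R) <- colnames(R) <- design$esv_ids
  }
  R
}

#' Generate a multi-environment compositional count dataset
#'
#' For each environment, latent per-ESV log-abundances are drawn from a
#' multivariate Gaussian whose correlation matrix embeds the planted latent
#' correlations (Gaussian copula), exponentiated, masked by per-ESV presence,
#' converted to per-sample relative abundances, and counted as a multinomial
#' draw of fixed sequencing depth, so every sample is genuinely
#' compositional.
#'
#' @param design A [planted_design()].
#' @return A list with elements `table` (an [abundance_table()] over all
#'   environments), `truth` (tibble of planted edges: `esv_a`, `esv_b`,
#'   `rho`, `sign`, `environments` list-column) and `metadata` (tibble of
#'   `sample_id`, `environment`).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(design$seed)
  p <- length(design$esv_ids)
  n <- design$samples_per_environment
  base_log <- rnorm(p, design$base_meanlog, design$base_sdlog)
  names(base_log) <- design$esv_ids
  if (design$match_planted_abundance && nrow(design$planted_edges) > 0) {
    pe <- design$planted_edges
    for (i in seq_len(nrow(pe))) {
      base_log[pe$esv_b[i]] <- base_log[pe$esv_a[i]] +
        rnorm(1, 0, design$match_sdlog)
    }
  }
  blocks <- vector("list", length(design$environments))
  envs_of <- character(0)
  for (k in seq_along(design$environments)) {
    env <- design$environments[k]
    R <- environment_correlation(design, env)
    L <- chol(R)
    Z <- t(L) %*% matrix(rnorm(p * n), p, n)
    A <- exp(base_log + Z)
    if (design$sparsity < 1) {
      pe <- design$planted_edges
      protected <- character(0)
      if (nrow(pe) > 0) {
        in_env <- vapply(pe$environments, function(e) env %in% e, logical(1))
        protected <- unique(c(pe$esv_a[in_env], pe$esv_b[in_env]))
      }
      present <- runif(p) <= design$sparsity |
        design$esv_ids %in% protected
      A[!present, ] <- 0
    }
    counts <- vapply(seq_len(n), function(j) {
      s <- sum(A[, j])
      pr <- if (s > 0) A[, j] / s else rep(1 / p, p)
      rmultinom(1, design$sequencing_depth, pr)[, 1]
    }, numeric(p))
    blocks[[k]] <- counts
    envs_of <- c(envs_of, rep(env, n))
  }
  counts <- do.call(cbind, blocks)
  sample_ids <- sprintf("s%05d", seq_len(ncol(counts)))
  dimnames(counts) <- list(design$esv_ids, sample_ids)
  env_map <- setNames(envs_of, sample_ids)
  truth <- design$planted_edges
  truth$sign <- ifelse(truth$rho >= 0, 1, -1)
  list(table = abundance_table(counts, env_map),
       truth = truth[, c("esv_a", "esv_b", "rho", "sign", "environments")],
       metadata = tibble(sample_id = sample_ids, environment = envs_of))
}

#' Generate a synthetic taxonomy for ESV ids
#'
#' Draws ranked lineages from a small pool of plausible (but fabricated)
#' taxon names; purely for exercising taxonomy-aware analyses on synthetic
#' data.
#'
#' @param esv_ids Character vector of ESV ids.
#' @param n_classes,n_genera Pool sizes at class and genus rank.
#' @param seed Integer seed.
#' @return A tibble with columns `esv_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
synthetic_taxonomy <- function(esv_ids, n_classes = 8, n_genera = 25,
                               seed = 1) {
  set.seed(seed)
  classes <- sprintf("Class%02d", seq_len(n_classes))
  genera <- sprintf("Genus%02d", seq_len(n_genera))
  genus_class <- setNames(sample(classes, n_genera, replace = TRUE), genera)
  g <- sample(genera, length(esv_ids), replace = TRUE)
  cl <- unname(genus_class[g])
  tibble(
    esv_id = esv_ids,
    domain = "Bacteria",
    phylum = paste0("Phylum_", substr(cl, 6, 7)),
    class = cl,
    order = paste0("Order_", substr(g, 6, 7)),
    family = paste0("Family_", substr(g, 6, 7)),
    genus = g
  )
}
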