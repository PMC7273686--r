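test_that("edge pairs canonicalize and self-loops are rejected", {
  net <- make_test_net(tibble::tibble(esv_a = "b", esv_b = "a", rho = 0.5))
  expect_identical(net$edges$esv_a, "a")
  expect_identical(net$edges$esv_b, "b")
  expect_error(
    make_test_net(tibble::tibble(esv_a = "a", esv_b = "a", rho = 0.5)),
    "Self-loops")
  expect_error(
    make_test_net(tibble::tibble(esv_a = c("a", "b"), esv_b = c("b", "a"),
                                 rho = c(0.5, 0.5))),
    "Duplicate edge record")
})

test_that("degree-zero vertices are dropped at construction", {
  edges <- tibble::tibble(
    esv_a = "a", esv_b = "b", sign = 1, rho = 0.6, bc_sim = 0.5,
    p_spearman = 1e-3, p_bc = 1e-3, p_merged = 1e-4, p_adjusted = 1e-3,
    environment = "soil")
  vertices <- tibble::tibble(esv_id = c("a", "b", "lonely"),
                             mean_rel_abundance = c(0.1, 0.2, 0.3))
  net <- cooc_network(vertices, edges)
  expect_setequal(net$vertices$esv_id, c("a", "b"))
})

test_that("an empty network writes and reads back in both formats", {
  empty <- cooc_network(
    tibble::tibble(esv_id = character(), mean_rel_abundance = double()),
    tibble::tibble(esv_a = character(), esv_b = character(),
                   sign = double(), rho = double(), bc_sim = double(),
                   p_spearman = double(), p_bc = double(),
                   p_merged = double(), p_adjusted = double(),
                   environment = character()))
  for (fmt in c("edge-tsv", "graphml")) {
    path <- withr::local_tempfile()
    write_network(empty, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_equal(nrow(back$edges), 0)
  }
})

test_that("networks round-trip through edge-TSV exactly", {
  set.seed(15)
  n <- 100
  ids <- sprintf("esv%03d", 1:40)
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), n)
  rho <- runif(n, -1, 1)
  rho[rho == 0] <- 0.1
  edges <- tibble::tibble(
    esv_a = pairs[pick, 1], esv_b = pairs[pick, 2],
    sign = sign(rho), rho = rho, bc_sim = runif(n),
    p_spearman = runif(n), p_bc = runif(n), p_merged = runif(n),
    p_adjusted = runif(n),
    environment = sample(c("soil", "saline water"), n, replace = TRUE))
  net <- cooc_network(tibble::tibble(esv_id = ids,
                                     mean_rel_abundance = runif(40)),
                      edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, format = "edge-tsv")
  back <- read_network(path, format = "edge-tsv")
  ord <- function(e) e[order(e$esv_a, e$esv_b, e$environment), ]
  expect_equal(ord(back$edges)[names(net$edges)], ord(net$edges),
               tolerance = 1e-12)
})

test_that("networks round-trip through GraphML with attributes intact", {
  set.seed(16)
  net <- make_test_net(tibble::tibble(
    esv_a = c("a", "a", "b"), esv_b = c("b", "c", "c"),
    rho = c(0.8, -0.5, 0.3), bc_sim = c(0.7, 0.1, 0.6)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  back <- read_network(path, format = "graphml")
  ord <- function(e) e[order(e$esv_a, e$esv_b), ]
  expect_equal(ord(back$edges)[names(net$edges)], ord(net$edges),
               tolerance = 1e-9)
  expect_equal(back$vertices[order(back$vertices$esv_id), ]$mean_rel_abundance,
               net$vertices[order(net$vertices$esv_id), ]$mean_rel_abundance,
               tolerance = 1e-9)
})

test_that("merging disjoint networks is a disjoint union", {
  n1 <- make_test_net(tibble::tibble(esv_a = c("a", "b"),
                                     esv_b = c("b", "c"),
                                     rho = c(0.5, 0.6)),
                      environment = "soil")
  n2 <- make_test_net(tibble::tibble(esv_a = "x", esv_b = "y", rho = 0.7),
                      environment = "saline water")
  merged <- merge_networks(list(n1, n2))
  expect_equal(nrow(merged$vertices), 5)
  expect_equal(nrow(distinct_edges(merged)), 3)
})

test_that("a shared edge accumulates its environment set", {
  n1 <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = 0.5),
                      environment = "soil")
  n2 <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = 0.6),
                      environment = "rhizosphere")
  merged <- merge_networks(list(n1, n2))
  de <- distinct_edges(merged)
  expect_equal(de$n_environments, 2)
  expect_identical(de$environments, "rhizosphere,soil")
  expect_false(de$sign_discordant)
})

test_that("sign-discordant shared edges are kept per sign and flagged", {
  n1 <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = 0.5),
                      environment = "soil")
  n2 <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = -0.5),
                      environment = "rhizosphere")
  merged <- merge_networks(list(n1, n2))
  expect_equal(nrow(merged$edges), 2)
  expect_true(distinct_edges(merged)$sign_discordant)
})

test_that("duplicate environment tags are rejected when merging", {
  n1 <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = 0.5),
                      environment = "soil")
  n2 <- make_test_net(tibble::tibble(esv_a = "c", esv_b = "d", rho = 0.5),
                      environment = "soil")
  expect_error(merge_networks(list(n1, n2)), "share an environment tag")
})

test_that("merging is commutative and bounded by the edge-count sum", {
  set.seed(31)
  make_random <- function(env, seed) {
    set.seed(seed)
    ids <- sprintf("v%02d", 1:12)
    pairs <- t(combn(ids, 2))
    pick <- sample(nrow(pairs), 15)
    make_test_net(tibble::tibble(esv_a = pairs[pick, 1],
                                 esv_b = pairs[pick, 2],
                                 rho = runif(15, 0.3, 0.9)),
                  environment = env)
  }
  a <- make_random("soil", 1)
  b <- make_random("saline water", 2)
  ab <- merge_networks(list(a, b))
  ba <- merge_networks(list(b, a))
  ord <- function(net) {
    e <- net$edges
    e[order(e$esv_a, e$esv_b, e$environment), ]
  }
  expect_equal(ord(ab), ord(ba))
  n_shared <- nrow(dplyr::inner_join(
    distinct_edges(a)[, c("esv_a", "esv_b")],
    distinct_edges(b)[, c("esv_a", "esv_b")], by = c("esv_a", "esv_b")))
  expect_equal(nrow(distinct_edges(ab)), 30 - n_shared)
  expect_lte(nrow(distinct_edges(ab)),
             nrow(distinct_edges(a)) + nrow(distinct_edges(b)))
  # environment sets are non-empty subsets of the input tags
  de <- distinct_edges(ab)
  envs <- unique(unlist(strsplit(de$environments, ",")))
  expect_true(all(envs %in% c("soil", "saline water")))
  expect_true(all(de$n_environments >= 1))
})
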