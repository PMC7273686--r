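test_that("a triangle has the hand-derived metric values", {
  k3 <- net_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  rep <- topology_report(k3)
  g <- glance(rep)
  expect_equal(g$edge_count, 3)
  expect_equal(g$diameter, 1)
  expect_equal(g$clustering_coefficient, 1)
  expect_equal(g$average_separation, 1)
  expect_equal(g$mean_betweenness, 0)
  expect_equal(g$modularity, 0)
  expect_equal(length(unique(rep$modules$module)), 1)
})

test_that("a four-vertex path has diameter 3 and mean betweenness 1", {
  p4 <- net_from_edges(c("a", "b", "c"), c("b", "c", "d"))
  g <- glance(topology_report(p4))
  expect_equal(g$diameter, 3)
  expect_equal(g$mean_betweenness, 1)          # (0 + 2 + 2 + 0) / 4
  expect_equal(g$clustering_coefficient, 0)    # trees have no triangles
})

test_that("two disjoint triangles split into modules with Q = 0.5", {
  two <- net_from_edges(c("a", "a", "b", "x", "x", "y"),
                        c("b", "c", "c", "y", "z", "z"))
  rep <- topology_report(two)
  g <- glance(rep)
  expect_equal(g$modularity, 0.5)
  expect_equal(g$n_components, 2)
  mods <- setNames(rep$modules$module, rep$modules$esv_id)
  expect_equal(length(unique(mods[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mods[c("x", "y", "z")])), 1)
  expect_false(mods[["a"]] == mods[["x"]])
  # greedy Q equals the definitional recomputation
  expect_equal(g$modularity,
               modularity_oracle(distinct_edges(two), mods),
               tolerance = 1e-10)
})

test_that("modularity matches its definitional recomputation on random graphs", {
  set.seed(23)
  for (rep_i in 1:3) {
    ids <- sprintf("v%02d", 1:15)
    pairs <- t(combn(ids, 2))
    pick <- sample(nrow(pairs), 25)
    net <- net_from_edges(pairs[pick, 1], pairs[pick, 2])
    rep <- topology_report(net)
    mods <- setNames(rep$modules$module, rep$modules$esv_id)
    expect_equal(glance(rep)$modularity,
                 modularity_oracle(distinct_edges(net), mods),
                 tolerance = 1e-10)
    # diameter bounds the average separation
    g <- glance(rep)
    expect_gte(g$diameter, g$average_separation)
  }
})

test_that("complete graphs have unit clustering and zero betweenness", {
  ids <- c("a", "b", "c", "d", "e")
  pairs <- t(combn(ids, 2))
  k5 <- net_from_edges(pairs[, 1], pairs[, 2])
  g <- glance(topology_report(k5))
  expect_equal(g$clustering_coefficient, 1)
  expect_equal(g$mean_betweenness, 0)
})

test_that("an empty network reports zeros with undefined diameter", {
  empty <- cooc_network(
    tibble::tibble(esv_id = character(), mean_rel_abundance = double()),
    tibble::tibble(esv_a = character(), esv_b = character(),
                   sign = double(), rho = double(), bc_sim = double(),
                   p_spearman = double(), p_bc = double(),
                   p_merged = double(), p_adjusted = double(),
                   environment = character()))
  g <- glance(topology_report(empty))
  expect_equal(g$edge_count, 0)
  expect_true(is.na(g$diameter))
})

test_that("exact power-law degree histograms fit with slope -2", {
  # freq(k) = 64 / k^2 for k in {1, 2, 4, 8}: 64 + 16 + 4 + 1 vertices
  deg <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  g <- igraph::realize_degseq(deg)
  el <- igraph::as_edgelist(g)
  net <- net_from_edges(sprintf("v%02d", el[, 1]), sprintf("v%02d", el[, 2]))
  fit <- scale_free_fit(net)
  expect_gte(fit$r_squared, 0.99)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
})

test_that("degenerate degree distributions are handled", {
  # regular graph: every degree equal, fit undefined
  ids <- c("a", "b", "c")
  k3 <- net_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  expect_true(is.na(scale_free_fit(k3)$r_squared))
  # star: two distinct degrees determine the line exactly
  star <- net_from_edges(rep("hub", 5), paste0("leaf", 1:5))
  fit <- scale_free_fit(star)
  expect_equal(fit$r_squared, 1)
})

test_that("abundance-degree association detects a planted hub", {
  # hub with inflated abundance vs leaves in a chain
  edges <- tibble::tibble(
    esv_a = c(rep("hub", 6), "leaf1", "leaf2"),
    esv_b = c(paste0("leaf", 1:6), "leaf3", "leaf4"),
    rho = rep(0.8, 8))
  ab <- setNames(c(0.5, 0.06, 0.05, 0.04, 0.03, 0.01, 0.02),
                 c("hub", paste0("leaf", 1:6)))
  net <- make_test_net(edges, abundances = ab)
  res <- abundance_degree_association(net)
  expect_gt(res$rho, 0)

  # constant abundance: undefined with documented NA
  star <- make_test_net(
    tibble::tibble(esv_a = rep("hub", 4), esv_b = paste0("l", 1:4),
                   rho = rep(0.8, 4)),
    abundances = setNames(rep(0.2, 5), c("hub", paste0("l", 1:4))))
  expect_true(is.na(abundance_degree_association(star)$rho))

  one <- make_test_net(tibble::tibble(esv_a = "a", esv_b = "b", rho = 0.5))
  expect_error(abundance_degree_association(one), "3 vertices")
})

test_that("module composition tabulates classes, environments and coverage", {
  net <- net_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  rep <- topology_report(net)
  tax <- tibble::tibble(esv_id = c("a", "b", "c"),
                        class = c("A", "A", "B"))
  mc <- module_composition(net, rep, taxonomy = tax)
  expect_equal(sort(mc$class_composition$fraction), c(1 / 3, 2 / 3))
  expect_equal(mc$top_coverage, 1)

  # ten disjoint dyads: top-8 coverage is 16/20
  a <- sprintf("p%02d", 1:10)
  b <- sprintf("q%02d", 1:10)
  net10 <- net_from_edges(a, b)
  rep10 <- topology_report(net10)
  mc10 <- module_composition(net10, rep10, taxonomy = NULL, top_n = 8)
  expect_equal(mc10$top_coverage, 16 / 20)
  expect_true(all(mc10$class_composition$class == "unclassified"))
})
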