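three_subnets <- function() {
  # soil: a-b (shared), c-d (endpoints general), e-f (f unique to soil)
  # rhizosphere: a-b, c-x, e-y
  # plant surface: c-z, d-w
  list(
    soil = make_test_net(tibble::tibble(
      esv_a = c("a", "c", "e"), esv_b = c("b", "d", "f"),
      rho = c(0.8, 0.7, -0.6)), environment = "soil"),
    rhizosphere = make_test_net(tibble::tibble(
      esv_a = c("a", "c", "e"), esv_b = c("b", "x", "y"),
      rho = c(0.9, 0.5, 0.5)), environment = "rhizosphere"),
    `plant surface` = make_test_net(tibble::tibble(
      esv_a = c("c", "d"), esv_b = c("z", "w"),
      rho = c(0.6, 0.6)), environment = "plant surface"))
}

test_that("edges classify into generalist and the two specialist groups", {
  cls <- classify_edges(three_subnets())
  edges <- tidy(cls)
  get_class <- function(a, b)
    edges$class[edges$esv_a == a & edges$esv_b == b]
  expect_equal(get_class("a", "b"), "generalist")
  # c and d both appear as vertices in >= 2 subnetworks
  expect_equal(get_class("c", "d"), "specialist_generalist_pair")
  # f appears only in soil
  expect_equal(get_class("e", "f"), "specialist_specialist_pair")
  expect_error(classify_edges(three_subnets()[1]), "At least 2")
})

test_that("per-subnetwork class proportions sum to one", {
  props <- glance(classify_edges(three_subnets()))
  sums <- props |>
    dplyr::group_by(environment) |>
    dplyr::summarise(s = sum(proportion))
  expect_equal(sums$s, rep(1, 3))
  expect_true(all(props$n >= 0))
})

test_that("omission scores expose environment-driven edges", {
  # edge correlated only inside "soil"; omitting soil destroys it
  set.seed(55)
  n_soil <- 40; n_rest <- 80; n_all <- n_soil + n_rest
  x_soil <- rlnorm(n_soil); y_soil <- x_soil * exp(rnorm(n_soil, 0, 0.1))
  x_rest <- rlnorm(n_rest); y_rest <- rlnorm(n_rest)
  background <- matrix(rpois(30 * n_all, 500), 30, n_all,
                       dimnames = list(sprintf("bg%02d", 1:30), NULL))
  counts <- rbind(
    a = round(1000 * c(x_soil, x_rest)),
    b = round(1000 * c(y_soil, y_rest)),
    background)
  colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  env <- setNames(rep(c("soil", "other"), c(n_soil, n_rest)),
                  colnames(counts))
  tab <- abundance_table(counts, env)
  res <- omission_score(tab, c("a", "b"), "soil", n_random = 300, seed = 2)
  expect_lt(res$ratio, 1)
  expect_lt(res$p, 0.05)
  # determinism
  res2 <- omission_score(tab, c("a", "b"), "soil", n_random = 300, seed = 2)
  expect_equal(res, res2)
})

test_that("omission p-values are roughly uniform under exchangeability", {
  set.seed(66)
  n <- 90
  env <- setNames(rep(c("soil", "other"), c(30, 60)), sprintf("s%03d", 1:n))
  ps <- vapply(1:25, function(i) {
    counts <- rbind(a = rpois(n, 300), b = rpois(n, 300),
                    matrix(rpois(20 * n, 300), 20, n,
                           dimnames = list(sprintf("bg%02d", 1:20), NULL)))
    colnames(counts) <- names(env)
    tab <- abundance_table(counts, env)
    omission_score(tab, c("a", "b"), "soil", n_random = 100,
                   seed = i)$p
  }, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("omission analysis adjusts p-values and flags local edges", {
  subnets <- planted_three_env()
  pooled <- subnets$dataset$table
  requests <- tibble::tibble(esv_a = c("esv0001", "esv0003"),
                             esv_b = c("esv0002", "esv0004"),
                             environment = "soil")
  res <- omission_analysis(pooled, requests, n_random = 100, seed = 3)
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted >= res$p))
  expect_type(res$local, "logical")
})

test_that("environment similarity is a Jaccard distance on edge sets", {
  n1 <- make_test_net(tibble::tibble(
    esv_a = c("a", "b", "c"), esv_b = c("b", "c", "d"),
    rho = rep(0.5, 3)), environment = "e1")
  n2same <- make_test_net(tibble::tibble(
    esv_a = c("a", "b", "c"), esv_b = c("b", "c", "d"),
    rho = rep(0.7, 3)), environment = "e2")
  n3 <- make_test_net(tibble::tibble(
    esv_a = c("b", "c", "d"), esv_b = c("c", "d", "e"),
    rho = rep(0.5, 3)), environment = "e3")
  n4 <- make_test_net(tibble::tibble(
    esv_a = c("p", "q"), esv_b = c("q", "r"), rho = rep(0.5, 2)),
    environment = "e4")
  sim <- environment_similarity(list(e1 = n1, e2 = n2same, e3 = n3,
                                     e4 = n4))
  expect_equal(sim$distance["e1", "e2"], 0)
  expect_equal(sim$distance["e1", "e4"], 1)
  # edge sets {ab, bc, cd} vs {bc, cd, de}: 1 - 2/4
  expect_equal(sim$distance["e1", "e3"], 0.5)
  expect_length(unique(sim$groups), 2)
})

test_that("Jaccard distances satisfy the triangle inequality", {
  set.seed(77)
  universe <- sprintf("v%02d", 1:10)
  pairs <- t(combn(universe, 2))
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) {
      pick <- sample(nrow(pairs), sample(3:10, 1))
      make_test_net(tibble::tibble(esv_a = pairs[pick, 1],
                                   esv_b = pairs[pick, 2],
                                   rho = rep(0.5, length(pick))),
                    environment = paste0("e", j))
    })
    names(sets) <- paste0("e", 1:3)
    d <- environment_similarity(sets)$distance
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("edge-type taxon profiles rank endpoints by abundance", {
  cls <- classify_edges(three_subnets())
  counts <- matrix(rep(c(800, 400, 200, 100, 50, 25, 12, 6, 3, 2, 1), 4),
                   nrow = 11, ncol = 4,
                   dimnames = list(
                     c("a", "b", "c", "d", "e", "f", "x", "y", "z", "w", "u"),
                     sprintf("s%d", 1:4)))
  tab <- abundance_table(counts)
  prof <- edge_type_taxa_profile(cls, tab, top_n = 2)
  gen <- prof$top_esvs[prof$top_esvs$class == "generalist", ]
  expect_equal(nrow(gen), 2)   # a and b, the only generalist endpoints
  expect_setequal(gen$esv_id, c("a", "b"))
  sgp <- prof$top_esvs[prof$top_esvs$class == "specialist_generalist_pair", ]
  # top 2 of {c, d, x} by abundance
  expect_identical(sgp$esv_id, c("c", "d"))
  prof_all <- edge_type_taxa_profile(cls, tab, top_n = 50)
  expect_true(all(table(prof_all$top_esvs$class) <= 50))
})

test_that("edge-type correlations recover complementarity and need four points", {
  props <- tibble::tibble(
    environment = rep(sprintf("e%d", 1:5), each = 3),
    class = rep(c("generalist", "specialist_generalist_pair",
                  "specialist_specialist_pair"), 5),
    n = rep(c(2L, 1L, 1L), 5),
    n_edges = rep(10L, 15),
    proportion = as.vector(vapply(1:5, function(i) {
      g <- 0.1 * i
      c(g, 0.2, 0.8 - g)
    }, numeric(3))))
  res <- edge_type_correlations(props)
  row <- res[res$var_a == "generalist" &
               res$var_b == "specialist_specialist_pair", ]
  expect_equal(row$rho, -1)
  const <- res[res$var_a == "generalist" &
                 res$var_b == "specialist_generalist_pair", ]
  expect_true(is.na(const$rho))  # the constant proportion is undefined
  expect_error(edge_type_correlations(props[props$environment %in%
                                              c("e1", "e2", "e3"), ]),
               "At least 4")
})

test_that("hub identification is deterministic under ties and order", {
  star <- net_from_edges(rep("hub", 5), paste0("l", 1:5))
  expect_identical(identify_hubs(star, k = 1)$esv_id, "hub")

  set.seed(88)
  ids <- sprintf("v%02d", 1:12)
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), 20)
  net <- net_from_edges(pairs[pick, 1], pairs[pick, 2])
  hubs <- identify_hubs(net, k = 4)
  de <- distinct_edges(net)
  deg <- sort(table(c(de$esv_a, de$esv_b)), decreasing = TRUE)
  expect_equal(sort(hubs$degree, decreasing = TRUE),
               as.integer(deg[1:4]))
  # input order invariance
  shuffled <- net_from_edges(pairs[rev(pick), 1], pairs[rev(pick), 2])
  expect_identical(identify_hubs(shuffled, k = 4)$esv_id, hubs$esv_id)

  small <- net_from_edges(c("a", "b"), c("b", "c"))
  out <- identify_hubs(small, k = 10)
  expect_equal(nrow(out), 3)
  expect_true(attr(out, "truncated"))
})

test_that("hub presence clustering counts specialist hubs", {
  same <- list(e1 = c("h1", "h2"), e2 = c("h1", "h2"))
  res <- hub_presence_clustering(same)
  expect_equal(res$n_specialist, 0)
  expect_equal(unname(res$clustering$height), 0)

  disjoint <- list(e1 = c("h1", "h2"), e2 = c("h3", "h4"))
  res2 <- hub_presence_clustering(disjoint)
  expect_equal(res2$n_specialist, 4)

  three <- list(e1 = c("a", "b", "c"), e2 = c("b", "c", "d"),
                e3 = c("c", "e", "f"))
  res3 <- hub_presence_clustering(three)
  # a, d, e, f occur once; b twice; c three times
  expect_equal(res3$n_specialist, 4)
  expect_setequal(res3$specialist_hubs$esv_id, c("a", "d", "e", "f"))
})

test_that("negative-edge profiles count signs and endpoint classes", {
  set.seed(99)
  ids <- sprintf("v%02d", 1:11)
  rho <- c(-0.5, rep(0.5, 9))
  net <- make_test_net(tibble::tibble(
    esv_a = ids[1:10], esv_b = ids[2:11], rho = rho),
    environment = "soil")
  prof <- negative_edge_profile(list(soil = net))
  expect_equal(prof$summary$pct_negative, 10)

  all_pos <- make_test_net(tibble::tibble(
    esv_a = "a", esv_b = "b", rho = 0.5), environment = "e")
  expect_equal(negative_edge_profile(list(e = all_pos))$summary$pct_negative,
               0)

  # both endpoints counted: negative edges (p,q) and (p,r)
  tax <- tibble::tibble(esv_id = c("p", "q", "r"),
                        class = c("A", "B", "C"))
  neg2 <- make_test_net(tibble::tibble(
    esv_a = c("p", "p"), esv_b = c("q", "r"), rho = c(-0.5, -0.6)),
    environment = "e")
  comp <- negative_edge_profile(list(e = neg2), taxonomy = tax)$composition
  counts <- setNames(comp$n, comp$class)
  expect_equal(counts[["A"]], 2)
  expect_equal(counts[["B"]], 1)
  expect_equal(counts[["C"]], 1)
})
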