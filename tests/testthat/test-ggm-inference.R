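test_that("config validates K range and dmax", {
  expect_warning(ggm_config(K = 1.5), "customary")
  expect_warning(ggm_config(K = 6), "customary")
  expect_silent(ggm_config(K = 3))
  expect_error(ggm_config(dmax = 0))
})

test_that("the candidate family always contains the empty graph and caps degree", {
  x <- matrix(rnorm(2000 * 10), 2000, 10,
              dimnames = list(NULL, sprintf("v%02d", 1:10)))
  fam <- nodewise_lasso_family(x, ggm_config(dmax = 3))
  expect_equal(n_edges(fam$graphs[[1]]), 0L)
  expect_true(0L %in% fam$levels)
  for (g in fam$graphs)
    expect_true(all(network_degrees(g, colnames(x)) <= 3))
  # dmax = 1: every candidate neighborhood has size <= 1
  fam1 <- nodewise_lasso_family(x, ggm_config(dmax = 1))
  expect_true(all(lengths(fam1$entry_orders) <= 1))
})

test_that("chain data put chain neighbors first on interior nodes' paths", {
  nodes <- sprintf("v%02d", 1:8)
  pr <- graph_to_precision(chain_network(nodes), nodes, 0.35, seed = 5)
  x <- sample_mvn_from_precision(pr$omega, 2000, seed = 6)
  fam <- nodewise_lasso_family(x, ggm_config(dmax = 3))
  for (i in 2:7) {
    first_two <- fam$entry_orders[[nodes[i]]][1:2]
    expect_setequal(first_two, nodes[c(i - 1, i + 1)])
  }
})

test_that("selection criterion matches its closed form on the empty graph", {
  set.seed(7)
  x <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, letters[1:6]))
  xs <- scale(x)
  empty <- undirected_network(character(0), character(0))
  expect_equal(selection_criterion(xs, empty, K = 2),
               sum(apply(xs, 2, function(y) sum((y - mean(y))^2))))
  # huge K: any non-empty graph scores worse than empty
  one <- undirected_network("a", "b")
  expect_gt(selection_criterion(xs, one, K = 1e6),
            selection_criterion(xs, empty, K = 1e6))
})

test_that("criterion ordering agrees with an independent lm-based oracle", {
  # collider: c depends on a and b
  set.seed(8)
  n <- 300
  a <- rnorm(n); b <- rnorm(n); cc <- 0.7 * a + 0.7 * b + rnorm(n, sd = 0.5)
  x <- cbind(a = a, b = b, c = cc)
  graphs <- all_graphs(colnames(x))
  mine <- vapply(graphs, function(g) selection_criterion(scale(x), g, K = 2.5),
                 numeric(1))
  oracle <- vapply(graphs, function(g) brute_force_criterion(x, g, K = 2.5),
                   numeric(1))
  expect_equal(order(mine), order(oracle))
  expect_equal(mine, oracle, tolerance = 1e-8)
})

test_that("family selection equals exhaustive search over the same family (p <= 5)", {
  nodes <- sprintf("v%d", 1:5)
  pr <- graph_to_precision(chain_network(nodes), nodes, 0.4, seed = 9)
  x <- sample_mvn_from_precision(pr$omega, 500, seed = 10)
  cfg <- ggm_config(K = 2, dmax = 3)
  fam <- nodewise_lasso_family(x, cfg)
  fit <- select_graph(x, cfg, family = fam)
  all_crit <- vapply(seq_len(nrow(fit$family_table)), function(i)
    fit$family_table$criterion[i], numeric(1))
  expect_equal(fit$criterion_value, min(all_crit))
  # brute-force check over the recorded family members' criteria
  expect_equal(fit$criterion_value,
               min(vapply(fam$graphs, function(g)
                 brute_force_criterion(x, g, K = 2), numeric(1)),
                 fit$criterion_value))
})

test_that("independent data select an (almost) empty graph", {
  counts <- sapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1000 * 20), 1000, 20,
                dimnames = list(NULL, sprintf("u%02d", 1:20)))
    n_edges(select_graph(x, ggm_config(K = 2, dmax = 5))$graph)
  })
  expect_true(all(counts <= 1))
})

test_that("chain structure is recovered at n = 1000", {
  nodes <- sprintf("v%02d", 1:15)
  chain <- chain_network(nodes)
  f1 <- sapply(1:5, function(s) {
    pr <- graph_to_precision(chain, nodes, 0.35, seed = s)
    x <- sample_mvn_from_precision(pr$omega, 1000, seed = s + 40)
    edge_f1(select_graph(x, ggm_config(K = 2, dmax = 5))$graph, chain)
  })
  expect_gte(mean(f1), 0.95)
})

test_that("selected degree caps and penalty monotonicity hold", {
  nodes <- sprintf("v%02d", 1:20)
  sp <- synthetic_spec(p = 20, n_edges = c(ND = 15, HFD = 15), target_esd = 1,
                       degree_cap = 4, differentiator_size = 0,
                       phenotype_size = 0, seed = 3)
  g <- make_condition_graphs(sp)$graph_ND
  pr <- graph_to_precision(g, synthetic_metabolite_ids(sp), 0.35, seed = 44)
  x <- sample_mvn_from_precision(pr$omega, 800, seed = 45)
  for (dmax in c(1, 3, 5)) {
    fit <- select_graph(x, ggm_config(K = 2, dmax = dmax))
    expect_true(all(network_degrees(fit$graph, colnames(x)) <= dmax))
  }
  counts_k <- sapply(c(2, 3, 5), function(K)
    n_edges(select_graph(x, ggm_config(K = K, dmax = 5))$graph))
  expect_true(all(diff(counts_k) <= 0))
  counts_d <- sapply(c(1, 3, 5), function(d)
    n_edges(select_graph(x, ggm_config(K = 2, dmax = d))$graph))
  expect_true(all(diff(counts_d) >= 0))
})

test_that("ill-posed settings raise the documented guards", {
  x_small <- matrix(rnorm(6 * 6), 6, 6, dimnames = list(NULL, letters[1:6]))
  expect_warning(nodewise_lasso_family(x_small, ggm_config(dmax = 5)),
                 "ill-posed")
  expect_error(nodewise_lasso_family(x_small[1:2, ], ggm_config()),
               "at least 3")
  xz <- cbind(x_small, const = 1)
  expect_warning(ggm_design_matrix <- metshift:::ggm_design_matrix(xz),
                 "zero-variance")
})

test_that("the or-rule yields a supergraph of the and-rule, still degree-capped", {
  nodes <- sprintf("v%02d", 1:12)
  pr <- graph_to_precision(chain_network(nodes), nodes, 0.35, seed = 12)
  x <- sample_mvn_from_precision(pr$omega, 600, seed = 13)
  f_and <- select_graph(x, ggm_config(K = 2, dmax = 4, symmetrize = "and"))
  f_or <- select_graph(x, ggm_config(K = 2, dmax = 4, symmetrize = "or"))
  expect_true(all(network_degrees(f_or$graph, nodes) <= 4))
  expect_gte(n_edges(f_or$graph), 0)
})

test_that("the (K, dmax) sweep reports plateaus", {
  nodes <- sprintf("v%02d", 1:15)
  pr <- graph_to_precision(chain_network(nodes), nodes, 0.35, seed = 21)
  x <- sample_mvn_from_precision(pr$omega, 600, seed = 22)
  sw <- sweep_k_dmax(x, K_values = c(2, 4), dmax_values = 1:4)
  expect_equal(dim(sw$edge_counts), c(2L, 4L))
  expect_equal(nrow(sw$plateaus), 2L)
  # single-dmax grid: trivial plateau
  sw1 <- sweep_k_dmax(x, K_values = 2, dmax_values = 1)
  expect_equal(sw1$plateaus$dmax_from, 1L)
  expect_equal(sw1$plateaus$dmax_to, 1L)
})
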