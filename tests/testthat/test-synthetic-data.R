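test_that("condition graphs hit the feasible shared-edge count nearest the target esd", {
  sp0 <- synthetic_spec(p = 20, n_edges = c(ND = 10, HFD = 10), target_esd = 0,
                        degree_cap = 4, differentiator_size = 0,
                        phenotype_size = 0, seed = 1)
  g0 <- make_condition_graphs(sp0)
  expect_equal(g0$graph_ND, g0$graph_HFD)
  expect_equal(g0$realized_esd, 0)

  sp1 <- synthetic_spec(p = 30, n_edges = c(ND = 10, HFD = 12), target_esd = 1,
                        degree_cap = 4, differentiator_size = 0,
                        phenotype_size = 0, seed = 2)
  g1 <- make_condition_graphs(sp1)
  expect_equal(n_edges(edge_intersect(g1$graph_ND, g1$graph_HFD)), 0L)
  expect_equal(g1$realized_esd, 1)

  # the emulated study's scale: 57 and 93 edges at esd 0.786 -> s = 16
  sp <- synthetic_spec(seed = 5)
  g <- make_condition_graphs(sp)
  expect_equal(g$shared_edges, 16L)
  expect_equal(g$realized_esd, 118 / 150)
  expect_equal(n_edges(g$graph_ND), 57L)
  expect_equal(n_edges(g$graph_HFD), 93L)
  expect_true(all(network_degrees(g$graph_HFD) <= sp$degree_cap))

  # infeasible: esd 0 needs equal edge counts
  expect_error(make_condition_graphs(
    synthetic_spec(p = 30, n_edges = c(ND = 5, HFD = 15), target_esd = 0,
                   differentiator_size = 0, phenotype_size = 0)),
    "infeasible")
})

test_that("realized esd equals the feasible value nearest the target, exactly", {
  set.seed(99)
  for (i in 1:25) {
    e1 <- sample(5:40, 1); e2 <- sample(5:40, 1)
    target <- runif(1, (e1 + e2 - 2 * min(e1, e2)) / (e1 + e2), 1)
    sp <- synthetic_spec(p = 60, n_edges = c(ND = e1, HFD = e2),
                         target_esd = target, degree_cap = 5,
                         differentiator_size = 0, phenotype_size = 0, seed = i)
    g <- make_condition_graphs(sp)
    s_grid <- 0:min(e1, e2)
    esd_grid <- (e1 + e2 - 2 * s_grid) / (e1 + e2)
    expect_equal(g$realized_esd, esd_grid[which.min(abs(esd_grid - target))])
    expect_equal(esd(g$graph_ND, g$graph_HFD)$value, g$realized_esd)
  }
})

test_that("precision matrices are positive definite with support equal to the graph", {
  nodes <- sprintf("n%02d", 1:10)
  empty <- undirected_network(character(0), character(0))
  pe <- graph_to_precision(empty, nodes, seed = 1)
  expect_equal(pe$omega, diag(1, 10), ignore_attr = TRUE)

  one <- undirected_network("n01", "n02")
  p1 <- graph_to_precision(one, sprintf("n%02d", 1:3), seed = 2)
  off <- p1$omega; diag(off) <- 0
  expect_equal(sum(off != 0), 2L)
  expect_true(off["n01", "n02"] != 0)

  chain <- chain_network(nodes)
  pc <- graph_to_precision(chain, nodes, seed = 3)
  ev <- eigen(pc$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  # matrix-inversion oracle: partial correlations from the inverse covariance
  # are nonzero exactly on chain edges
  sigma <- solve(pc$omega)
  om2 <- solve(sigma)
  pcor <- -om2 / sqrt(tcrossprod(diag(om2)))
  diag(pcor) <- 0
  on_edge <- abs(pcor[cbind(chain$node_a, chain$node_b)])
  off_edge <- abs(pcor[upper.tri(pcor)])
  expect_true(all(on_edge > 1e-8))
  expect_equal(sum(abs(pcor) > 1e-8) / 2, n_edges(chain))
  expect_error(graph_to_precision(empty, character(0)), "empty")
})

test_that("empirical covariance converges to the inverse precision with n", {
  nodes <- sprintf("n%02d", 1:10)
  pr <- graph_to_precision(chain_network(nodes), nodes, seed = 11)
  sigma <- chol2inv(chol(pr$omega))
  dev <- sapply(c(500, 10000), function(n) {
    x <- sample_mvn_from_precision(pr$omega, n, seed = 21)
    max(abs(cov(x) * (n - 1) / n - sigma))
  })
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.08)
})

test_that("sampled tables respect censoring, planted shifts and determinism", {
  sp <- synthetic_spec(p = 40, n_per_condition = c(ND = 30, HFD = 30),
                       n_edges = c(ND = 15, HFD = 15), target_esd = 0.8,
                       differentiator_size = 5, phenotype_size = 4,
                       detection_floor_quantile = 0, seed = 31)
  sim <- sample_table(sp)
  expect_equal(sum(is.na(sim$table$values)), 0L)
  sim2 <- sample_table(sp)
  expect_identical(sim$table$values, sim2$table$values)
  expect_identical(sim$meta, sim2$meta)

  # censoring removes values only from the lower tail
  spc <- synthetic_spec(p = 30, n_per_condition = c(ND = 20, HFD = 20),
                        n_edges = c(ND = 10, HFD = 10), target_esd = 0.8,
                        differentiator_size = 0, phenotype_size = 0,
                        detection_floor_quantile = 0.1, seed = 32)
  simc <- simulate_study(spc)
  v <- simc$table$values
  expect_gt(sum(is.na(v)), 0)
  # regenerate uncensored twin to check which cells went missing
  spc0 <- spc; spc0$detection_floor_quantile <- 0
  v0 <- sample_table(spc0, make_synthetic_truth(spc0))$table$values
  expect_equal(v0[!is.na(v)], v[!is.na(v)])
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) expect_lt(max(v0[miss, j]), min(v0[!miss, j]))
  }
})

test_that("planted differentiators carry the designed power", {
  # 3-SD shift at n = 30 per condition: two-sample t rejects at alpha 0.01
  rejections <- sapply(1:10, function(s) {
    sp <- synthetic_spec(p = 30, n_per_condition = c(ND = 30, HFD = 30),
                         n_edges = c(ND = 10, HFD = 10), target_esd = 0.8,
                         differentiator_size = 5, phenotype_size = 0,
                         detection_floor_quantile = 0, seed = s)
    sim <- simulate_study(sp)
    tab <- impute_min_and_log(sim$table)$table
    m <- sim$truth$differentiator_ids[1]
    pv <- t.test(tab$values[sim$meta$diet == "HFD", m],
                 tab$values[sim$meta$diet == "ND", m])$p.value
    pv < 0.01
  })
  expect_gte(sum(rejections), 9)
})

test_that("genotype design covers the three reaction-norm classes consistently", {
  sim <- simulate_study(synthetic_spec(seed = 8))
  expect_equal(nrow(sim$meta), 31L)
  expect_equal(as.vector(table(sim$meta$diet)), c(16L, 15L))
  expect_setequal(levels(sim$meta$reaction_norm), c("N_gt_HF", "zero", "N_lt_HF"))
  # triglyceride phenotypes reproduce each genotype's class under the 25% rule
  per_gt <- unique(sim$meta[, c("genotype", "reaction_norm")])
  for (g in per_gt$genotype) {
    rows <- sim$meta$genotype == g
    nd <- unique(sim$meta$triglyceride[rows & sim$meta$diet == "ND"])
    hfd <- unique(sim$meta$triglyceride[rows & sim$meta$diet == "HFD"])
    if (length(nd) == 1 && length(hfd) == 1)
      expect_equal(as.character(assign_reaction_norm(nd, hfd)),
                   as.character(per_gt$reaction_norm[per_gt$genotype == g]))
  }
})
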